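## Desk-scale replay pipeline: simulate -> call -> merge -> prune ->
## statistics -> inference -> projection -> ROH, with a consolidated report.

#' Default replay configuration
#'
#' The default scale (100k SNPs on 22 chromosomes of 100 cM, i.e. ~440
#' five-centimorgan jackknife blocks; 10 diploid samples for the modern
#' outgroup and 1--4 pseudo-haploid samples per ancient population) is large
#' enough for |Z| > 3 admixture signals yet runs in minutes.
#'
#' @param nSnps number of SNPs to simulate.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param outDir output directory, or NULL to skip writing artifacts.
#' @return Nested configuration list for [runReplay()].
#' @export
defaultReplayConfig <- function(nSnps = 1e5, seed = 1, outDir = NULL) {
  list(
    preset = "jones2015",
    nSnps = nSnps,
    seed = seed,
    outDir = outDir,
    blockCm = 5,
    coverage = 1.4,
    errorRate = 0.001,
    stages = list(call = TRUE, merge = TRUE, prune = TRUE, stats = TRUE,
                  fit = FALSE, pca = TRUE, roh = TRUE),
    prune = list(profile = "pca"),
    fit = list(start = c(whgSplitYears = 60000, chgEfSplitYears = 18000),
               lower = c(25000, 17000), upper = c(95000, 44000)),
    roh = list(chromLengths = c(r1 = 5e7, r2 = 5e7), hetDensity = 5e-4,
               segments = data.frame(chrom = "r1", start = 1e7, end = 1.5e7),
               errorHetRate = 0.001, snpDensity = 1e-3)
  )
}

#' Read or write a replay configuration
#'
#' YAML round-trip of the [defaultReplayConfig()] structure; missing keys are
#' filled with defaults.
#'
#' @param path file path.
#' @param config configuration list (writer).
#' @return \code{readRunConfig()} returns the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultReplayConfig()
  mergeCfg <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]])) {
        mergeCfg(base[[k]], new[[k]])
      } else if (!is.null(base[[k]]) && !is.list(base[[k]]) &&
                 is.list(new[[k]])) {
        # named vectors are stored as YAML maps; restore the atomic form
        unlist(new[[k]])
      } else new[[k]]
    }
    base
  }
  cfg <- mergeCfg(base, cfg)
  if (is.data.frame(cfg$roh$segments) == FALSE &&
      !is.null(cfg$roh$segments)) {
    cfg$roh$segments <- as.data.frame(cfg$roh$segments)
  }
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  config$roh$segments <- as.list(as.data.frame(config$roh$segments))
  # yaml::write_yaml drops names on atomic vectors; write these as maps
  config$fit$start <- as.list(config$fit$start)
  config$roh$chromLengths <- as.list(config$roh$chromLengths)
  yaml::write_yaml(config, path)
  invisible(path)
}

writeTsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full synthetic replay
#'
#' Executes the pipeline on data simulated under the configured preset:
#' frequency drift simulation, genotype sampling, pseudo-haploid calling of a
#' low-coverage pileup, ancient/modern merge, LD pruning, f-statistics with
#' block-jackknife errors, the three-topology outgroup-f3 test, the CHG clade
#' D-test, the admixture-f3 scan of the steppe population, the f4-ratio
#' ancestry proportion, optional split-time fitting, PCA projection and ROH
#' profiling.  Writes EIGENSTRAT intermediates and TSV tables when
#' \code{config$outDir} is set, and returns a consolidated report whose
#' \code{pass} field reflects the headline assertions (correct topology
#' winner, supported CHG clade, (CHG, EHG) scan winner, f4-ratio within 2 SE
#' of one half).
#'
#' @param config configuration list from [defaultReplayConfig()] or
#'   [readRunConfig()].
#' @return Report list (invisibly returns artifacts under
#'   \code{config$outDir} when set).
#' @export
runReplay <- function(config = defaultReplayConfig()) {
  dir <- config$outDir
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  report <- list(config = list(preset = config$preset, nSnps = config$nSnps,
                               seed = config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("replay stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  model <- stage("model", buildPreset(config$preset))
  freqs <- stage("simulate",
                 simulateFrequencies(model, config$nSnps, config$seed))
  panel <- stage("sample", sampleGenotypes(freqs, model, config$seed + 1))
  snp <- snpTable(panel)

  if (isTRUE(config$stages$call)) {
    pile <- stage("pileup", simulatePileup(
      snp, coverage = config$coverage, errorRate = config$errorRate,
      seed = config$seed + 2, freq = freqs[, "Satsurblia"]))
    called <- stage("call", pseudoHaploidCall(
      pile, snp, seed = config$seed + 3, sampleId = "Satsurblia_lc",
      population = "Satsurblia"))
    report$called <- list(nCalled = sum(!is.na(dosage(called))),
                          nSites = nrow(called))
  } else called <- NULL

  if (isTRUE(config$stages$merge)) {
    smp <- sampleTable(panel)
    modern <- subsetPanel(panel,
                          sampleIds = smp$sampleId[smp$ploidy == "diploid"])
    ancient <- subsetPanel(panel,
                           sampleIds = smp$sampleId[smp$ploidy == "pseudohaploid"])
    if (!is.null(called)) {
      ancient <- GenoPanel(cbind(dosage(ancient), dosage(called)),
                           snpTable(ancient),
                           rbind(sampleTable(ancient), sampleTable(called)))
    }
    merged <- stage("merge", mergePanels(ancient, modern, minPopSize = 4))
    panel <- merged$panel
    snp <- snpTable(panel)
    report$merge <- merged$report
    writeTsv(merged$report, dir, "merge_report.tsv")
  }

  if (!is.null(dir)) {
    writeEigenstrat(panel, file.path(dir, "replay_panel"))
  }

  prunedIds <- if (isTRUE(config$stages$prune)) {
    ids <- stage("prune", ldPrune(panel, profile = config$prune$profile))
    report$prune <- list(kept = length(ids), total = nrow(snp))
    ids
  } else snp$snpId

  blocks <- assignBlocks(snp, config$blockCm)
  grouping <- list(Outgroup = "Outgroup", EF = "EF", EHG = "EHG",
                   Yamnaya = "Yamnaya",
                   WHG = c("Bichon", "Loschbour"),
                   CHG = c("Kotias", "Satsurblia"))
  fe <- popFrequencies(panel, grouping)

  if (isTRUE(config$stages$stats)) {
    topo <- stage("topology", topologyTest(fe, "CHG", "EF", "WHG",
                                           "Outgroup", blocks))
    report$topology <- list(winner = topo$winner, decisive = topo$decisive,
                            table = topo$table)
    writeTsv(topo$table, dir, "topology_f3.tsv")

    feLeaf <- popFrequencies(panel)
    clade <- stage("clade", cladeTest(feLeaf, "Outgroup",
                                      c("EF", "Bichon", "EHG"),
                                      "Kotias", "Satsurblia", blocks))
    report$clade <- list(supported = attr(clade, "cladeSupported"),
                         table = clade)
    writeTsv(clade, dir, "clade_dstats.tsv")

    scan <- stage("scan", admixtureScan(fe, "Yamnaya",
                                        c("CHG", "EHG", "WHG", "EF"),
                                        blocks, inbreed = TRUE))
    report$scan <- list(winner = unlist(scan[1, c("sourceA", "sourceB")],
                                        use.names = FALSE),
                        significant = scan$significant[1], table = scan)
    writeTsv(scan, dir, "admixture_scan.tsv")

    alpha <- stage("f4ratio", f4Ratio(feLeaf, "Outgroup", "Satsurblia",
                                      "Kotias", "EHG", "Yamnaya", blocks))
    report$f4ratio <- list(alpha = statEstimate(alpha), se = statSE(alpha))

    affinity <- stage("affinity", affinityRank(fe, "CHG",
                                               c("Outgroup", "EF"),
                                               "Yamnaya", blocks))
    writeTsv(affinity, dir, "affinity_rank.tsv")
  }

  if (isTRUE(config$stages$fit)) {
    obs <- stage("fit-observe", outgroupF3Table(
      popFrequencies(panel), "Outgroup",
      c("Bichon", "Loschbour", "Kotias", "Satsurblia", "EF", "EHG"), blocks))
    builder <- function(t, Ne, genTime) {
      buildPreset(config$preset, whgSplitYears = t[["whgSplitYears"]],
                  chgEfSplitYears = t[["chgEfSplitYears"]],
                  Ne = Ne, genTime = genTime)
    }
    fitres <- stage("fit", fitSplitTimes(
      obs, builder, start = config$fit$start,
      lower = config$fit$lower, upper = config$fit$upper,
      Ne = model@Ne, genTime = model@genTime))
    report$splitFit <- list(times = fitres$times, rss = fitres$rss)
  }

  if (isTRUE(config$stages$pca)) {
    smp <- sampleTable(panel)
    modernIds <- smp$sampleId[smp$ploidy == "diploid"]
    modern <- subsetPanel(panel, snpIds = prunedIds, sampleIds = modernIds)
    pm <- stage("pca", pcaFit(modern, nComponents = 2))
    ancientIds <- setdiff(smp$sampleId, modernIds)
    proj <- stage("project", lsqProject(
      subsetPanel(panel, snpIds = prunedIds, sampleIds = ancientIds), pm))
    scores <- rbind(pm@scores, proj)
    report$pca <- list(varianceExplained = pm@varianceExplained)
    if (!is.null(dir)) {
      writeTsv(data.frame(sample = rownames(scores), scores), dir,
               "pca_scores.tsv")
    }
  }

  if (isTRUE(config$stages$roh)) {
    rg <- stage("roh-genome", simulateRohGenome(
      unlist(config$roh$chromLengths), config$roh$hetDensity,
      config$roh$segments, config$roh$errorHetRate,
      seed = config$seed + 4, snpDensity = config$roh$snpDensity))
    iv <- stage("roh", detectRoh(rg))
    sm <- rohSummary(iv)
    report$roh <- list(nIntervals = nrow(iv), shortLong = sm$shortLong)
    writeTsv(iv, dir, "roh_intervals.tsv")
    writeTsv(sm$perBin, dir, "roh_summary.tsv")
  }

  if (isTRUE(config$stages$stats)) {
    report$pass <- list(
      topology = setequal(report$topology$winner, c("CHG", "EF")) &&
        report$topology$decisive,
      clade = isTRUE(report$clade$supported),
      scan = setequal(report$scan$winner, c("CHG", "EHG")) &&
        isTRUE(report$scan$significant),
      f4ratio = abs(report$f4ratio$alpha - 0.5) <= 2 * report$f4ratio$se
    )
    report$passAll <- all(unlist(report$pass))
  }
  if (!is.null(dir)) {
    summaryLines <- utils::capture.output(utils::str(report, max.level = 3))
    writeLines(summaryLines, file.path(dir, "replay_report.txt"))
  }
  report
}

#' Write the small fixture set used by examples and tests
#'
#' Generates, deterministically from the seed: a toy EIGENSTRAT panel
#' simulated under a two-population model, a pileup TSV, a planted-segment
#' ROH genome, the demography config for the preset, and an oracle table of
#' expected f2/f3/f4 values from the moment engine for the toy model.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named list of file paths, invisibly.
#' @export
makeFixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- DemographyModel(
    edges = data.frame(parent = c("R", "R", "A", "A"),
                       child = c("A", "B", "A1", "A2"),
                       drift = c(0.02, 0.05, 0.01, 0.01)),
    sampling = data.frame(population = c("A1", "A2", "B"),
                          nDiploid = c(4, 0, 4), nPseudo = c(0, 2, 0)))
  p <- simulateFrequencies(model, 500, seed)
  panel <- sampleGenotypes(p, model, seed + 1, nChrom = 2,
                           chromLengthBp = 1e7)
  paths <- list()
  paths$eigenstrat <- writeEigenstrat(panel, file.path(dir, "toy"))
  pile <- simulatePileup(snpTable(panel), coverage = 1.4, errorRate = 0.01,
                         seed = seed + 2, freq = p[, "A2"])
  paths$pileup <- writePileup(pile, file.path(dir, "toy_pileup.tsv"))
  rg <- simulateRohGenome(c(rchr = 2e7), hetDensity = 5e-4,
                          plantedSegments = data.frame(chrom = "rchr",
                                                       start = 5e6,
                                                       end = 1e7),
                          errorHetRate = 0.001, seed = seed + 3)
  paths$roh <- writeEigenstrat(rg, file.path(dir, "toy_roh"))
  paths$demography <- writeDemography(model, file.path(dir, "toy_model.yaml"))
  mt <- expectedFMoments(model)
  oracle <- data.frame(
    statistic = c("f2(A1,B)", "f3(A1;A2,B)", "f4(A1,A2;B,R)"),
    expected = c(expectedF2(mt, "A1", "B"),
                 expectedF3(mt, "A1", "A2", "B"),
                 expectedF4(mt, "A1", "A2", "B", "R")))
  paths$oracle <- file.path(dir, "toy_oracle.tsv")
  write.table(oracle, paths$oracle, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
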