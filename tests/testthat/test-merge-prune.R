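miniPanel <- function(d, chrom, position, allele1, allele2, pops, ploidy,
                      ids = NULL, snpIds = NULL) {
  n <- nrow(d)
  if (is.null(snpIds)) snpIds <- sprintf("s%d", seq_len(n))
  if (is.null(ids)) ids <- sprintf("i%d", seq_len(ncol(d)))
  GenoPanel(d,
            data.frame(snpId = snpIds, chrom = chrom, position = position,
                       geneticPos = position / 1e4, allele1 = allele1,
                       allele2 = allele2),
            data.frame(sampleId = ids, population = pops, ploidy = ploidy))
}

test_that("the merge applies every ancient-panel filter in turn", {
  # modern: 5 "Mod" + 2 "Tiny" diploids over 6 SNPs
  md <- rbind(
    c(0, 1, 2, 1, 0, 1, 2),   # m1: shared, polymorphic
    c(2, 1, 0, 1, 2, 0, 1),   # m2: shared, ancient lists alleles swapped
    c(2, 2, 2, 2, 2, 0, 0),   # m3: fixed among retained moderns -> MAF 0
    c(0, 1, 1, 0, 2, 1, 1),   # m4: ancient allele pair mismatches
    c(1, 1, 0, 2, 1, 0, 2),   # m5: on X -> non-autosomal
    c(0, 0, 1, 2, 1, 1, 0))   # m6: absent from the ancient panel
  modern <- miniPanel(md,
                      chrom = c("1", "1", "1", "1", "X", "1"),
                      position = c(100L, 200L, 300L, 400L, 100L, 500L),
                      allele1 = c("A", "C", "A", "A", "A", "C"),
                      allele2 = c("G", "T", "C", "G", "G", "G"),
                      pops = c(rep("Mod", 5), rep("Tiny", 2)),
                      ploidy = "diploid",
                      snpIds = sprintf("m%d", 1:6))
  ad <- matrix(c(2L, 0L, 2L, 0L, 2L, 0L), ncol = 1)
  ancient <- miniPanel(ad,
                       chrom = c("1", "1", "1", "1", "1", "X"),
                       position = c(100L, 200L, 300L, 400L, 450L, 100L),
                       allele1 = c("A", "T", "A", "A", "A", "A"),
                       allele2 = c("G", "C", "C", "T", "G", "G"),
                       pops = "Anc", ploidy = "pseudohaploid", ids = "anc1",
                       snpIds = c("m1", "m2", "m3", "m4", "a7", "m5"))
  res <- mergePanels(ancient, modern, minPopSize = 4)
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "snp_not_shared"], 2)
  expect_equal(rep$removed[rep$filter == "non_autosomal"], 1)
  expect_equal(rep$removed[rep$filter == "modern_population_too_small"], 1)
  expect_equal(rep$removed[rep$filter == "modern_maf_zero"], 1)
  expect_equal(rep$removed[rep$filter == "allele_mismatch"], 1)
  panel <- res$panel
  expect_equal(snpTable(panel)$snpId, c("m1", "m2"))
  smp <- sampleTable(panel)
  expect_equal(smp$population, c(rep("Mod", 5), "Anc"))
  d <- dosage(panel)
  expect_equal(unname(d[, 1:5]), md[1:2, 1:5])
  # m1 direct (dosage 2), m2 recoded for the swapped allele order: 2 - 0
  expect_equal(unname(d[, 6]), c(2L, 2L))
  expect_error(mergePanels(ancient, modern, minPopSize = 10), "sufficient")
})

test_that("a merged panel survives an EIGENSTRAT round-trip unchanged", {
  m <- twoLeafModel(0.02, sampling = data.frame(
    population = c("A", "B"), nDiploid = c(5, 0), nPseudo = c(0, 2)))
  p <- simulateFrequencies(m, 300, seed = 12)
  panel <- sampleGenotypes(p, m, seed = 13, nChrom = 2, chromLengthBp = 1e7)
  smp <- sampleTable(panel)
  res <- mergePanels(
    subsetPanel(panel, sampleIds = smp$sampleId[smp$ploidy == "pseudohaploid"]),
    subsetPanel(panel, sampleIds = smp$sampleId[smp$ploidy == "diploid"]))
  prefix <- file.path(withr::local_tempdir(), "merged")
  writeEigenstrat(res$panel, prefix)
  back <- readEigenstrat(prefix, pseudohaploid = "B")
  expect_equal(unname(dosage(back)), unname(dosage(res$panel)))
  expect_equal(sampleTable(back)$ploidy, sampleTable(res$panel)$ploidy)
})

test_that("LD pruning removes the lower-MAF member of correlated pairs", {
  g1 <- c(0, 0, 0, 1, 1, 2, 2, 2)          # MAF 0.5
  gLow <- c(0, 0, 0, 0, 0, 2, 2, 2)        # r2 = 0.8 with g1, MAF 0.375
  gInd <- c(2, 0, 1, 1, 2, 0, 2, 0)        # r2 = 1/36 with g1
  expect_gt(cor(g1, gLow)^2, 0.5)
  expect_lt(cor(g1, gInd)^2, 0.5)
  panel <- miniPanel(rbind(g1, g1, gLow, gInd), chrom = "1",
                     position = c(100L, 200L, 300L, 400L),
                     allele1 = "A", allele2 = "G",
                     pops = "P", ploidy = "diploid")
  kept <- ldPrune(panel, window = 10, step = 5, r2Threshold = 0.5)
  # the duplicate pair ties on MAF -> the later position goes; then the
  # r2 = 0.8 pair drops the lower-MAF member
  expect_equal(kept, c("s1", "s4"))
})

test_that("pruning restarts at chromosome boundaries", {
  g1 <- c(0, 0, 0, 1, 1, 2, 2, 2)
  panel <- miniPanel(rbind(g1, g1), chrom = c("1", "2"),
                     position = c(100L, 100L),
                     allele1 = "A", allele2 = "G",
                     pops = "P", ploidy = "diploid")
  expect_equal(ldPrune(panel, window = 10, step = 5, r2Threshold = 0.5),
               c("s1", "s2"))
})

test_that("pruning is invariant to sample order and warns on empty SNPs", {
  m <- twoLeafModel(0.05, sampling = data.frame(
    population = c("A", "B"), nDiploid = c(6, 6), nPseudo = 0))
  p <- simulateFrequencies(m, 400, seed = 20)
  panel <- sampleGenotypes(p, m, seed = 21, nChrom = 2, chromLengthBp = 1e7)
  kept <- ldPrune(panel, window = 50, step = 10, r2Threshold = 0.3)
  perm <- sample(ncol(panel))
  shuffled <- GenoPanel(dosage(panel)[, perm], snpTable(panel),
                        sampleTable(panel)[perm, ])
  expect_equal(ldPrune(shuffled, window = 50, step = 10, r2Threshold = 0.3),
               kept)
  d <- dosage(panel)
  d[3, ] <- NA
  blank <- GenoPanel(d, snpTable(panel), sampleTable(panel))
  expect_warning(ldPrune(blank, window = 50, step = 10, r2Threshold = 0.3),
                 "no data")
})

test_that("pruning profiles carry the published parameters", {
  expect_equal(pruneProfile("pca"),
               list(window = 200, step = 25, r2Threshold = 0.2))
  expect_equal(pruneProfile("admixture"),
               list(window = 200, step = 25, r2Threshold = 0.5))
  expect_error(pruneProfile("bogus"))
})

test_that("jackknife blocks are 5 cM windows restarting per chromosome", {
  snp <- data.frame(chrom = c("1", "1", "1", "1", "2", "2"),
                    geneticPos = c(0, 4.99, 5, 12, 0.1, 7))
  expect_equal(assignBlocks(snp),
               c("1:0", "1:0", "1:1", "1:2", "2:0", "2:1"))
  expect_equal(assignBlocks(snp, blockCm = 6),
               c("1:0", "1:0", "1:0", "1:2", "2:0", "2:1"))
  expect_error(assignBlocks(data.frame(chrom = "1", geneticPos = NA_real_)),
               "genetic positions")
  # two 100 cM chromosomes yield 20 blocks each at the 5 cM default
  m <- twoLeafModel(0.02, sampling = data.frame(
    population = "A", nDiploid = 2, nPseudo = 0))
  p <- simulateFrequencies(m, 2000, seed = 30)
  panel <- sampleGenotypes(p, m, seed = 31, nChrom = 2, chromLengthBp = 1e8)
  expect_equal(length(unique(assignBlocks(snpTable(panel)))), 40)
})
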