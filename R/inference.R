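## Decision procedures built on f-statistics: topology and clade tests,
## affinity ranking, admixture scans and moments-based split-time fitting.

# Per-SNP f3 terms and complete-case mask (shared by the difference
# jackknife of topologyTest).
f3Terms <- function(freqs, C, A, B, inbreed = FALSE) {
  pC <- feP(freqs, C); pA <- feP(freqs, A); pB <- feP(freqs, B)
  nEff <- if (inbreed) feInds(freqs, C) else feN(freqs, C)
  keep <- !is.na(pC) & !is.na(pA) & !is.na(pB) & nEff >= 2
  corr <- ifelse(is.infinite(nEff), 0, pC * (1 - pC) / (nEff - 1))
  list(terms = (pC - pA) * (pC - pB) - corr, keep = keep)
}

#' Three-topology outgroup-f3 test
#'
#' Computes \eqn{f3(\mathrm{outgroup}; P_i, P_j)} for the three pairs among
#' \code{P1, P2, P3}.  The pair sharing the most post-outgroup drift (largest
#' f3) is the inferred clade; the verdict is decisive when the winner exceeds
#' both alternatives by a difference with jackknife |Z| > 3.
#'
#' @inheritParams f2Stat
#' @param P1,P2,P3 the three candidate populations.
#' @param outgroup outgroup population (distinct from the candidates).
#' @return list of class \code{"TopologyVerdict"}: \code{table} (pair, f3,
#'   se, z per candidate clade), \code{winner} (character vector of the two
#'   clade members), \code{differenceZ} (winner minus each alternative),
#'   \code{decisive}.
#' @export
topologyTest <- function(freqs, P1, P2, P3, outgroup, blocks) {
  pops <- c(P1, P2, P3)
  if (anyDuplicated(c(pops, outgroup))) {
    stop("populations and outgroup must be distinct")
  }
  pairs <- list(c(P1, P2), c(P1, P3), c(P2, P3))
  stats <- lapply(pairs, function(pr) {
    f3Stat(freqs, outgroup, pr[1], pr[2], blocks)
  })
  tab <- data.frame(
    pop1 = vapply(pairs, `[`, "", 1), pop2 = vapply(pairs, `[`, "", 2),
    f3 = vapply(stats, statEstimate, 0),
    se = vapply(stats, statSE, 0),
    z = vapply(stats, statZ, 0),
    nSnps = vapply(stats, function(s) s@nSnps, 0)
  )
  winIdx <- which.max(tab$f3)
  terms <- lapply(pairs, function(pr) {
    f3Terms(freqs, outgroup, pr[1], pr[2])
  })
  diffZ <- numeric(0)
  for (j in setdiff(seq_along(pairs), winIdx)) {
    keep <- terms[[winIdx]]$keep & terms[[j]]$keep
    dterms <- terms[[winIdx]]$terms - terms[[j]]$terms
    jk <- jackknifeTerms(dterms, NULL, blocks, keep)
    diffZ[paste(pairs[[j]], collapse = ",")] <- jk$estimate / jk$se
  }
  structure(list(table = tab, winner = pairs[[winIdx]],
                 differenceZ = diffZ,
                 decisive = all(abs(diffZ) > 3)),
            class = "TopologyVerdict")
}

#' @export
print.TopologyVerdict <- function(x, ...) {
  cat("Outgroup-f3 topology test\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("winner: (%s) | min difference Z = %.2f -> %s\n",
              paste(x$winner, collapse = ", "), min(abs(x$differenceZ)),
              if (x$decisive) "decisive" else "indecisive"))
  invisible(x)
}

#' Clade test against a probe set
#'
#' For each probe population computes \eqn{D(\mathrm{outgroup},
#' \mathrm{probe}; A, B)}.  If A and B form a clade with respect to every
#' probe, no statistic should be significant; any |Z| > 3 marks gene flow
#' violating the clade.
#'
#' @inheritParams f2Stat
#' @param outgroup outgroup population.
#' @param probes character vector of probe populations.
#' @return data.frame (one row per probe: estimate, se, z, nSnps, nBlocks,
#'   significant) with attribute \code{cladeSupported}.
#' @export
cladeTest <- function(freqs, outgroup, probes, A, B, blocks) {
  if (length(probes) == 0) stop("probe set is empty")
  if (anyDuplicated(c(outgroup, probes, A, B))) {
    stop("outgroup, probes and clade members must be distinct")
  }
  rows <- lapply(probes, function(pr) {
    s <- dStat(freqs, outgroup, pr, A, B, blocks)
    data.frame(probe = pr, estimate = statEstimate(s), se = statSE(s),
               z = statZ(s), nSnps = s@nSnps, nBlocks = s@nBlocks)
  })
  out <- do.call(rbind, rows)
  out$significant <- abs(out$z) > 3
  attr(out, "cladeSupported") <- !any(out$significant)
  out
}

#' Rank modern populations by shared drift with an ancient sample
#'
#' Outgroup-f3 affinity scan: \eqn{f3(\mathrm{outgroup}; \mathrm{modern},
#' \mathrm{ancient})} per modern population, ranked descending; the top row
#' shares the most genetic history with the ancient genome.
#'
#' @inheritParams f2Stat
#' @param ancient ancient population.
#' @param moderns character vector of modern populations.
#' @param outgroup outgroup population.
#' @return data.frame sorted by decreasing f3.
#' @export
affinityRank <- function(freqs, ancient, moderns, outgroup, blocks) {
  if (length(moderns) == 0) stop("need at least one modern population")
  rows <- lapply(moderns, function(m) {
    s <- f3Stat(freqs, outgroup, m, ancient, blocks)
    data.frame(modern = m, f3 = statEstimate(s), se = statSE(s),
               z = statZ(s), nSnps = s@nSnps, nBlocks = s@nBlocks)
  })
  out <- do.call(rbind, rows)
  out[order(-out$f3), , drop = FALSE]
}

#' Admixture-f3 source scan
#'
#' Computes \eqn{f3(X, Y; \mathrm{target})} for every unordered candidate
#' pair; a more negative value marks a more likely source pair, and
#' \eqn{Z < -3} marks a significant admixture signal.  Use
#' \code{inbreed = TRUE} when the target consists of ancient/pseudo-haploid
#' samples.
#'
#' @inheritParams f2Stat
#' @param target the putatively admixed population.
#' @param candidates candidate source populations (>= 2).
#' @return data.frame of candidate pairs sorted ascending by the statistic,
#'   with a \code{significant} flag (Z < -3).
#' @export
admixtureScan <- function(freqs, target, candidates, blocks,
                          inbreed = FALSE) {
  if (length(candidates) < 2) stop("need at least two candidate sources")
  if (target %in% candidates) stop("target cannot be among the candidates")
  prs <- utils::combn(candidates, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    s <- f3Stat(freqs, target, pr[1], pr[2], blocks, inbreed = inbreed)
    data.frame(sourceA = pr[1], sourceB = pr[2],
               f3 = statEstimate(s), se = statSE(s), z = statZ(s),
               nSnps = s@nSnps, nBlocks = s@nBlocks)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$z < -3
  out[order(out$f3), , drop = FALSE]
}

#' Observed outgroup-f3 table for split-time fitting
#'
#' Convenience builder of the observed-statistic table consumed by
#' [fitSplitTimes()]: \eqn{f3(\mathrm{outgroup}; X, Y)} for all unordered
#' pairs of \code{pops}.  Outgroup-f3 statistics need the small-sample
#' correction only on the outgroup, so they remain estimable when the other
#' populations are single pseudo-haploid genomes.
#'
#' @inheritParams f2Stat
#' @param outgroup outgroup population.
#' @param pops populations to pair.
#' @return data.frame with columns \code{type}, \code{pop1} (f3 target),
#'   \code{pop2}, \code{pop3}, \code{estimate}, \code{se}.
#' @export
outgroupF3Table <- function(freqs, outgroup, pops, blocks) {
  prs <- utils::combn(pops, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    s <- f3Stat(freqs, outgroup, pr[1], pr[2], blocks)
    data.frame(type = "f3", pop1 = outgroup, pop2 = pr[1], pop3 = pr[2],
               pop4 = NA_character_, estimate = statEstimate(s),
               se = statSE(s))
  })
  do.call(rbind, rows)
}

expectedStatRow <- function(mt, row) {
  switch(row$type,
         f2 = expectedF2(mt, row$pop1, row$pop2),
         f3 = expectedF3(mt, row$pop1, row$pop2, row$pop3),
         f4 = expectedF4(mt, row$pop1, row$pop2, row$pop3, row$pop4),
         stop(sprintf("unknown statistic type '%s'", row$type)))
}

#' Fit split times by the method of moments
#'
#' Minimizes \eqn{\sum_i [(\mathrm{obs}_i - \mathrm{exp}_i(t)) / se_i]^2}
#' over free split times, where expected statistics come from the exact
#' drift-moment engine ([expectedFMoments()]) applied to the model the
#' builder constructs for a candidate time vector.  The effective size and
#' generation time are not identifiable from f-statistics alone and must be
#' supplied explicitly.
#'
#' @param observed data.frame of observed statistics: columns \code{type}
#'   ("f2"/"f3"/"f4"), \code{pop1..pop4} (f3 rows: pop1 = target) ,
#'   \code{estimate}, \code{se}; see [outgroupF3Table()].
#' @param builder function \code{(times, Ne, genTime) -> DemographyModel}
#'   mapping a named vector of free split times to a model.
#' @param start named numeric vector of starting times (years).
#' @param lower,upper box bounds on the times (years).
#' @param Ne diploid effective size (required, no default).
#' @param genTime generation time in years (required, no default).
#' @return list of class \code{"SplitFit"}: \code{times} (fitted, years),
#'   \code{rss}, \code{convergence}, \code{nonIdentifiable}, \code{fixed}
#'   (Ne/genTime), \code{nStats}.
#' @export
fitSplitTimes <- function(observed, builder, start, lower = 0, upper = Inf,
                          Ne, genTime) {
  if (missing(Ne) || missing(genTime)) {
    stop("Ne and genTime must be supplied explicitly")
  }
  if (nrow(observed) < length(start)) {
    stop("more free parameters than observed statistics")
  }
  if (any(observed$se <= 0 | !is.finite(observed$se))) {
    stop("observed statistics need positive finite standard errors")
  }
  objective <- function(t) {
    names(t) <- names(start)
    model <- tryCatch(builder(t, Ne, genTime), error = function(e) NULL)
    if (is.null(model)) return(1e12)
    mt <- expectedFMoments(model)
    expv <- vapply(seq_len(nrow(observed)),
                   function(i) expectedStatRow(mt, observed[i, ]), 0)
    sum(((observed$estimate - expv) / observed$se)^2)
  }
  fit <- if (length(start) == 1) {
    optim(start, objective, method = "Brent",
          lower = max(lower, 0), upper = min(upper, 1e7))
  } else {
    optim(start, objective, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(factr = 1e4))
  }
  # flat-objective (non-identifiability) probe
  base <- fit$value
  flat <- all(vapply(seq_along(fit$par), function(k) {
    t2 <- fit$par
    t2[k] <- t2[k] * 1.02 + 1
    abs(objective(t2) - base) < 1e-9
  }, logical(1)))
  structure(list(times = setNames(fit$par, names(start)), rss = fit$value,
                 convergence = fit$convergence, nonIdentifiable = flat,
                 fixed = list(Ne = Ne, genTime = genTime),
                 nStats = nrow(observed)),
            class = "SplitFit")
}

#' Split-time recovery experiment on the built-in preset
#'
#' Runs one end-to-end divergence-dating experiment: simulate allele
#' frequencies under the \code{"jones2015"} preset, sample its default
#' genotype panel, compute all outgroup-f3 statistics among the six ancient
#' leaves with block-jackknife errors, and fit the two free split times (WHG
#' vs the CHG+EF ancestor, and CHG vs EF) by [fitSplitTimes()] with the
#' effective size and generation time fixed to the preset's own values.
#' All randomness derives from \code{seed}, so results are reproducible.
#'
#' @param seed integer seed for the whole experiment.
#' @param nSnps number of SNPs to simulate (default 200000).
#' @return The \code{"SplitFit"} from [fitSplitTimes()]; fitted times are in
#'   years under names \code{whgSplitYears} and \code{chgEfSplitYears}.
#' @export
fitPresetSplitTimes <- function(seed, nSnps = 200000) {
  model <- buildPreset("jones2015")
  p <- simulateFrequencies(model, nSnps, seed)
  panel <- sampleGenotypes(p, model)   # continues the seeded RNG stream
  fe <- popFrequencies(panel)
  blocks <- assignBlocks(snpTable(panel))
  obs <- outgroupF3Table(fe, "Outgroup",
                         c("Bichon", "Loschbour", "Kotias", "Satsurblia",
                           "EF", "EHG"), blocks)
  builder <- function(t, Ne, genTime) {
    buildPreset("jones2015", whgSplitYears = t[["whgSplitYears"]],
                chgEfSplitYears = t[["chgEfSplitYears"]],
                Ne = Ne, genTime = genTime)
  }
  fitSplitTimes(obs, builder,
                start = c(whgSplitYears = 60000, chgEfSplitYears = 18000),
                lower = c(25000, 17000), upper = c(95000, 44000),
                Ne = model@Ne, genTime = model@genTime)
}

#' @export
print.SplitFit <- function(x, ...) {
  cat("Moments-based split-time fit\n")
  for (nm in names(x$times)) {
    cat(sprintf("  %s: %.0f years (%.1f kya)\n", nm, x$times[nm],
                x$times[nm] / 1000))
  }
  cat(sprintf("  RSS %.4g over %d statistics (Ne = %g, genTime = %g)%s\n",
              x$rss, x$nStats, x$fixed$Ne, x$fixed$genTime,
              if (x$nonIdentifiable) " [flat objective: not identifiable]"
              else ""))
  invisible(x)
}
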