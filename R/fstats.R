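## Allele-frequency estimation and f/D statistics with weighted block
## jackknife.

#' Estimate per-population allele frequencies
#'
#' Counts allele1 chromosomes per (population, SNP).  A diploid sample
#' contributes its dosage out of 2 chromosomes; a pseudo-haploid sample
#' contributes its single sampled allele out of 1 chromosome (the duplicated
#' homozygote carries no second observation).  Missing dosages are excluded
#' per SNP.  The individual count per (population, SNP) is retained for the
#' inbreed-aware small-sample correction of [f3Stat()].
#'
#' @param panel a [GenoPanel-class].
#' @param grouping optional named list mapping analysis population names to
#'   vectors of panel population labels (e.g.
#'   \code{list(CHG = c("Kotias", "Satsurblia"))}); by default every panel
#'   population is its own group.
#' @return A [FreqEstimate-class].
#' @export
popFrequencies <- function(panel, grouping = NULL) {
  smp <- sampleTable(panel)
  d <- dosage(panel)
  if (is.null(grouping)) {
    grouping <- split(unique(smp$population), unique(smp$population))
  }
  groups <- names(grouping)
  nSnp <- nrow(d)
  counts <- matrix(0, nSnp, length(groups), dimnames = list(NULL, groups))
  chroms <- counts
  inds <- counts
  for (g in groups) {
    j <- which(smp$population %in% grouping[[g]])
    if (length(j) == 0) stop(sprintf("population group '%s' is empty", g))
    sub <- d[, j, drop = FALSE]
    w <- ifelse(smp$ploidy[j] == "diploid", 1, 0.5)
    W <- matrix(w, nSnp, length(j), byrow = TRUE)
    obs <- !is.na(sub)
    counts[, g] <- rowSums(sub * W, na.rm = TRUE)
    chroms[, g] <- rowSums(obs * (2 * W))
    inds[, g] <- rowSums(obs)
  }
  new("FreqEstimate", counts = counts, chroms = chroms,
      snpId = snpTable(panel)$snpId) -> fe
  attr(fe, "inds") <- inds
  fe
}

#' Frequency table from known (noise-free) frequencies
#'
#' Wraps a SNPs x populations frequency matrix as a [FreqEstimate-class] with
#' infinite chromosome counts, so that all small-sample corrections vanish.
#' Useful for comparing statistics computed on simulated frequencies directly
#' against the moment oracle.
#'
#' @param p SNPs x populations matrix of frequencies in [0,1].
#' @param snpId optional SNP ids.
#' @return A [FreqEstimate-class].
#' @export
freqEstimateFromFrequencies <- function(p, snpId = NULL) {
  p <- as.matrix(p)
  if (is.null(snpId)) snpId <- sprintf("snp%d", seq_len(nrow(p)))
  inf <- matrix(Inf, nrow(p), ncol(p), dimnames = dimnames(p))
  # counts slot holds the frequencies directly when chroms are infinite
  fe <- new("FreqEstimate", counts = p, chroms = inf, snpId = snpId)
  attr(fe, "inds") <- inf
  fe
}

setMethod("show", "FreqEstimate", function(object) {
  cat(sprintf("FreqEstimate: %d SNPs x %d populations (%s)\n",
              nrow(object@counts), ncol(object@counts),
              paste(colnames(object@counts), collapse = ", ")))
})

#' @describeIn popFrequencies Frequency matrix \eqn{\hat p = a/n}
#'   (NaN where a population has no data).
#' @param freqs a [FreqEstimate-class].
#' @export
freqMatrix <- function(freqs) {
  p <- freqs@counts / freqs@chroms
  p[is.infinite(freqs@chroms)] <- freqs@counts[is.infinite(freqs@chroms)]
  p
}

feP <- function(freqs, pop) {
  if (!pop %in% colnames(freqs@counts)) {
    stop(sprintf("unknown population '%s'", pop))
  }
  n <- freqs@chroms[, pop]
  p <- ifelse(is.infinite(n), freqs@counts[, pop], freqs@counts[, pop] / n)
  p[n == 0] <- NA_real_
  p
}

feN <- function(freqs, pop) freqs@chroms[, pop]

feInds <- function(freqs, pop) {
  ind <- attr(freqs, "inds")
  if (is.null(ind)) freqs@chroms[, pop] else ind[, pop]
}

newFStat <- function(label, jk, nSnps) {
  z <- if (is.na(jk$se) || jk$se == 0) {
    if (!is.na(jk$se) && jk$estimate == 0) 0 else NA_real_
  } else jk$estimate / jk$se
  new("FStat", label = label, estimate = jk$estimate, se = jk$se,
      z = z, nSnps = nSnps, nBlocks = jk$nBlocks)
}

setMethod("show", "FStat", function(object) {
  cat(sprintf("%s = %.6g  SE %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              object@label, object@estimate, object@se, object@z,
              object@nSnps, object@nBlocks))
})

#' @describeIn f2Stat Point estimate of an [FStat-class].
#' @param x an [FStat-class].
#' @export
statEstimate <- function(x) x@estimate

#' @describeIn f2Stat Jackknife standard error.
#' @export
statSE <- function(x) x@se

#' @describeIn f2Stat Z-score (estimate / SE).
#' @export
statZ <- function(x) x@z

#' Weighted delete-one-block jackknife
#'
#' Given per-block numerator sums (and, for ratio statistics, denominator
#' sums) with block weights, returns the full-data estimate and the weighted
#' jackknife standard error for unequal block sizes: with \eqn{h_j = n/m_j},
#' pseudovalues \eqn{\tau_j = h_j\hat\theta - (h_j-1)\hat\theta_{(-j)}} and
#' \eqn{\mathrm{Var} = g^{-1} \sum_j (\tau_j - \theta_\cdot)^2/(h_j-1)} where
#' \eqn{\theta_\cdot = g\hat\theta - \sum_j (1-m_j/n)\hat\theta_{(-j)}}.
#' Reduces to the textbook unweighted jackknife for equal blocks.
#'
#' @param num per-block numerator sums.
#' @param den per-block denominator sums, or NULL for a mean-of-terms
#'   statistic (denominator = block weight).
#' @param weights per-block SNP counts.
#' @return list with \code{estimate}, \code{se} (NA when fewer than 2
#'   blocks), \code{nBlocks}.
#' @export
blockJackknife <- function(num, den = NULL, weights) {
  stopifnot(length(num) == length(weights))
  if (is.null(den)) den <- weights
  g <- length(num)
  Sn <- sum(num)
  Sd <- sum(den)
  if (Sd == 0) stop("zero denominator in jackknife statistic")
  theta <- Sn / Sd
  if (g < 2) {
    return(list(estimate = theta, se = NA_real_, nBlocks = g))
  }
  loo <- (Sn - num) / (Sd - den)
  if (any(!is.finite(loo))) stop("a single block carries the whole denominator")
  n <- sum(weights)
  h <- n / weights
  tau <- h * theta - (h - 1) * loo
  thetaDot <- g * theta - sum((1 - weights / n) * loo)
  v <- sum((tau - thetaDot)^2 / (h - 1)) / g
  list(estimate = theta, se = sqrt(v), nBlocks = g)
}

# Sum per-SNP terms within blocks and jackknife.  terms/den may contain NA
# (excluded SNPs); keep = complete-case mask.
jackknifeTerms <- function(terms, den = NULL, blocks, keep) {
  if (!any(keep)) stop("no SNPs usable for this statistic")
  b <- blocks[keep]
  numB <- rowsum(terms[keep], b)[, 1]
  wB <- rowsum(rep(1, sum(keep)), b)[, 1]
  denB <- if (is.null(den)) NULL else rowsum(den[keep], b)[, 1]
  jk <- blockJackknife(numB, denB, wB)
  jk$nSnps <- sum(keep)
  jk
}

#' f-statistics with block-jackknife errors
#'
#' Unbiased moment estimators over a [FreqEstimate-class]:
#' \describe{
#'   \item{f2(A,B)}{per-SNP \eqn{(\hat a-\hat b)^2 - \hat a(1-\hat a)/(n_A-1)
#'     - \hat b(1-\hat b)/(n_B-1)}; requires \eqn{\ge 2} chromosomes in both
#'     populations at a SNP.}
#'   \item{f3(C;A,B)}{per-SNP \eqn{(\hat c-\hat a)(\hat c-\hat b) -
#'     \hat c(1-\hat c)/(n_C-1)}; with \code{inbreed = TRUE} the correction
#'     divisor counts individuals as single chromosomes (within-individual
#'     heterozygosity uninformative), the appropriate choice when the target
#'     is ancient/pseudo-haploid.  A significantly negative f3 indicates the
#'     target is admixed between A- and B-related sources.}
#'   \item{f4(W,X;Y,Z)}{per-SNP \eqn{(\hat w-\hat x)(\hat y-\hat z)}, no
#'     correction needed.}
#'   \item{D(W,X;Y,Z)}{the normalized ratio
#'     \eqn{\sum(\hat w-\hat x)(\hat y-\hat z) / \sum(\hat w+\hat x-2\hat w
#'     \hat x)(\hat y+\hat z-2\hat y\hat z)}, jackknifed as a ratio.}
#' }
#' A SNP enters a statistic only when every population in it has data there.
#' Standard errors come from the weighted block jackknife over
#' genetic-distance blocks ([assignBlocks()]); statistics with |Z| > 3 are
#' conventionally called significant.
#'
#' @param freqs a [FreqEstimate-class].
#' @param A,B,C,W,X,Y,Z population names in \code{freqs}.
#' @param blocks per-SNP block ids aligned with \code{freqs}.
#' @param inbreed logical; see Description (f3 only).
#' @return An [FStat-class].
#' @export
f2Stat <- function(freqs, A, B, blocks) {
  if (A == B) {
    # same population twice: identically zero (the cross-sample corrections
    # assume independent draws and would otherwise bias this degenerate case)
    return(new("FStat", label = sprintf("f2(%s, %s)", A, B), estimate = 0,
               se = 0, z = 0, nSnps = sum(!is.na(feP(freqs, A))),
               nBlocks = length(unique(blocks))))
  }
  pA <- feP(freqs, A); pB <- feP(freqs, B)
  nA <- feN(freqs, A); nB <- feN(freqs, B)
  keep <- !is.na(pA) & !is.na(pB) & nA >= 2 & nB >= 2
  corrA <- ifelse(is.infinite(nA), 0, pA * (1 - pA) / (nA - 1))
  corrB <- ifelse(is.infinite(nB), 0, pB * (1 - pB) / (nB - 1))
  terms <- (pA - pB)^2 - corrA - corrB
  jk <- jackknifeTerms(terms, NULL, blocks, keep)
  newFStat(sprintf("f2(%s, %s)", A, B), jk, jk$nSnps)
}

#' @rdname f2Stat
#' @export
f3Stat <- function(freqs, C, A, B, blocks, inbreed = FALSE) {
  pC <- feP(freqs, C); pA <- feP(freqs, A); pB <- feP(freqs, B)
  nC <- feN(freqs, C)
  nEff <- if (inbreed) feInds(freqs, C) else nC
  keep <- !is.na(pC) & !is.na(pA) & !is.na(pB) & nEff >= 2
  if (!any(keep)) {
    stop(paste("f3 target has < 2 chromosomes everywhere; use inbreed = TRUE",
               "with >= 2 individuals, or an outgroup-rooted statistic"))
  }
  corr <- ifelse(is.infinite(nEff), 0, pC * (1 - pC) / (nEff - 1))
  terms <- (pC - pA) * (pC - pB) - corr
  jk <- jackknifeTerms(terms, NULL, blocks, keep)
  newFStat(sprintf("f3(%s; %s, %s)", C, A, B), jk, jk$nSnps)
}

#' @rdname f2Stat
#' @export
f4Stat <- function(freqs, W, X, Y, Z, blocks) {
  pW <- feP(freqs, W); pX <- feP(freqs, X)
  pY <- feP(freqs, Y); pZ <- feP(freqs, Z)
  keep <- !is.na(pW) & !is.na(pX) & !is.na(pY) & !is.na(pZ)
  terms <- (pW - pX) * (pY - pZ)
  jk <- jackknifeTerms(terms, NULL, blocks, keep)
  newFStat(sprintf("f4(%s, %s; %s, %s)", W, X, Y, Z), jk, jk$nSnps)
}

#' @rdname f2Stat
#' @export
dStat <- function(freqs, W, X, Y, Z, blocks) {
  pW <- feP(freqs, W); pX <- feP(freqs, X)
  pY <- feP(freqs, Y); pZ <- feP(freqs, Z)
  keep <- !is.na(pW) & !is.na(pX) & !is.na(pY) & !is.na(pZ)
  num <- (pW - pX) * (pY - pZ)
  den <- (pW + pX - 2 * pW * pX) * (pY + pZ - 2 * pY * pZ)
  jk <- jackknifeTerms(num, den, blocks, keep)
  newFStat(sprintf("D(%s, %s; %s, %s)", W, X, Y, Z), jk, jk$nSnps)
}

#' f4-ratio estimate of an admixture proportion
#'
#' For a target M modeled as a mixture of an A-related and a B-related
#' source, with X a population on A's lineage (inside the A clade but not A
#' itself) and O an outgroup, the ancestry proportion from the A side is
#' \deqn{\alpha = f4(O, X; B, M) / f4(O, X; B, A),}
#' jackknifed as a ratio over blocks.  A denominator with |Z| < 3 makes the
#' ratio unreliable and triggers a warning.
#'
#' @inheritParams f2Stat
#' @param O outgroup; \code{X} population attached on A's lineage;
#'   \code{A},\code{B} source proxies; \code{M} admixed target.
#' @return An [FStat-class] whose estimate is \eqn{\alpha}.
#' @export
f4Ratio <- function(freqs, O, X, A, B, M, blocks) {
  pO <- feP(freqs, O); pX <- feP(freqs, X); pA <- feP(freqs, A)
  pB <- feP(freqs, B); pM <- feP(freqs, M)
  keep <- !is.na(pO) & !is.na(pX) & !is.na(pA) & !is.na(pB) & !is.na(pM)
  num <- (pO - pX) * (pB - pM)
  den <- (pO - pX) * (pB - pA)
  denStat <- f4Stat(freqs, O, X, B, A, blocks)
  if (!is.na(denStat@z) && abs(denStat@z) < 3) {
    warning("f4-ratio denominator not significant (|Z| < 3); estimate unreliable")
  }
  jk <- jackknifeTerms(num, den, blocks, keep)
  newFStat(sprintf("f4ratio(%s, %s; %s, %s; %s)", O, X, A, B, M),
           jk, jk$nSnps)
}
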