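## Runs-of-homozygosity detection and length-bin summaries.

#' Default ROH detection parameters
#'
#' Sliding-window settings in the PLINK tradition: 50-SNP windows tolerating
#' one heterozygote, runs kept when supported by at least 25 SNPs and 500 kb,
#' split at inter-SNP gaps above 100 kb.  The 1.6 Mb short/long boundary and
#' the 4 Mb consanguinity boundary are the conventional reporting cut-offs.
#'
#' @param windowSnps window size in SNPs.
#' @param maxHetPerWindow heterozygote tolerance per window.
#' @param minSnps minimum SNPs supporting a reported run.
#' @param minLength minimum run length in bp.
#' @param maxGap maximum inter-SNP gap in bp before a run is split.
#' @param shortLongBoundary short/long reporting boundary in bp.
#' @param consanguinityBoundary boundary above which runs suggest recent
#'   consanguinity, in bp.
#' @return list of parameters for [detectRoh()].
#' @export
rohParams <- function(windowSnps = 50, maxHetPerWindow = 1, minSnps = 25,
                      minLength = 5e5, maxGap = 1e5,
                      shortLongBoundary = 1.6e6,
                      consanguinityBoundary = 4e6) {
  stopifnot(windowSnps > 0, maxHetPerWindow >= 0, minSnps > 0,
            minLength > 0, maxGap > 0,
            minLength <= shortLongBoundary,
            shortLongBoundary <= consanguinityBoundary)
  list(windowSnps = windowSnps, maxHetPerWindow = maxHetPerWindow,
       minSnps = minSnps, minLength = minLength, maxGap = maxGap,
       shortLongBoundary = shortLongBoundary,
       consanguinityBoundary = consanguinityBoundary)
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan per diploid sample and chromosome: every window of
#' \code{windowSnps} consecutive SNPs with at most \code{maxHetPerWindow}
#' heterozygotes is a homozygous window; a SNP is "in a run" when more than
#' 5\% of the windows covering it are homozygous.  Maximal in-run stretches
#' are split at inter-SNP gaps above \code{maxGap} and reported when they
#' reach \code{minSnps} SNPs and \code{minLength} bp.  Deterministic.
#'
#' @param panel a diploid [GenoPanel-class].
#' @param params parameter list from [rohParams()].
#' @return data.frame with columns \code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{nSnps}, \code{length}.
#' @export
detectRoh <- function(panel, params = rohParams()) {
  smp <- sampleTable(panel)
  if (any(smp$ploidy != "diploid")) {
    stop("ROH detection requires diploid samples (impute or exclude pseudo-haploid calls)")
  }
  snp <- snpTable(panel)
  D <- dosage(panel)
  W <- params$windowSnps
  out <- list()
  for (s in seq_len(ncol(D))) {
    for (ch in unique(snp$chrom)) {
      i <- which(snp$chrom == ch)
      m <- length(i)
      if (m < W) next
      het <- as.integer(!is.na(D[i, s]) & D[i, s] == 1)
      cs <- c(0, cumsum(het))
      nWin <- m - W + 1
      winHet <- cs[(W + 1):(m + 1)] - cs[1:nWin]
      winOk <- as.integer(winHet <= params$maxHetPerWindow)
      # windows covering SNP j: max(1, j - W + 1) .. min(j, nWin)
      cso <- c(0, cumsum(winOk))
      j <- seq_len(m)
      lo <- pmax(1L, j - W + 1L)
      hi <- pmin(j, nWin)
      nCover <- hi - lo + 1L
      nOk <- cso[hi + 1L] - cso[lo]
      inRun <- nCover > 0 & (nOk / nCover) > 0.05
      if (!any(inRun)) next
      pos <- snp$position[i]
      r <- rle(inRun)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        # split at large physical gaps
        gaps <- diff(pos[idx])
        cut <- which(gaps > params$maxGap)
        segStarts <- c(idx[1], idx[cut + 1])
        segEnds <- c(idx[cut], idx[length(idx)])
        for (q in seq_along(segStarts)) {
          ii <- segStarts[q]:segEnds[q]
          len <- pos[ii[length(ii)]] - pos[ii[1]] + 1L
          if (length(ii) >= params$minSnps && len >= params$minLength) {
            out[[length(out) + 1L]] <- data.frame(
              sample = smp$sampleId[s], chrom = ch,
              start = pos[ii[1]], end = pos[ii[length(ii)]],
              nSnps = length(ii), length = len)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      nSnps = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

#' Summarize ROH by length bin
#'
#' Totals run lengths per sample in half-open length bins \code{[lo, hi)},
#' plus the conventional short (< boundary) versus long (>= boundary) totals
#' used to separate small ancestral population size from recent
#' consanguinity.
#'
#' @param intervals data.frame from [detectRoh()].
#' @param bins sorted bin boundaries in bp (first bin starts at the first
#'   value; use \code{Inf} to close the last).
#' @param shortLongBoundary boundary in bp (default 1.6 Mb).
#' @return list with \code{perBin} (sample, bin, totalLength) and
#'   \code{shortLong} (sample, shortTotal, longTotal, boundary).
#' @export
rohSummary <- function(intervals,
                       bins = c(0, 1e6, 1.6e6, 2e6, 4e6, 8e6, Inf),
                       shortLongBoundary = 1.6e6) {
  stopifnot(!is.unsorted(bins, strictly = TRUE))
  labels <- sprintf("[%s,%s)", format(bins[-length(bins)], scientific = FALSE,
                                      trim = TRUE),
                    format(bins[-1], scientific = FALSE, trim = TRUE))
  samples <- unique(intervals$sample)
  perBin <- expand.grid(sample = samples, bin = labels,
                        stringsAsFactors = FALSE)
  perBin$totalLength <- rep(0, nrow(perBin))
  shortLong <- data.frame(sample = samples,
                          shortTotal = rep(0, length(samples)),
                          longTotal = rep(0, length(samples)),
                          boundary = rep(shortLongBoundary, length(samples)))
  if (nrow(intervals)) {
    binOf <- labels[findInterval(intervals$length, bins,
                                 rightmost.closed = FALSE)]
    agg <- stats::aggregate(length ~ sample + bin,
                            data = data.frame(sample = intervals$sample,
                                              bin = binOf,
                                              length = intervals$length),
                            FUN = sum)
    i <- match(paste(agg$sample, agg$bin), paste(perBin$sample, perBin$bin))
    perBin$totalLength[i] <- agg$length
    for (s in samples) {
      li <- intervals$length[intervals$sample == s]
      shortLong$shortTotal[shortLong$sample == s] <-
        sum(li[li < shortLongBoundary])
      shortLong$longTotal[shortLong$sample == s] <-
        sum(li[li >= shortLongBoundary])
    }
  }
  list(perBin = perBin, shortLong = shortLong)
}
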