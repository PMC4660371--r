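## Pseudo-haploid calling, molecular sexing, panel merging, LD pruning and
## jackknife block assignment.

#' Call pseudo-haploid genotypes from a base-count pileup
#'
#' At each SNP covered by at least one read, sites showing any base outside
#' the SNP's two panel alleles are discarded (the triallelic rule); otherwise
#' one allele is drawn with probability equal to its frequency among the
#' observed bases and duplicated to a homozygous dosage (2 copies of allele1,
#' or 0).  Zero-depth SNPs are missing.
#'
#' @param pileup pileup data.frame (see [simulatePileup()]); its SNP ids must
#'   be a subset of \code{snp$snpId}.
#' @param snp SNP table the call is aligned to.
#' @param seed integer seed for the random allele draws.
#' @param sampleId,population,sex annotation for the resulting sample.
#' @return A one-sample pseudo-haploid [GenoPanel-class] over all SNPs in
#'   \code{snp}.
#' @export
pseudoHaploidCall <- function(pileup, snp, seed = NULL,
                              sampleId = "ancient1", population = "ancient",
                              sex = "U") {
  if (!is.null(seed)) set.seed(seed)
  if (!all(pileup$snpId %in% snp$snpId)) {
    stop("pileup contains SNPs absent from the SNP table")
  }
  n <- nrow(snp)
  dos <- rep(NA_integer_, n)
  i <- match(pileup$snpId, snp$snpId)
  cnt <- as.matrix(pileup[, c("countA", "countC", "countG", "countT")])
  colnames(cnt) <- c("A", "C", "G", "T")
  a1 <- snp$allele1[i]
  a2 <- snp$allele2[i]
  c1 <- cnt[cbind(seq_len(nrow(cnt)), match(a1, colnames(cnt)))]
  c2 <- cnt[cbind(seq_len(nrow(cnt)), match(a2, colnames(cnt)))]
  total <- rowSums(cnt)
  clean <- (c1 + c2) == total & total > 0   # no off-panel base observed
  pick1 <- rep(NA, length(i))
  pick1[clean] <- runif(sum(clean)) < c1[clean] / total[clean]
  dos[i[clean]] <- ifelse(pick1[clean], 2L, 0L)
  samples <- data.frame(sampleId = sampleId, population = population,
                        ploidy = "pseudohaploid", sex = sex)
  GenoPanel(matrix(dos, ncol = 1), snp, samples)
}

#' Determine molecular sex from sex-chromosome read counts
#'
#' Computes the ratio \eqn{R_y = n_Y / (n_X + n_Y)} of reads aligning to the
#' Y chromosome over reads aligning to either sex chromosome, with a
#' normal-approximation 95\% confidence interval.  The sample is called XX
#' when the interval lies entirely below \code{xxMax} and XY when entirely
#' above \code{xyMin}; otherwise the call is indeterminate.
#'
#' @param nY,nX read counts on Y and on X.
#' @param xxMax,xyMin calling thresholds on \eqn{R_y} (defaults 0.016 and
#'   0.075, from the standard shotgun-sexing method).
#' @return list with fields \code{nY}, \code{nXY}, \code{Ry}, \code{ci95}
#'   (length-2 vector) and \code{call} ("XX", "XY" or "indeterminate").
#' @examples
#' determineSex(nY = 0, nX = 10000)$call   # "XX"
#' @export
determineSex <- function(nY, nX, xxMax = 0.016, xyMin = 0.075) {
  n <- nX + nY
  if (n <= 0) stop("total sex-chromosome read count must be positive")
  ry <- nY / n
  se <- sqrt(ry * (1 - ry) / n)
  ci <- pmin(pmax(ry + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  call <- if (ci[2] < xxMax) "XX" else if (ci[1] > xyMin) "XY" else
    "indeterminate"
  structure(list(nY = nY, nXY = n, Ry = ry, ci95 = ci, call = call),
            class = "SexCall")
}

#' @export
print.SexCall <- function(x, ...) {
  cat(sprintf("Ry = %.4f (95%% CI %.4f-%.4f), %d/%d Y reads -> %s\n",
              x$Ry, x$ci95[1], x$ci95[2], x$nY, x$nXY, x$call))
  invisible(x)
}

isAutosome <- function(chrom) {
  !(toupper(chrom) %in% c("X", "Y", "XY", "MT", "M", "23", "24", "90", "91"))
}

#' Merge an ancient panel into a modern reference panel
#'
#' Intersects SNPs by id, then applies the standard ancient-merge filters:
#' non-autosomal SNPs are dropped; modern populations with fewer than
#' \code{minPopSize} individuals are removed; SNPs with a minor allele
#' frequency of zero across the retained modern samples are dropped; and SNPs
#' whose ancient alleles are not both found among the modern panel alleles are
#' dropped rather than strand-flipped (A/T and C/G pairs are undecidable).
#' Ancient dosages are recoded when their allele pair is listed in swapped
#' order.
#'
#' @param ancient,modern [GenoPanel-class] objects sharing SNP identifiers.
#' @param minPopSize minimum modern population size (default 4).
#' @return list with \code{panel} (merged [GenoPanel-class], modern samples
#'   first) and \code{report} (data.frame of per-filter removal counts).
#' @export
mergePanels <- function(ancient, modern, minPopSize = 4) {
  msnp <- snpTable(modern)
  asnp <- snpTable(ancient)
  shared <- intersect(msnp$snpId, asnp$snpId)
  if (length(shared) == 0) stop("no overlapping SNPs between panels")
  report <- data.frame(filter = character(0), removed = integer(0))
  note <- function(f, k) {
    report <<- rbind(report, data.frame(filter = f, removed = k))
  }
  note("snp_not_shared",
       (nrow(msnp) - length(shared)) + (nrow(asnp) - length(shared)))
  keep <- msnp$snpId[msnp$snpId %in% shared]   # modern order

  aut <- isAutosome(msnp$chrom[match(keep, msnp$snpId)])
  note("non_autosomal", sum(!aut))
  keep <- keep[aut]

  msmp <- sampleTable(modern)
  popN <- table(msmp$population)
  smallPops <- names(popN)[popN < minPopSize]
  keepSamp <- !(msmp$population %in% smallPops)
  note("modern_population_too_small", length(smallPops))
  if (!any(keepSamp)) stop("no modern populations of sufficient size")

  mdos <- dosage(modern)[match(keep, msnp$snpId), keepSamp, drop = FALSE]
  mw <- ifelse(msmp$ploidy[keepSamp] == "diploid", 1, 0.5)
  W <- matrix(mw, nrow(mdos), ncol(mdos), byrow = TRUE)
  a <- rowSums(mdos * W, na.rm = TRUE)
  nchr <- rowSums((!is.na(mdos)) * 2 * W)
  p <- a / nchr
  poly <- !is.na(p) & p > 0 & p < 1
  note("modern_maf_zero", sum(!poly))
  keep <- keep[poly]

  im <- match(keep, msnp$snpId)
  ia <- match(keep, asnp$snpId)
  same <- asnp$allele1[ia] == msnp$allele1[im] &
    asnp$allele2[ia] == msnp$allele2[im]
  swap <- asnp$allele1[ia] == msnp$allele2[im] &
    asnp$allele2[ia] == msnp$allele1[im]
  ok <- same | swap
  note("allele_mismatch", sum(!ok))
  keep <- keep[ok]
  im <- im[ok]
  ia <- ia[ok]
  swap <- swap[ok]

  ados <- dosage(ancient)[ia, , drop = FALSE]
  ados[swap, ] <- 2L - ados[swap, , drop = FALSE]
  mdos <- dosage(modern)[im, keepSamp, drop = FALSE]
  snp <- msnp[im, , drop = FALSE]
  samples <- rbind(msmp[keepSamp, , drop = FALSE], sampleTable(ancient))
  panel <- GenoPanel(cbind(mdos, ados), snp, samples)
  list(panel = panel, report = report)
}

#' LD-pruning parameter profiles
#'
#' \code{"pca"}: 200-SNP window, step 25, r-squared threshold 0.2 (the
#' pruning used ahead of principal component analysis);
#' \code{"admixture"}: 200/25/0.5 (the \code{--indep-pairwise 200 25 0.5}
#' profile used ahead of model-based clustering).
#'
#' @param name profile name.
#' @return list with \code{window}, \code{step}, \code{r2Threshold}.
#' @export
pruneProfile <- function(name = c("admixture", "pca")) {
  name <- match.arg(name)
  switch(name,
         admixture = list(window = 200, step = 25, r2Threshold = 0.5),
         pca = list(window = 200, step = 25, r2Threshold = 0.2))
}

#' Prune SNPs in linkage disequilibrium
#'
#' Sliding-window pairwise pruning: within each window of \code{window} SNPs
#' (advanced by \code{step}, restarting at each chromosome), while any pair of
#' surviving SNPs has squared Pearson correlation of dosages above
#' \code{r2Threshold} (pairwise-complete samples), the member of the worst
#' pair with the lower minor allele frequency is removed (ties broken towards
#' the later position).  Deterministic and invariant to sample order.
#'
#' @param panel a [GenoPanel-class].
#' @param window,step,r2Threshold pruning parameters; see [pruneProfile()].
#' @param profile optional profile name overriding the three parameters.
#' @return Sorted character vector of retained SNP ids (panel order).
#' @export
ldPrune <- function(panel, window = 200, step = 25, r2Threshold = 0.5,
                    profile = NULL) {
  if (!is.null(profile)) {
    p <- pruneProfile(profile)
    window <- p$window; step <- p$step; r2Threshold <- p$r2Threshold
  }
  stopifnot(window > step, step > 0, r2Threshold > 0, r2Threshold <= 1)
  snp <- snpTable(panel)
  d <- dosage(panel)
  nmiss <- rowSums(!is.na(d))
  pbar <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(pbar, 1 - pbar)
  maf[nmiss == 0] <- -1   # all-missing SNPs sort last, flagged below
  if (any(nmiss == 0)) {
    warning(sprintf("%d SNP(s) with no data treated as uncorrelated",
                    sum(nmiss == 0)))
  }
  alive <- rep(TRUE, nrow(snp))
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch)
    m <- length(idx)
    starts <- if (m <= window) 1L else
      unique(c(seq(1L, m - window, by = step), m - window + 1L))
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, m)]
      win <- win[alive[win]]
      if (length(win) < 2) next
      R <- suppressWarnings(
        cor(d[win, , drop = FALSE] |> t(), use = "pairwise.complete.obs"))
      R2 <- R^2
      R2[is.na(R2)] <- 0
      diag(R2) <- 0
      live <- rep(TRUE, length(win))
      repeat {
        R2w <- R2
        R2w[!live, ] <- 0
        R2w[, !live] <- 0
        mx <- max(R2w)
        if (mx <= r2Threshold) break
        pair <- which(R2w == mx, arr.ind = TRUE)[1, ]
        i1 <- win[pair[1]]; i2 <- win[pair[2]]
        drop <- if (maf[i1] < maf[i2]) pair[1]
                else if (maf[i2] < maf[i1]) pair[2]
                else if (snp$position[i1] >= snp$position[i2]) pair[1]
                else pair[2]
        live[drop] <- FALSE
      }
      alive[win[!live]] <- FALSE
    }
  }
  snp$snpId[alive]
}

#' Assign SNPs to genetic-distance jackknife blocks
#'
#' Blocks are half-open windows \eqn{[k b, (k+1) b)} centimorgans restarting
#' at each chromosome (default block size 5 cM, the standard for f-statistic
#' jackknifing).
#'
#' @param snp SNP table with \code{chrom} and \code{geneticPos} (cM).
#' @param blockCm block size in cM.
#' @return Character vector of block ids, one per SNP.
#' @export
assignBlocks <- function(snp, blockCm = 5.0) {
  if (is.null(snp$geneticPos) || anyNA(snp$geneticPos)) {
    stop("genetic positions are required for block assignment")
  }
  stopifnot(blockCm > 0)
  paste0(snp$chrom, ":", floor(snp$geneticPos / blockCm))
}
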