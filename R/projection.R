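## PCA on modern diploids with least-squares projection of incomplete
## (ancient) samples.

#' Fit principal components on a modern diploid panel
#'
#' Each SNP is centered by its mean dosage \eqn{\mu} and scaled by
#' \eqn{\sqrt{p(1-p)}} with \eqn{p = \mu/2}; missing dosages contribute 0
#' after centering.  Components are the eigenvectors of the sample covariance
#' of the standardized matrix; no outlier-removal iterations are performed.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so plots are reproducible across runs.
#'
#' @param panel a [GenoPanel-class]; all samples must be diploid and all SNPs
#'   polymorphic in the panel.
#' @param nComponents number of components to retain.
#' @return A [PcaModel-class].
#' @export
pcaFit <- function(panel, nComponents = 2) {
  smp <- sampleTable(panel)
  if (!all(smp$ploidy == "diploid")) {
    stop("PCA reference samples must be diploid; project the others instead")
  }
  D <- dosage(panel)
  mu <- rowMeans(D, na.rm = TRUE)
  p <- mu / 2
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("monomorphic or all-missing SNPs in the PCA panel; filter first")
  }
  sc <- sqrt(p * (1 - p))
  X <- (D - mu) / sc
  X[is.na(X)] <- 0
  X <- t(X)                        # samples x SNPs
  n <- nrow(X)
  k <- min(nComponents, n - 1, ncol(X))
  if (k < 1) stop("need at least two samples")
  sv <- svd(X)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    mx <- max(abs(v))
    if (mx == 0) return(1)
    # sign anchored on the first loading of near-maximal magnitude; exact
    # argmax ties between opposite-signed loadings would otherwise make the
    # orientation depend on summation order
    sign(v[which(abs(v) >= 0.5 * mx)[1]])
  }, 0)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  rownames(scores) <- smp$sampleId
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_len(k))
  new("PcaModel",
      center = mu, scale = sc, loadings = loadings,
      eigenvalues = sv$d[seq_len(k)]^2 / (n - 1),
      varianceExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
      scores = scores, snpId = snpTable(panel)$snpId,
      sampleId = smp$sampleId)
}

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d SNPs, %d samples, %d components\n",
              length(object@snpId), length(object@sampleId),
              ncol(object@loadings)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained),
            collapse = ", "), "\n")
})

#' Project a (possibly incomplete) sample onto fitted components
#'
#' Solves the least-squares problem for the component scores using only the
#' sample's non-missing SNPs, standardized with the model's centering and
#' scale.  With complete data this equals the ordinary PCA score exactly; for
#' ancient samples with missing genotypes it is the standard
#' \code{lsqproject}-style placement.
#'
#' @param x either a dosage vector aligned with the model's SNPs (NA =
#'   missing) or a [GenoPanel-class] whose samples are each projected.
#' @param model a [PcaModel-class].
#' @return A score vector (or a samples x components matrix for a panel).
#' @export
lsqProject <- function(x, model) {
  if (is(x, "GenoPanel")) {
    idx <- match(model@snpId, snpTable(x)$snpId)
    if (anyNA(idx)) stop("panel lacks SNPs present in the PCA model")
    D <- dosage(x)[idx, , drop = FALSE]
    out <- t(apply(D, 2, lsqProject, model = model))
    colnames(out) <- colnames(model@loadings)
    return(out)
  }
  if (length(x) != length(model@snpId)) {
    stop("dosage vector length must match the model's SNPs")
  }
  obs <- !is.na(x)
  k <- ncol(model@loadings)
  if (sum(obs) < k) stop("too few non-missing SNPs to project")
  z <- (x[obs] - model@center[obs]) / model@scale[obs]
  L <- model@loadings[obs, , drop = FALSE]
  g <- crossprod(L)
  if (rcond(g) < 1e-12) stop("ill-conditioned projection (too much missingness)")
  drop(solve(g, crossprod(L, z)))
}
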