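#' @import methods
#' @importFrom stats rbeta rbinom rpois runif optim pchisq qnorm setNames cor
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom utils read.table write.table
NULL

#' Population demography with drift and admixture
#'
#' A rooted population graph: tree edges carry either a dimensionless drift
#' amount \eqn{d \in [0,1)} or a duration in years (converted to drift through
#' the diploid effective size and generation time), and admixture events create
#' new populations as linear mixtures \eqn{\alpha p_A + (1-\alpha) p_B} of two
#' existing ones.  The model also records how each sampled population is
#' genotyped (number of diploid and of pseudo-haploid individuals) and the
#' distribution of the ancestral allele frequency at the root.
#'
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{drift}, \code{duration}; exactly one of \code{drift}/\code{duration}
#'   is non-\code{NA} per row.
#' @slot admixture data.frame with columns \code{target}, \code{sourceA},
#'   \code{sourceB}, \code{alpha} (ancestry fraction from \code{sourceA}).
#' @slot Ne diploid effective population size used for time-to-drift
#'   conversion.
#' @slot genTime generation time in years.
#' @slot ancestralFreq list describing the root frequency distribution;
#'   either \code{list(dist="uniform", min=, max=)} or
#'   \code{list(dist="beta", shape1=, shape2=)}.
#' @slot sampling data.frame with columns \code{population}, \code{nDiploid},
#'   \code{nPseudo}.
#'
#' @seealso [DemographyModel()], [buildPreset()], [expectedFMoments()],
#'   [simulateFrequencies()]
#' @exportClass DemographyModel
setClass("DemographyModel",
  representation(
    edges = "data.frame",
    admixture = "data.frame",
    Ne = "numeric",
    genTime = "numeric",
    ancestralFreq = "list",
    sampling = "data.frame"
  )
)

setValidity("DemographyModel", function(object) {
  ed <- object@edges
  ad <- object@admixture
  msgs <- character(0)
  need <- c("parent", "child", "drift", "duration")
  if (!all(need %in% names(ed))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(ed) > 0) {
    one <- xor(is.na(ed$drift), is.na(ed$duration))
    if (!all(one)) {
      msgs <- c(msgs, "each edge needs exactly one of drift or duration")
    }
    dr <- ed$drift[!is.na(ed$drift)]
    if (any(dr < 0 | dr >= 1)) msgs <- c(msgs, "drift must lie in [0,1)")
    du <- ed$duration[!is.na(ed$duration)]
    if (any(du < 0)) msgs <- c(msgs, "durations must be non-negative")
    if (anyDuplicated(ed$child)) {
      msgs <- c(msgs, "a node may have at most one parent edge")
    }
  }
  if (nrow(ad) > 0) {
    if (any(ad$alpha < 0 | ad$alpha > 1)) {
      msgs <- c(msgs, "admixture alpha must lie in [0,1]")
    }
    if (any(ad$target %in% ed$child)) {
      msgs <- c(msgs, "admixture targets cannot also have a parent edge")
    }
    if (anyDuplicated(ad$target)) {
      msgs <- c(msgs, "duplicated admixture target")
    }
  }
  if (length(object@Ne) != 1L || object@Ne <= 0) {
    msgs <- c(msgs, "Ne must be a single positive number")
  }
  if (length(object@genTime) != 1L || object@genTime <= 0) {
    msgs <- c(msgs, "genTime must be a single positive number")
  }
  # single root, acyclic: topoSortModel() throws on failure
  res <- tryCatch({
    topoSortModel(ed, ad)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) msgs <- c(msgs, res)
  sp <- object@sampling
  if (nrow(sp) > 0) {
    nodes <- unique(c(ed$parent, ed$child, ad$target))
    if (!all(sp$population %in% nodes)) {
      msgs <- c(msgs, "sampling spec names unknown populations")
    }
    if (anyDuplicated(sp$population)) {
      msgs <- c(msgs, "duplicated population in sampling spec")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Exact first and second moments of population allele frequencies
#'
#' Holds \eqn{E[p_X]} and \eqn{E[p_X p_Y]} for every population of a
#' [DemographyModel-class], from which expected f-statistics follow as
#' linear combinations.
#'
#' @slot pops population identifiers.
#' @slot m1 named numeric vector of first moments \eqn{E[p_X]}.
#' @slot m2 symmetric matrix of second moments \eqn{E[p_X p_Y]}.
#' @seealso [expectedFMoments()], [expectedF2()], [expectedF3()],
#'   [expectedF4()]
#' @exportClass MomentTable
setClass("MomentTable",
  representation(pops = "character", m1 = "numeric", m2 = "matrix")
)

setValidity("MomentTable", function(object) {
  m1 <- object@m1
  m2 <- object@m2
  tol <- 1e-8
  if (!identical(names(m1), object@pops)) return("m1 names must match pops")
  if (!identical(rownames(m2), object@pops)) return("m2 dimnames must match pops")
  if (max(abs(m2 - t(m2))) > tol) return("m2 must be symmetric")
  if (any(m1 < -tol | m1 > 1 + tol)) return("first moments must lie in [0,1]")
  if (any(m2 < -tol | m2 > 1 + tol)) return("second moments must lie in [0,1]")
  v <- diag(m2) - m1^2
  if (any(v < -1e-6)) return("E[p^2] must be >= E[p]^2")
  TRUE
})

#' Genotype panel with SNP and sample annotation
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"dosage"}
#' counts copies of \code{allele1} per sample (0/1/2, \code{NA} missing), rows
#' are SNPs and columns samples.  Row metadata carries \code{snpId},
#' \code{chrom}, \code{position} (bp), \code{geneticPos} (cM), \code{allele1},
#' \code{allele2}; column metadata carries \code{sampleId}, \code{sex},
#' \code{population} and \code{ploidy} (\code{"diploid"} or
#' \code{"pseudohaploid"}).  Pseudo-haploid samples hold one sampled allele
#' duplicated to a homozygote, so dosage 1 never occurs in their columns.
#'
#' @seealso [GenoPanel()], [dosage()], [snpTable()], [sampleTable()],
#'   [readEigenstrat()]
#' @exportClass GenoPanel
setClass("GenoPanel", contains = "SummarizedExperiment")

setValidity("GenoPanel", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'dosage' is required")
  }
  d <- SummarizedExperiment::assay(object, "dosage")
  bad <- !(d %in% c(0, 1, 2)) & !is.na(d)
  if (any(bad)) return("dosage values must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  needR <- c("snpId", "chrom", "position", "geneticPos", "allele1", "allele2")
  if (!all(needR %in% names(rd))) {
    return(paste("rowData must have columns", paste(needR, collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  needC <- c("sampleId", "population", "ploidy")
  if (!all(needC %in% names(cd))) {
    return(paste("colData must have columns", paste(needC, collapse = ", ")))
  }
  if (!all(cd$ploidy %in% c("diploid", "pseudohaploid"))) {
    return("ploidy must be 'diploid' or 'pseudohaploid'")
  }
  ph <- cd$ploidy == "pseudohaploid"
  if (any(ph) && any(d[, ph, drop = FALSE] == 1, na.rm = TRUE)) {
    return("pseudo-haploid samples cannot carry dosage 1")
  }
  # positions sorted within chromosome, genetic positions non-decreasing
  for (ch in unique(rd$chrom)) {
    i <- rd$chrom == ch
    if (is.unsorted(rd$position[i], strictly = FALSE)) {
      return(sprintf("positions not sorted on chromosome %s", ch))
    }
    if (is.unsorted(rd$geneticPos[i])) {
      return(sprintf("genetic positions not sorted on chromosome %s", ch))
    }
  }
  TRUE
})

#' Per-population allele counts and frequencies
#'
#' For each (population, SNP) pair: the allele1 chromosome count \eqn{a}, the
#' total observed chromosome count \eqn{n}, and \eqn{\hat p = a/n}.  Diploid
#' samples contribute their dosage out of 2 chromosomes; pseudo-haploid
#' samples contribute the single sampled allele out of 1 chromosome, since the
#' duplicated homozygote contains no extra information.  Entries with
#' \eqn{n = \infty} denote known (noise-free) frequencies, for which all
#' small-sample corrections vanish.
#'
#' @slot counts SNP x population matrix of allele1 chromosome counts.
#' @slot chroms SNP x population matrix of observed chromosome counts.
#' @slot snpId SNP identifiers (rownames of the matrices).
#' @seealso [popFrequencies()], [freqEstimateFromFrequencies()]
#' @exportClass FreqEstimate
setClass("FreqEstimate",
  representation(counts = "matrix", chroms = "matrix", snpId = "character")
)

setValidity("FreqEstimate", function(object) {
  if (!identical(dim(object@counts), dim(object@chroms))) {
    return("counts and chroms must have the same dimensions")
  }
  if (any(object@counts < 0, na.rm = TRUE)) return("counts must be >= 0")
  if (any(object@counts > object@chroms, na.rm = TRUE)) {
    return("counts cannot exceed chromosome totals")
  }
  if (nrow(object@counts) != length(object@snpId)) {
    return("snpId length must match rows")
  }
  TRUE
})

#' f-statistic with block-jackknife uncertainty
#'
#' Point estimate of an f- or D-statistic together with its weighted
#' block-jackknife standard error and Z-score, the number of SNPs entering the
#' statistic and the number of jackknife blocks.  A statistic is conventionally
#' called significant when |Z| > 3.
#'
#' @slot label human-readable statistic label, e.g. \code{"f3(O; A, B)"}.
#' @slot estimate point estimate over all blocks.
#' @slot se weighted block-jackknife standard error (NA with < 2 blocks).
#' @slot z estimate / se.
#' @slot nSnps number of SNPs used.
#' @slot nBlocks number of non-empty jackknife blocks.
#' @seealso [f2Stat()], [f3Stat()], [f4Stat()], [dStat()], [blockJackknife()]
#' @exportClass FStat
setClass("FStat",
  representation(
    label = "character", estimate = "numeric", se = "numeric",
    z = "numeric", nSnps = "numeric", nBlocks = "numeric"
  )
)

#' Principal components model of a modern reference panel
#'
#' Fitted on diploid reference samples: per-SNP centering means and
#' \eqn{\sqrt{p(1-p)}} scale factors, orthonormal SNP loadings, eigenvalues of
#' the sample covariance and the fraction of total variance each component
#' explains, plus the scores of the fitting samples.  Ancient or incomplete
#' samples are placed on these axes by least squares over their observed SNPs
#' ([lsqProject()]).
#'
#' @slot center per-SNP mean dosage.
#' @slot scale per-SNP standard-deviation proxy \eqn{\sqrt{p(1-p)}}, p = mean/2.
#' @slot loadings SNP x component orthonormal loadings.
#' @slot eigenvalues covariance eigenvalues, non-increasing.
#' @slot varianceExplained fraction of total variance per component.
#' @slot scores fitting-sample scores (sample x component).
#' @slot snpId,sampleId identifiers aligned with loadings rows / scores rows.
#' @seealso [pcaFit()], [lsqProject()]
#' @exportClass PcaModel
setClass("PcaModel",
  representation(
    center = "numeric", scale = "numeric", loadings = "matrix",
    eigenvalues = "numeric", varianceExplained = "numeric",
    scores = "matrix", snpId = "character", sampleId = "character"
  )
)

setValidity("PcaModel", function(object) {
  k <- ncol(object@loadings)
  if (k > 0) {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(k))) > 1e-6) return("loadings must be orthonormal")
  }
  if (is.unsorted(rev(object@eigenvalues))) {
    return("eigenvalues must be non-increasing")
  }
  if (sum(object@varianceExplained) > 1 + 1e-8) {
    return("variance fractions must sum to <= 1")
  }
  TRUE
})
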