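## GenoPanel construction and accessors.

#' Construct a genotype panel
#'
#' @param dosage SNP x sample matrix of allele1 dosages (0/1/2, NA missing).
#' @param snp data.frame with columns \code{snpId}, \code{chrom},
#'   \code{position}, \code{geneticPos}, \code{allele1}, \code{allele2},
#'   one row per dosage row, sorted by (chrom, position).
#' @param samples data.frame with columns \code{sampleId}, \code{population},
#'   \code{ploidy} and optionally \code{sex}, one row per dosage column.
#' @return A [GenoPanel-class] object.
#' @examples
#' snp <- data.frame(snpId = c("s1", "s2"), chrom = "1",
#'                   position = c(100L, 200L), geneticPos = c(0.0001, 0.0002),
#'                   allele1 = "A", allele2 = "G")
#' smp <- data.frame(sampleId = "I1", population = "P", ploidy = "diploid")
#' gp <- GenoPanel(matrix(c(0, 1), 2, 1), snp, smp)
#' dosage(gp)
#' @export
GenoPanel <- function(dosage, snp, samples) {
  dosage <- as.matrix(dosage)
  snp <- as.data.frame(snp)
  samples <- as.data.frame(samples)
  if (is.null(samples$sex)) samples$sex <- "U"
  rownames(dosage) <- snp$snpId
  colnames(dosage) <- samples$sampleId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(snp),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sampleId)
  )
  new("GenoPanel", se)
}

#' @describeIn GenoPanel The dosage matrix (SNP x sample).
#' @param x a [GenoPanel-class].
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenoPanel SNP annotation as a data.frame.
#' @export
snpTable <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn GenoPanel Sample annotation as a data.frame.
#' @export
sampleTable <- function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  rownames(df) <- NULL
  df
}

#' @describeIn GenoPanel Per-sample ploidy mode, named by sample id.
#' @export
ploidyMode <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(cd$ploidy, cd$sampleId)
}

setMethod("show", "GenoPanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("GenoPanel: %d SNPs x %d samples (%d diploid, %d pseudo-haploid)\n",
              nrow(object), ncol(object),
              sum(cd$ploidy == "diploid"), sum(cd$ploidy == "pseudohaploid")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(rd$chrom), collapse = ", ")))
  cat(sprintf("  populations: %s\n",
              paste(unique(cd$population), collapse = ", ")))
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missingness: %.2f%%\n", 100 * mean(is.na(d))))
})

# Subset a panel to SNP ids (keeping order of the panel) or samples.
subsetPanel <- function(panel, snpIds = NULL, sampleIds = NULL) {
  i <- if (is.null(snpIds)) seq_len(nrow(panel)) else
    which(SummarizedExperiment::rowData(panel)$snpId %in% snpIds)
  j <- if (is.null(sampleIds)) seq_len(ncol(panel)) else
    which(SummarizedExperiment::colData(panel)$sampleId %in% sampleIds)
  panel[i, j]
}
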