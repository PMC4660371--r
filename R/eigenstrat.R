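## EIGENSTRAT geno/snp/ind reader and writer.

#' Read an EIGENSTRAT genotype triplet
#'
#' Expects \code{<prefix>.geno} (one line per SNP, one character per sample:
#' '0'/'1'/'2' copies of allele1, '9' missing), \code{<prefix>.snp}
#' (id, chromosome, genetic position in Morgans, physical position, allele1,
#' allele2) and \code{<prefix>.ind} (id, sex, population).  Genetic positions
#' are converted to centimorgans in the returned panel; a pseudo-haploid
#' sample is recognized by the absence of dosage 1 only when declared through
#' \code{pseudohaploid}.
#'
#' @param prefix path prefix of the triplet.
#' @param pseudohaploid character vector of sample ids (or population labels)
#'   to mark as pseudo-haploid.
#' @return A [GenoPanel-class].
#' @seealso [writeEigenstrat()]
#' @export
readEigenstrat <- function(prefix, pseudohaploid = character(0)) {
  genoFile <- paste0(prefix, ".geno")
  snpFile <- paste0(prefix, ".snp")
  indFile <- paste0(prefix, ".ind")
  for (f in c(genoFile, snpFile, indFile)) {
    if (!file.exists(f)) stop(sprintf("missing file: %s", f))
  }
  ind <- read.table(indFile, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sampleId", "sex", "population"))
  snp <- read.table(snpFile, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("snpId", "chrom", "geneticPos",
                                  "position", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  snp$geneticPos <- snp$geneticPos * 100  # Morgans -> cM
  lines <- readLines(genoFile)
  if (length(lines) != nrow(snp)) {
    stop(sprintf("geno has %d lines but snp lists %d SNPs",
                 length(lines), nrow(snp)))
  }
  nSamp <- nrow(ind)
  widths <- nchar(lines)
  if (any(widths != nSamp)) {
    bad <- which(widths != nSamp)[1]
    stop(sprintf("geno line %d has %d characters, expected %d",
                 bad, widths[bad], nSamp))
  }
  chars <- unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid genotype character '%s' at geno line %d",
                 chars[bad], (bad - 1) %/% nSamp + 1))
  }
  d <- as.integer(chars)
  d[d == 9L] <- NA_integer_
  dosage <- matrix(d, nrow = nrow(snp), ncol = nSamp, byrow = TRUE)
  ind$ploidy <- ifelse(ind$sampleId %in% pseudohaploid |
                         ind$population %in% pseudohaploid,
                       "pseudohaploid", "diploid")
  GenoPanel(dosage, snp, ind)
}

#' Write a panel as an EIGENSTRAT triplet
#'
#' Inverse of [readEigenstrat()]; genetic positions are written in Morgans.
#' Round-trips losslessly apart from the ploidy annotation, which EIGENSTRAT
#' does not carry.
#'
#' @param panel a [GenoPanel-class].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
writeEigenstrat <- function(panel, prefix) {
  snp <- snpTable(panel)
  smp <- sampleTable(panel)
  d <- dosage(panel)
  d[is.na(d)] <- 9L
  lines <- apply(d, 1, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snpOut <- data.frame(snp$snpId, snp$chrom,
                       format(snp$geneticPos / 100, scientific = FALSE,
                              trim = TRUE, digits = 10),
                       snp$position, snp$allele1, snp$allele2)
  write.table(snpOut, paste0(prefix, ".snp"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  write.table(data.frame(smp$sampleId, smp$sex, smp$population),
              paste0(prefix, ".ind"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}
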