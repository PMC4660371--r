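## Monte-Carlo generators: frequency drift, genotype sampling, pileups and
## autozygous-genome fixtures.

#' Simulate per-population allele frequencies by drift
#'
#' Draws the root frequency per SNP from the model's ancestral distribution
#' and propagates it down the graph with the Balding--Nichols transition
#' \eqn{p' \sim \mathrm{Beta}(p(1-d)/d,\ (1-p)(1-d)/d)} on each branch
#' (mean-preserving, variance \eqn{d\,p(1-p)}), with 0 and 1 absorbing and
#' \eqn{p' = p} when \eqn{d = 0}.  Admixed populations are the exact linear
#' mixture of their source frequencies.
#'
#' @param model a [DemographyModel-class].
#' @param nSnps number of independent SNPs.
#' @param seed integer seed (sets the RNG).
#' @return Numeric matrix, SNPs x populations (all graph nodes as columns).
#' @examples
#' m <- DemographyModel(
#'   edges = data.frame(parent = "R", child = c("A", "B"), drift = 0.02))
#' p <- simulateFrequencies(m, 1000, seed = 1)
#' colnames(p)
#' @export
simulateFrequencies <- function(model, nSnps, seed = NULL) {
  stopifnot(nSnps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ts <- topoSortModel(model@edges, model@admixture)
  drift <- effectiveDrift(model)
  if (any(drift >= 1)) stop("drift of 1 is degenerate (fixation certain)")
  P <- matrix(NA_real_, nSnps, length(ts$order),
              dimnames = list(NULL, ts$order))
  for (node in ts$order) {
    ev <- ts$events[[node]]
    if (ev$type == "root") {
      P[, node] <- drawAncestral(model@ancestralFreq, nSnps)
    } else if (ev$type == "edge") {
      p <- P[, model@edges$parent[ev$edge]]
      d <- drift[[node]]
      if (d == 0) {
        P[, node] <- p
      } else {
        q <- p
        inner <- p > 0 & p < 1
        s <- (1 - d) / d
        q[inner] <- rbeta(sum(inner), p[inner] * s, (1 - p[inner]) * s)
        P[, node] <- q
      }
    } else {
      a <- model@admixture[ev$admix, ]
      P[, node] <- a$alpha * P[, a$sourceA] + (1 - a$alpha) * P[, a$sourceB]
    }
  }
  P
}

#' Sample a genotype panel from population frequencies
#'
#' Diploid samples receive dosages \eqn{\sim \mathrm{Binomial}(2, p)};
#' pseudo-haploid samples receive a single Bernoulli(\eqn{p}) allele
#' duplicated to a homozygote (dosage 0 or 2), mimicking the random-allele
#' representation of low-coverage ancient genomes.  SNPs are placed uniformly
#' on \code{nChrom} chromosomes with a uniform genetic map so that
#' genetic-distance jackknife blocks exist.
#'
#' @param freqs SNPs x populations frequency matrix
#'   (from [simulateFrequencies()]).
#' @param model the generating [DemographyModel-class]; its sampling spec
#'   decides how many diploid/pseudo-haploid samples each population gets.
#' @param seed integer seed.
#' @param nChrom number of chromosomes to spread SNPs over (>= 2).
#' @param chromLengthBp chromosome length in bp.
#' @param cmPerMb uniform genetic map rate (centimorgan per megabase).
#' @return A [GenoPanel-class].
#' @export
sampleGenotypes <- function(freqs, model, seed = NULL, nChrom = 22,
                            chromLengthBp = 1e8, cmPerMb = 1) {
  if (!is.null(seed)) set.seed(seed)
  sp <- model@sampling
  if (nrow(sp) == 0) stop("model has no sampling spec")
  miss <- setdiff(sp$population, colnames(freqs))
  if (length(miss)) {
    stop(sprintf("frequency matrix lacks sampled population(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (nChrom < 2) stop("need at least 2 chromosomes for jackknife blocks")
  nSnps <- nrow(freqs)
  chrom <- sort(rep_len(seq_len(nChrom), nSnps))
  position <- integer(nSnps)
  for (ch in seq_len(nChrom)) {
    i <- chrom == ch
    position[i] <- sort(sample.int(chromLengthBp, sum(i)))
  }
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, nSnps, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1))
  snp <- data.frame(
    snpId = sprintf("snp%d", seq_len(nSnps)),
    chrom = as.character(chrom), position = position,
    geneticPos = position / 1e6 * cmPerMb,
    allele1 = a1, allele2 = unname(a2)
  )
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(sp))) {
    pop <- sp$population[i]
    p <- freqs[, pop]
    nd <- sp$nDiploid[i]
    np <- sp$nPseudo[i]
    if (nd > 0) {
      for (j in seq_len(nd)) {
        cols[[length(cols) + 1L]] <- rbinom(nSnps, 2, p)
        meta[[length(meta) + 1L]] <- data.frame(
          sampleId = sprintf("%s_d%d", pop, j), population = pop,
          ploidy = "diploid")
      }
    }
    if (np > 0) {
      for (j in seq_len(np)) {
        cols[[length(cols) + 1L]] <- 2L * rbinom(nSnps, 1, p)
        meta[[length(meta) + 1L]] <- data.frame(
          sampleId = sprintf("%s_p%d", pop, j), population = pop,
          ploidy = "pseudohaploid")
      }
    }
  }
  GenoPanel(do.call(cbind, cols), snp, do.call(rbind, meta))
}

#' Simulate a per-SNP base-count pileup for one individual
#'
#' Sequencing depth is Poisson(\code{coverage}); each read carries one of the
#' individual's two alleles and is mis-read as a uniformly chosen other base
#' with probability \code{errorRate}.  SNPs with zero depth are absent from
#' the output.  The individual's diploid genotype is either supplied or drawn
#' as Binomial(2, \code{freq}).
#'
#' @param snp SNP table (as in [GenoPanel()]): \code{snpId}, \code{chrom},
#'   \code{position}, \code{allele1}, \code{allele2}.
#' @param coverage mean sequencing depth (> 0).
#' @param errorRate per-base error probability in [0, 0.25).
#' @param seed integer seed.
#' @param freq per-SNP population frequency of allele1 (used to draw the
#'   genotype when \code{genotype} is NULL).
#' @param genotype optional explicit allele1 dosage vector (0/1/2).
#' @return data.frame with columns \code{snpId}, \code{chrom},
#'   \code{position}, \code{countA}, \code{countC}, \code{countG},
#'   \code{countT}; one row per SNP with depth >= 1.
#' @export
simulatePileup <- function(snp, coverage, errorRate, seed = NULL,
                           freq = NULL, genotype = NULL) {
  stopifnot(coverage > 0, errorRate >= 0, errorRate < 0.25)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(snp)
  if (is.null(genotype)) {
    if (is.null(freq)) stop("supply either freq or genotype")
    genotype <- rbinom(n, 2, freq)
  }
  stopifnot(length(genotype) == n)
  depth <- rpois(n, coverage)
  idx <- rep(seq_len(n), depth)
  nr <- length(idx)
  bases <- c("A", "C", "G", "T")
  trueA1 <- rbinom(nr, 1, genotype[idx] / 2) == 1
  base <- ifelse(trueA1, snp$allele1[idx], snp$allele2[idx])
  err <- runif(nr) < errorRate
  if (any(err)) {
    base[err] <- vapply(base[err],
                        function(b) sample(setdiff(bases, b), 1), character(1))
  }
  cnt <- unclass(table(factor(idx, levels = seq_len(n)),
                       factor(base, levels = bases)))
  keep <- depth > 0
  data.frame(
    snpId = snp$snpId[keep], chrom = snp$chrom[keep],
    position = snp$position[keep],
    countA = cnt[keep, "A"], countC = cnt[keep, "C"],
    countG = cnt[keep, "G"], countT = cnt[keep, "T"],
    row.names = NULL
  )
}

#' Read or write a pileup TSV
#'
#' Tab-delimited dialect: \code{snpId}, \code{chrom}, \code{position},
#' \code{countA}, \code{countC}, \code{countG}, \code{countT} with a header.
#'
#' @param pileup pileup data.frame (writer).
#' @param path file path.
#' @return \code{readPileup()} returns the pileup data.frame.
#' @export
readPileup <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "character", "integer",
                            "integer", "integer", "integer", "integer"))
}

#' @rdname readPileup
#' @export
writePileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a diploid genome with planted autozygous segments
#'
#' Generates SNPs at uniform density.  Outside planted segments a SNP is
#' heterozygous with probability \code{hetDensity / snpDensity}; inside a
#' planted segment heterozygotes occur only at \code{errorHetRate} (genotyping
#' error), emulating a run of autozygosity.
#'
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param hetDensity heterozygous sites per bp outside segments.
#' @param plantedSegments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, inclusive); segments must lie within their chromosome and
#'   not overlap.
#' @param errorHetRate per-SNP heterozygosity inside segments.
#' @param seed integer seed.
#' @param snpDensity SNPs per bp (default 1/1000).
#' @param sampleId,population sample annotation for the single genome.
#' @return A [GenoPanel-class] with one diploid sample.
#' @export
simulateRohGenome <- function(chromLengths, hetDensity, plantedSegments,
                              errorHetRate, seed = NULL, snpDensity = 1e-3,
                              sampleId = "ROH1", population = "ROHpop") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(chromLengths))) {
    names(chromLengths) <- as.character(seq_along(chromLengths))
  }
  seg <- as.data.frame(plantedSegments)
  if (nrow(seg)) {
    seg$chrom <- as.character(seg$chrom)
    if (!all(seg$chrom %in% names(chromLengths))) {
      stop("planted segment on unknown chromosome")
    }
    if (any(seg$start < 1) ||
        any(seg$end > chromLengths[seg$chrom]) ||
        any(seg$start > seg$end)) {
      stop("planted segments must lie within chromosome bounds")
    }
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("planted segments overlap")
      }
    }
  }
  hetP <- hetDensity / snpDensity
  if (hetP > 1) stop("hetDensity exceeds snpDensity")
  rows <- list()
  geno <- list()
  for (ch in names(chromLengths)) {
    len <- chromLengths[[ch]]
    n <- max(2L, round(len * snpDensity))
    pos <- sort(sample.int(len, n))
    inSeg <- rep(FALSE, n)
    s <- seg[seg$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(s))) {
      inSeg <- inSeg | (pos >= s$start[k] & pos <= s$end[k])
    }
    het <- runif(n) < ifelse(inSeg, errorHetRate, hetP)
    g <- ifelse(het, 1L, 2L * rbinom(n, 1, 0.5))
    rows[[ch]] <- data.frame(chrom = ch, position = pos)
    geno[[ch]] <- g
  }
  snp <- do.call(rbind, rows)
  snp <- data.frame(
    snpId = sprintf("rsnp%d", seq_len(nrow(snp))),
    chrom = snp$chrom, position = snp$position,
    geneticPos = snp$position / 1e6,
    allele1 = "A", allele2 = "G", row.names = NULL
  )
  samples <- data.frame(sampleId = sampleId, population = population,
                        ploidy = "diploid")
  GenoPanel(matrix(unlist(geno), ncol = 1), snp, samples)
}
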