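# FreqEstimate with exact (infinite-n) frequencies for some populations and
# finite counts for others.
mixedFreqEstimate <- function(exact, counts, chroms) {
  stopifnot(nrow(exact) == nrow(counts))
  cnt <- cbind(exact, counts)
  chr <- cbind(matrix(Inf, nrow(exact), ncol(exact),
                      dimnames = dimnames(exact)), chroms)
  fe <- new("FreqEstimate", counts = cnt, chroms = chr,
            snpId = sprintf("s%d", seq_len(nrow(cnt))))
  attr(fe, "inds") <- chr
  fe
}

test_that("population frequency counting distinguishes ploidy", {
  d <- matrix(c(1L, 2L, NA,
                2L, NA, 0L), nrow = 3)   # col1 diploid, col2 pseudo-haploid
  panel <- GenoPanel(d,
                     data.frame(snpId = c("s1", "s2", "s3"), chrom = "1",
                                position = c(1L, 2L, 3L),
                                geneticPos = c(0.01, 0.02, 0.03),
                                allele1 = "A", allele2 = "G"),
                     data.frame(sampleId = c("dip", "ph"), population = "P",
                                ploidy = c("diploid", "pseudohaploid")))
  fe <- popFrequencies(panel)
  # s1: diploid 1/2 + pseudo-haploid 1/1 -> 2 of 3 chromosomes
  expect_equal(unname(fe@counts[, "P"]), c(2, 2, 0))
  expect_equal(unname(fe@chroms[, "P"]), c(3, 2, 1))
  expect_equal(unname(attr(fe, "inds")[, "P"]), c(2, 1, 1))
  expect_equal(unname(freqMatrix(fe)[, "P"]), c(2 / 3, 1, 0))
  grouped <- popFrequencies(panel, list(All = "P"))
  expect_equal(grouped@counts[, "All"], fe@counts[, "P"])
  expect_error(popFrequencies(panel, list(X = "nope")), "empty")
})

test_that("f3 reproduces the frozen two-SNP worked example", {
  # target C at 2/4 chromosomes both SNPs; A, B known exactly.
  # mean (c-a)(c-b) = (0.4*0.3 + 0.4*0.3) / 2 = 0.12, correction
  # 0.25/(4-1) at each SNP
  fe <- mixedFreqEstimate(
    exact = cbind(A = c(0.1, 0.9), B = c(0.2, 0.8)),
    counts = cbind(C = c(2, 2)), chroms = cbind(C = c(4, 4)))
  s <- f3Stat(fe, "C", "A", "B", blocks = c("b1", "b2"))
  expect_equal(statEstimate(s), 0.12 - 0.25 / 3, tolerance = 1e-12)
  expect_equal(s@nSnps, 2)
  expect_equal(s@nBlocks, 2)
})

test_that("f2 of a population with itself is exactly zero", {
  fe <- mixedFreqEstimate(exact = cbind(A = c(0.1, 0.5)),
                          counts = cbind(C = c(3, 1)),
                          chroms = cbind(C = c(6, 4)))
  s <- f2Stat(fe, "C", "C", blocks = c("b1", "b2"))
  expect_identical(statEstimate(s), 0)
  expect_identical(statSE(s), 0)
  expect_identical(statZ(s), 0)
})

test_that("f4 is antisymmetric and additive; f3 equals its f2 combination", {
  set.seed(40)
  n <- 400
  chroms <- matrix(10, n, 5, dimnames = list(NULL, c("A", "B", "C", "Q", "O")))
  counts <- matrix(rbinom(n * 5, 10, runif(n * 5, 0.2, 0.8)), n, 5,
                   dimnames = dimnames(chroms))
  fe <- new("FreqEstimate", counts = counts, chroms = chroms,
            snpId = sprintf("s%d", seq_len(n)))
  blocks <- freqBlocks(n, 20)
  f4 <- function(...) statEstimate(f4Stat(fe, ..., blocks = blocks))
  expect_equal(f4("A", "B", "C", "O"), -f4("B", "A", "C", "O"))
  expect_equal(f4("A", "B", "C", "O"), -f4("A", "B", "O", "C"))
  expect_equal(f4("A", "B", "C", "O"), f4("C", "O", "A", "B"))
  expect_equal(f4("A", "B", "C", "O"),
               f4("A", "B", "C", "Q") + f4("A", "B", "Q", "O"),
               tolerance = 1e-12)
  # estimator-level identity: f3(C;A,B) = (f2(C,A) + f2(C,B) - f2(A,B)) / 2,
  # exact including the small-sample corrections
  f2 <- function(x, y) statEstimate(f2Stat(fe, x, y, blocks))
  expect_equal(statEstimate(f3Stat(fe, "C", "A", "B", blocks)),
               (f2("C", "A") + f2("C", "B") - f2("A", "B")) / 2,
               tolerance = 1e-12)
})

test_that("the weighted jackknife reduces to the textbook form", {
  set.seed(41)
  num <- rnorm(30)
  w <- rep(4, 30)
  jk <- blockJackknife(num, NULL, w)
  theta <- sum(num) / sum(w)
  loo <- (sum(num) - num) / (sum(w) - w)
  expect_equal(jk$estimate, theta)
  expect_equal(jk$se, sqrt((29 / 30) * sum((loo - mean(loo))^2)))
  expect_true(is.na(blockJackknife(1.5, NULL, 10)$se))
  expect_error(blockJackknife(c(1, 2), NULL, c(0, 0)), "denominator")
})

test_that("D normalizes f4 by the heterozygosity product", {
  p <- cbind(W = c(0.9, 0.1, 0.5, 0.3), X = c(0.1, 0.8, 0.4, 0.6),
             Y = c(0.8, 0.2, 0.7, 0.2), Z = c(0.2, 0.7, 0.2, 0.9))
  fe <- freqEstimateFromFrequencies(p)
  blocks <- c("b1", "b1", "b2", "b2")
  s <- dStat(fe, "W", "X", "Y", "Z", blocks)
  num <- sum((p[, "W"] - p[, "X"]) * (p[, "Y"] - p[, "Z"]))
  den <- sum((p[, "W"] + p[, "X"] - 2 * p[, "W"] * p[, "X"]) *
               (p[, "Y"] + p[, "Z"] - 2 * p[, "Y"] * p[, "Z"]))
  expect_equal(statEstimate(s), num / den, tolerance = 1e-12)
  expect_true(abs(statEstimate(s)) <= 1)
})

test_that("genotype-level f2 is consistent with the moment oracle", {
  d <- 0.03
  m <- twoLeafModel(d, sampling = data.frame(
    population = c("A", "B"), nDiploid = 8, nPseudo = 0))
  p <- simulateFrequencies(m, 20000, seed = 50)
  panel <- sampleGenotypes(p, m, seed = 51, nChrom = 10, chromLengthBp = 1e8)
  fe <- popFrequencies(panel)
  blocks <- assignBlocks(snpTable(panel))
  s <- f2Stat(fe, "A", "B", blocks)
  oracle <- expectedF2(expectedFMoments(m), "A", "B")
  expect_lt(abs(statEstimate(s) - oracle), 3 * statSE(s))
  # the small-sample correction matters: the naive squared difference is
  # biased upward by the sampling noise of 16 chromosomes per population
  naive <- mean((freqMatrix(fe)[, "A"] - freqMatrix(fe)[, "B"])^2)
  expect_gt(naive, oracle + 3 * statSE(s))
})

test_that("f3 demands a usable target and f4-ratio warns on weak denominators", {
  fe <- mixedFreqEstimate(exact = cbind(A = c(0.1, 0.5), B = c(0.3, 0.7)),
                          counts = cbind(C = c(1, 0)),
                          chroms = cbind(C = c(1, 1)))
  expect_error(f3Stat(fe, "C", "A", "B", blocks = c("b1", "b2")),
               "2 chromosomes")
  set.seed(52)
  n <- 200
  p <- matrix(runif(5 * n, 0.2, 0.8), n, 5,
              dimnames = list(NULL, c("O", "X", "A", "B", "M")))
  fe2 <- freqEstimateFromFrequencies(p)
  # unrelated populations: the f4 denominator is pure noise
  expect_warning(f4Ratio(fe2, "O", "X", "A", "B", "M", freqBlocks(n, 20)),
                 "denominator")
  expect_error(f2Stat(fe2, "O", "nope", freqBlocks(n, 20)), "unknown")
})
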