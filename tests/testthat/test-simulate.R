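test_that("frequency simulation is seed-deterministic", {
  m <- twoLeafModel(0.02)
  p1 <- simulateFrequencies(m, 200, seed = 5)
  p2 <- simulateFrequencies(m, 200, seed = 5)
  p3 <- simulateFrequencies(m, 200, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_setequal(colnames(p1), c("R", "A", "B"))
})

test_that("zero drift transmits frequencies unchanged", {
  p <- simulateFrequencies(twoLeafModel(0), 300, seed = 1)
  expect_identical(p[, "A"], p[, "R"])
  expect_identical(p[, "B"], p[, "R"])
})

test_that("fixed and lost alleles are absorbing states", {
  # degenerate ancestral distributions pin the root at 0 or 1
  for (val in c(0, 1)) {
    m <- DemographyModel(
      edges = data.frame(parent = "R", child = c("A", "B"), drift = 0.3),
      ancestralFreq = list(dist = "uniform", min = val, max = val))
    p <- simulateFrequencies(m, 100, seed = 2)
    expect_true(all(p == val))
  }
})

test_that("drift increments match the Balding-Nichols variance", {
  d <- 0.02
  p <- simulateFrequencies(twoLeafModel(d), 50000, seed = 11)
  # standardized squared increment has mean d under the transition model
  t <- (p[, "A"] - p[, "R"])^2 / (p[, "R"] * (1 - p[, "R"]))
  expect_lt(abs(mean(t) - d), 3 * sd(t) / sqrt(length(t)))
})

test_that("sampled genotypes are binomial around the population frequency", {
  m <- twoLeafModel(0.01, sampling = data.frame(
    population = c("A", "B"), nDiploid = c(6, 0), nPseudo = c(0, 6)))
  p <- simulateFrequencies(m, 5000, seed = 3)
  panel <- sampleGenotypes(p, m, seed = 4, nChrom = 4, chromLengthBp = 1e7)
  smp <- sampleTable(panel)
  d <- dosage(panel)
  expect_identical(smp$ploidy, rep(c("diploid", "pseudohaploid"), each = 6))
  expect_true(all(grepl("^A_d", smp$sampleId[1:6])))
  # pseudo-haploid columns never carry a heterozygote
  expect_false(any(d[, smp$ploidy == "pseudohaploid"] == 1))
  # overall allele frequency matches the simulated truth
  phatA <- mean(d[, 1:6]) / 2
  expect_lt(abs(phatA - mean(p[, "A"])), 0.01)
  phatB <- mean(d[, 7:12]) / 2
  expect_lt(abs(phatB - mean(p[, "B"])), 0.01)
  # SNP map: sorted positions per chromosome, uniform genetic map
  snp <- snpTable(panel)
  expect_equal(snp$geneticPos, snp$position / 1e6)
  for (ch in unique(snp$chrom)) {
    expect_false(is.unsorted(snp$position[snp$chrom == ch]))
  }
  expect_error(sampleGenotypes(p, m, nChrom = 1), "chromosomes")
  expect_error(sampleGenotypes(p[, "R", drop = FALSE], m), "lacks")
})

test_that("pileup depth is Poisson and errors respect the rate", {
  snp <- data.frame(snpId = sprintf("s%d", 1:4000), chrom = "1",
                    position = seq_len(4000) * 100L,
                    geneticPos = seq_len(4000) * 1e-4,
                    allele1 = "A", allele2 = "G")
  # homozygous allele1 and no error: only A bases ever observed
  pile <- simulatePileup(snp, coverage = 1.4, errorRate = 0,
                         seed = 9, genotype = rep(2L, 4000))
  expect_true(all(pile$countC == 0 & pile$countG == 0 & pile$countT == 0))
  expect_true(all(pile$countA >= 1))   # zero-depth SNPs are absent
  depth <- pile$countA
  # mean depth of a zero-truncated Poisson(1.4)
  lam <- 1.4
  expect_lt(abs(mean(depth) - lam / (1 - exp(-lam))), 0.05)
  expect_lt(abs(nrow(pile) / 4000 - (1 - exp(-lam))), 0.03)
  # with an error rate, off-panel bases appear at roughly that rate
  pile2 <- simulatePileup(snp, coverage = 2, errorRate = 0.1,
                          seed = 10, genotype = rep(2L, 4000))
  tot <- sum(pile2[, c("countA", "countC", "countG", "countT")])
  off <- sum(pile2$countC + pile2$countT) + sum(pile2$countG)
  expect_lt(abs(off / tot - 0.1), 0.02)
  expect_error(simulatePileup(snp, coverage = 1, errorRate = 0.3,
                              genotype = rep(2L, 4000)), "errorRate")
  expect_error(simulatePileup(snp, coverage = 1, errorRate = 0), "freq")
})

test_that("pileup TSV round-trips", {
  snp <- data.frame(snpId = c("s1", "s2", "s3"), chrom = "2",
                    position = c(10L, 20L, 30L),
                    geneticPos = c(1e-5, 2e-5, 3e-5),
                    allele1 = "C", allele2 = "T")
  pile <- simulatePileup(snp, coverage = 3, errorRate = 0.01, seed = 1,
                         freq = rep(0.5, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePileup(pile, path)
  expect_equal(readPileup(path), pile)
})

test_that("planted autozygous segments suppress heterozygosity", {
  seg <- data.frame(chrom = "c1", start = 4e6, end = 8e6)
  panel <- simulateRohGenome(c(c1 = 2e7), hetDensity = 5e-4,
                             plantedSegments = seg, errorHetRate = 0.001,
                             seed = 21)
  snp <- snpTable(panel)
  g <- dosage(panel)[, 1]
  inside <- snp$position >= 4e6 & snp$position <= 8e6
  hetIn <- mean(g[inside] == 1)
  hetOut <- mean(g[!inside] == 1)
  expect_lt(hetIn, 0.01)
  expect_gt(hetOut, 0.4)   # hetDensity / snpDensity = 0.5
  expect_identical(sampleTable(panel)$ploidy, "diploid")
})

test_that("invalid planted segments are rejected", {
  expect_error(simulateRohGenome(c(c1 = 1e7), 5e-4,
                                 data.frame(chrom = "c1",
                                            start = c(1e6, 2e6),
                                            end = c(3e6, 4e6)),
                                 0.001, seed = 1), "overlap")
  expect_error(simulateRohGenome(c(c1 = 1e7), 5e-4,
                                 data.frame(chrom = "c1", start = 5e6,
                                            end = 2e7),
                                 0.001, seed = 1), "bounds")
  expect_error(simulateRohGenome(c(c1 = 1e7), 5e-4,
                                 data.frame(chrom = "zz", start = 1, end = 2),
                                 0.001, seed = 1), "unknown")
  expect_error(simulateRohGenome(c(c1 = 1e7), hetDensity = 0.01,
                                 data.frame(chrom = "c1", start = 1, end = 2),
                                 0.001, seed = 1, snpDensity = 1e-3),
               "exceeds")
})
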