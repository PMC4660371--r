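inferenceFreqs <- function(model, nSnps, seed) {
  p <- simulateFrequencies(model, nSnps, seed)
  list(fe = freqEstimateFromFrequencies(p), blocks = freqBlocks(nSnps, 50))
}

test_that("the topology test recovers the generating clade on the preset", {
  sim <- getPresetSim()
  verdict <- topologyTest(sim$grouped, "CHG", "EF", "WHG", "Outgroup",
                          sim$blocks)
  expect_setequal(verdict$winner, c("CHG", "EF"))
  expect_true(verdict$decisive)
  expect_true(all(verdict$differenceZ > 3))
  # permutation invariance of the candidate order
  verdict2 <- topologyTest(sim$grouped, "WHG", "CHG", "EF", "Outgroup",
                           sim$blocks)
  expect_setequal(verdict2$winner, verdict$winner)
  expect_equal(sort(verdict2$table$f3), sort(verdict$table$f3))
  expect_output(print(verdict), "decisive")
  expect_error(topologyTest(sim$grouped, "CHG", "CHG", "WHG", "Outgroup",
                            sim$blocks), "distinct")
})

test_that("a star phylogeny yields an indecisive verdict", {
  star <- DemographyModel(
    edges = data.frame(parent = "R", child = c("O", "A", "B", "C"),
                       drift = 0.02))
  sim <- inferenceFreqs(star, 5000, seed = 61)
  verdict <- topologyTest(sim$fe, "A", "B", "C", "O", sim$blocks)
  expect_false(verdict$decisive)
})

test_that("the clade D-test distinguishes clean trees from gene flow", {
  clean <- DemographyModel(
    edges = data.frame(
      parent = c("R", "R", "T", "T", "AB", "AB"),
      child = c("O", "T", "P", "AB", "A", "B"),
      drift = c(0.05, 0.02, 0.04, 0.03, 0.02, 0.02)))
  sim <- inferenceFreqs(clean, 5000, seed = 62)
  res <- cladeTest(sim$fe, "O", "P", "A", "B", sim$blocks)
  expect_true(attr(res, "cladeSupported"))
  expect_false(any(res$significant))

  flow <- DemographyModel(
    edges = data.frame(
      parent = c("R", "R", "T", "P0", "T", "AB", "AB", "Aadm"),
      child = c("O", "T", "P0", "P", "AB", "Aanc", "B", "A"),
      drift = c(0.05, 0.02, 0.03, 0.01, 0.03, 0.02, 0.02, 0.005)),
    admixture = data.frame(target = "Aadm", sourceA = "P0",
                           sourceB = "Aanc", alpha = 0.4))
  sim2 <- inferenceFreqs(flow, 5000, seed = 63)
  res2 <- cladeTest(sim2$fe, "O", "P", "A", "B", sim2$blocks)
  expect_false(attr(res2, "cladeSupported"))
  expect_true(res2$significant[res2$probe == "P"])
  expect_error(cladeTest(sim$fe, "O", character(0), "A", "B", sim$blocks),
               "empty")
  expect_error(cladeTest(sim$fe, "O", "P", "P", "B", sim$blocks), "distinct")
})

test_that("outgroup-f3 affinity ranks the closer population first", {
  m <- DemographyModel(
    edges = data.frame(
      parent = c("R", "R", "T", "T", "IX", "IX"),
      child = c("O", "T", "M2", "IX", "M1", "X"),
      drift = c(0.05, 0.02, 0.03, 0.02, 0.01, 0.01)))
  sim <- inferenceFreqs(m, 5000, seed = 64)
  rk <- affinityRank(sim$fe, "X", c("M2", "M1"), "O", sim$blocks)
  expect_equal(rk$modern, c("M1", "M2"))
  expect_gt(rk$f3[1], rk$f3[2])
  expect_error(affinityRank(sim$fe, "X", character(0), "O", sim$blocks),
               "at least one")
})

test_that("the admixture scan flags the true source pair and only it", {
  m <- DemographyModel(
    edges = data.frame(
      parent = c("R", "R", "R", "AB", "AB", "Aanc", "Banc", "Madm"),
      child = c("O", "C", "AB", "Aanc", "Banc", "A", "B", "M"),
      drift = c(0.05, 0.05, 0.01, 0.06, 0.06, 0.02, 0.02, 0.005)),
    admixture = data.frame(target = "Madm", sourceA = "Aanc",
                           sourceB = "Banc", alpha = 0.5))
  sim <- inferenceFreqs(m, 5000, seed = 65)
  scan <- admixtureScan(sim$fe, "M", c("A", "B", "C", "O"), sim$blocks)
  expect_setequal(unlist(scan[1, c("sourceA", "sourceB")],
                         use.names = FALSE), c("A", "B"))
  expect_true(scan$significant[1])
  # an unadmixed target shows no significantly negative pair
  scan2 <- admixtureScan(sim$fe, "C", c("A", "B", "O"), sim$blocks)
  expect_false(any(scan2$significant))
  expect_error(admixtureScan(sim$fe, "M", "A", sim$blocks), "two candidate")
  expect_error(admixtureScan(sim$fe, "M", c("M", "A"), sim$blocks),
               "cannot be among")
})

test_that("split-time fitting recovers the truth from exact statistics", {
  truth <- buildPreset("jones2015")
  mt <- expectedFMoments(truth)
  leaves <- c("Bichon", "Loschbour", "Kotias", "Satsurblia", "EF", "EHG")
  prs <- utils::combn(leaves, 2, simplify = FALSE)
  obs <- do.call(rbind, lapply(prs, function(pr) {
    data.frame(type = "f3", pop1 = "Outgroup", pop2 = pr[1], pop3 = pr[2],
               pop4 = NA_character_,
               estimate = expectedF3(mt, "Outgroup", pr[1], pr[2]),
               se = 1e-4)
  }))
  builder <- function(t, Ne, genTime) {
    buildPreset("jones2015", whgSplitYears = t[["whgSplitYears"]],
                chgEfSplitYears = t[["chgEfSplitYears"]],
                Ne = Ne, genTime = genTime)
  }
  fit <- fitSplitTimes(obs, builder,
                       start = c(whgSplitYears = 60000,
                                 chgEfSplitYears = 18000),
                       lower = c(25000, 17000), upper = c(95000, 44000),
                       Ne = 10000, genTime = 29)
  expect_lt(abs(fit$times[["whgSplitYears"]] - 45000) / 45000, 0.02)
  expect_lt(abs(fit$times[["chgEfSplitYears"]] - 25000) / 25000, 0.02)
  expect_false(fit$nonIdentifiable)
  expect_equal(fit$convergence, 0)
  expect_output(print(fit), "kya")
})

test_that("one-parameter fits use the bounded scalar optimizer", {
  truth <- buildPreset("jones2015")
  mt <- expectedFMoments(truth)
  obs <- data.frame(type = "f3", pop1 = "Outgroup", pop2 = "Bichon",
                    pop3 = c("Kotias", "EF", "Loschbour"),
                    pop4 = NA_character_, se = 1e-4)
  obs$estimate <- vapply(seq_len(nrow(obs)), function(i) {
    expectedF3(mt, "Outgroup", obs$pop2[i], obs$pop3[i])
  }, 0)
  builder <- function(t, Ne, genTime) {
    buildPreset("jones2015", whgSplitYears = t[["whgSplitYears"]],
                Ne = Ne, genTime = genTime)
  }
  fit <- fitSplitTimes(obs, builder, start = c(whgSplitYears = 60000),
                       lower = 25000, upper = 95000, Ne = 10000, genTime = 29)
  expect_lt(abs(fit$times[["whgSplitYears"]] - 45000) / 45000, 0.02)
})

test_that("the fitter validates its inputs and flags flat objectives", {
  obs <- data.frame(type = "f2", pop1 = "A", pop2 = "B",
                    pop3 = NA_character_, pop4 = NA_character_,
                    estimate = 0.01, se = 0.001)
  builder <- function(t, Ne, genTime) twoLeafModel(0.02)
  expect_error(fitSplitTimes(obs, builder, start = c(tA = 1000, tB = 1000),
                             Ne = 1e4, genTime = 29), "more free parameters")
  expect_error(fitSplitTimes(obs, builder, start = c(tA = 1000)),
               "Ne and genTime")
  bad <- obs
  bad$se <- 0
  expect_error(fitSplitTimes(bad, builder, start = c(tA = 1000),
                             Ne = 1e4, genTime = 29), "positive finite")
  # the builder ignores the parameter: flat objective, not identifiable
  fit <- fitSplitTimes(obs, builder, start = c(tA = 1000), lower = 100,
                       upper = 1e5, Ne = 1e4, genTime = 29)
  expect_true(fit$nonIdentifiable)
})
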