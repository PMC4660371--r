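# Shared model builders and a cached preset simulation.

# two leaves under a root, equal drift
twoLeafModel <- function(d = 0.01, sampling = NULL) {
  DemographyModel(
    edges = data.frame(parent = "R", child = c("A", "B"), drift = d),
    sampling = if (is.null(sampling)) emptyTestSampling() else sampling
  )
}

emptyTestSampling <- function() {
  data.frame(population = character(0), nDiploid = integer(0),
             nPseudo = integer(0))
}

# random bifurcating tree over nLeaves tips with random drift per edge
randomTreeModel <- function(nLeaves, seed) {
  set.seed(seed)
  edges <- data.frame(parent = "R", child = c("L1", "L2"),
                      drift = runif(2, 0.002, 0.05))
  leaves <- c("L1", "L2")
  nid <- 2
  while (length(leaves) < nLeaves) {
    pick <- sample(leaves, 1)
    kids <- paste0("L", nid + 1:2)
    nid <- nid + 2
    edges <- rbind(edges,
                   data.frame(parent = pick, child = kids,
                              drift = runif(2, 0.002, 0.05)))
    leaves <- c(setdiff(leaves, pick), kids)
  }
  DemographyModel(edges = edges)
}

# equal-length blocks over a frequency matrix
freqBlocks <- function(nSnps, nBlocks = 100) {
  sprintf("b%d", ceiling(seq_len(nSnps) / (nSnps / nBlocks)))
}

# cached moderate preset simulation shared by inference tests
presetSimEnv <- new.env()
getPresetSim <- function(nSnps = 30000, seed = 42) {
  key <- sprintf("sim_%d_%d", nSnps, seed)
  if (is.null(presetSimEnv[[key]])) {
    model <- buildPreset("jones2015")
    p <- simulateFrequencies(model, nSnps, seed)
    panel <- sampleGenotypes(p, model, seed + 1)
    presetSimEnv[[key]] <- list(
      model = model, freqs = p, panel = panel,
      blocks = assignBlocks(snpTable(panel)),
      grouped = popFrequencies(panel, list(
        Outgroup = "Outgroup", EF = "EF", EHG = "EHG", Yamnaya = "Yamnaya",
        WHG = c("Bichon", "Loschbour"), CHG = c("Kotias", "Satsurblia"))),
      leaf = popFrequencies(panel))
  }
  presetSimEnv[[key]]
}

# small diploid panel straight from a frequency matrix (one population per
# column), for unit tests that need genotype-level noise
panelFromFreqs <- function(p, nDip, seed, nChrom = 2) {
  pops <- colnames(p)
  model <- DemographyModel(
    edges = data.frame(parent = "R", child = pops, drift = 0),
    sampling = data.frame(population = pops, nDiploid = nDip, nPseudo = 0))
  sampleGenotypes(p, model, seed, nChrom = nChrom, chromLengthBp = 1e7)
}
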