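## DemographyModel construction, presets and config I/O.

# Topologically order the population graph.  Returns a list with the root,
# the node order, and for each node the event ("root", "edge" with its edge
# row, or "admix" with its admixture row).  Errors on multiple roots or cycles.
topoSortModel <- function(edges, admixture) {
  nodes <- unique(c(edges$parent, edges$child,
                    admixture$target, admixture$sourceA, admixture$sourceB))
  if (length(nodes) == 0) stop("model has no nodes")
  incoming <- c(edges$child, admixture$target)
  roots <- setdiff(nodes, incoming)
  if (length(roots) != 1L) {
    stop(sprintf("model must have exactly one root (found: %s)",
                 paste(roots, collapse = ", ")))
  }
  resolved <- roots
  order <- roots
  events <- list()
  events[[roots]] <- list(type = "root")
  repeat {
    progress <- FALSE
    if (nrow(edges) > 0) {
      ready <- which(edges$parent %in% resolved & !(edges$child %in% resolved))
      for (i in ready) {
        ch <- edges$child[i]
        resolved <- c(resolved, ch)
        order <- c(order, ch)
        events[[ch]] <- list(type = "edge", edge = i)
        progress <- TRUE
      }
    }
    if (nrow(admixture) > 0) {
      ready <- which(admixture$sourceA %in% resolved &
                     admixture$sourceB %in% resolved &
                     !(admixture$target %in% resolved))
      for (i in ready) {
        tg <- admixture$target[i]
        resolved <- c(resolved, tg)
        order <- c(order, tg)
        events[[tg]] <- list(type = "admix", admix = i)
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  if (length(resolved) < length(nodes)) {
    stop(sprintf("population graph is cyclic or disconnected (unreachable: %s)",
                 paste(setdiff(nodes, resolved), collapse = ", ")))
  }
  list(root = roots, order = order, events = events)
}

#' Construct a demographic model
#'
#' @param edges data.frame with columns \code{parent}, \code{child} and either
#'   \code{drift} (dimensionless, in \eqn{[0,1)}) or \code{duration} (years);
#'   missing columns are filled with \code{NA}.
#' @param admixture data.frame with columns \code{target}, \code{sourceA},
#'   \code{sourceB}, \code{alpha}; \code{alpha} is the ancestry fraction the
#'   target draws from \code{sourceA}.  May be empty.
#' @param Ne diploid effective population size for converting durations to
#'   drift.
#' @param genTime generation time in years.
#' @param ancestralFreq root allele-frequency distribution:
#'   \code{list(dist = "uniform", min =, max =)} (default Uniform(0.05, 0.95))
#'   or \code{list(dist = "beta", shape1 =, shape2 =)}.
#' @param sampling data.frame with columns \code{population}, \code{nDiploid},
#'   \code{nPseudo} specifying how sampled populations are genotyped.
#' @return A [DemographyModel-class] object.
#' @examples
#' m <- DemographyModel(
#'   edges = data.frame(parent = c("R", "R"), child = c("A", "B"),
#'                      drift = c(0.01, 0.01)),
#'   sampling = data.frame(population = c("A", "B"),
#'                         nDiploid = 5, nPseudo = 0))
#' populations(m)
#' @export
DemographyModel <- function(edges,
                            admixture = emptyAdmixture(),
                            Ne = 10000,
                            genTime = 29,
                            ancestralFreq = list(dist = "uniform",
                                                 min = 0.05, max = 0.95),
                            sampling = emptySampling()) {
  edges <- as.data.frame(edges)
  if (is.null(edges$drift)) edges$drift <- NA_real_
  if (is.null(edges$duration)) edges$duration <- NA_real_
  edges <- edges[, c("parent", "child", "drift", "duration")]
  admixture <- as.data.frame(admixture)
  sampling <- as.data.frame(sampling)
  new("DemographyModel", edges = edges, admixture = admixture,
      Ne = Ne, genTime = genTime, ancestralFreq = ancestralFreq,
      sampling = sampling)
}

emptyAdmixture <- function() {
  data.frame(target = character(0), sourceA = character(0),
             sourceB = character(0), alpha = numeric(0))
}

emptySampling <- function() {
  data.frame(population = character(0), nDiploid = integer(0),
             nPseudo = integer(0))
}

#' Convert a branch duration in years to a drift amount
#'
#' Under pure genetic drift the standardized frequency variance accumulated
#' over \eqn{t/g} generations in a diploid population of effective size
#' \eqn{N_e} is \eqn{d = 1 - \exp(-t / (g \cdot 2 N_e))}.
#'
#' @param t duration in years (vectorized).
#' @param Ne diploid effective size.
#' @param genTime generation time in years.
#' @return Drift values in \eqn{[0,1)}.
#' @examples
#' timeToDrift(0, 10000, 29)           # 0
#' timeToDrift(2 * 10000 * 29, 10000, 29)  # 1 - exp(-1)
#' @export
timeToDrift <- function(t, Ne, genTime) {
  if (any(t < 0)) stop("durations must be non-negative")
  if (Ne <= 0) stop("Ne must be positive")
  if (genTime <= 0) stop("genTime must be positive")
  1 - exp(-t / (genTime * 2 * Ne))
}

# Per-edge drift with durations converted through Ne and generation time.
effectiveDrift <- function(model) {
  ed <- model@edges
  d <- ed$drift
  i <- is.na(d)
  d[i] <- timeToDrift(ed$duration[i], model@Ne, model@genTime)
  names(d) <- ed$child
  d
}

#' @describeIn DemographyModel All population identifiers in the graph.
#' @param model a [DemographyModel-class].
#' @export
populations <- function(model) {
  topoSortModel(model@edges, model@admixture)$order
}

#' @describeIn DemographyModel Populations with no descendant edge (sampleable
#'   tips).
#' @export
leafPopulations <- function(model) {
  setdiff(populations(model), model@edges$parent)
}

#' @describeIn DemographyModel The sampling specification.
#' @export
samplingSpec <- function(model) model@sampling

#' @describeIn DemographyModel The edge table with effective drift attached.
#' @export
edgeTable <- function(model) {
  ed <- model@edges
  ed$effectiveDrift <- unname(effectiveDrift(model))
  ed
}

#' @describeIn DemographyModel The admixture event table.
#' @export
admixtureTable <- function(model) model@admixture

setMethod("show", "DemographyModel", function(object) {
  ts <- topoSortModel(object@edges, object@admixture)
  cat(sprintf("DemographyModel: %d populations, %d edges, %d admixture event(s)\n",
              length(ts$order), nrow(object@edges), nrow(object@admixture)))
  cat(sprintf("  root: %s | Ne = %g, generation time = %g y\n",
              ts$root, object@Ne, object@genTime))
  cat(sprintf("  leaves: %s\n",
              paste(leafPopulations(object), collapse = ", ")))
  if (nrow(object@sampling)) {
    cat(sprintf("  sampled: %s\n",
                paste(sprintf("%s (%dD/%dP)", object@sampling$population,
                              object@sampling$nDiploid, object@sampling$nPseudo),
                      collapse = ", ")))
  }
})

#' Built-in demographic presets
#'
#' \code{"jones2015"} encodes the published model of the deep structure of
#' West Eurasian ancestry: an African-like outgroup; western hunter-gatherers
#' (WHG, two tips resembling the Bichon and Loschbour genomes) splitting from
#' the common ancestor of Caucasus hunter-gatherers (CHG, tips resembling
#' Kotias and Satsurblia) and early farmers (EF) 45 kya; CHG and EF separating
#' 25 kya around the Last Glacial Maximum; eastern hunter-gatherers (EHG) on
#' the WHG side of the tree; and a Bronze Age steppe population (Yamnaya)
#' formed as an even mixture of CHG-related and EHG-related sources.
#'
#' Split times not reported for the model (outgroup, EHG, within-WHG and
#' within-CHG splits, admixture date, Ne, generation time) are package
#' defaults, exposed as arguments.
#'
#' @param name preset identifier; currently \code{"jones2015"}.
#' @param whgSplitYears split of WHG from the CHG+EF ancestor (default 45000).
#' @param chgEfSplitYears CHG--EF split (default 25000).
#' @param outgroupSplitYears outgroup divergence (default 1e5).
#' @param ehgSplitYears EHG--WHG split (default 20000).
#' @param tipSplitYears within-WHG and within-CHG tip splits (default 17000).
#' @param admixYears date of the steppe admixture event (default 5000).
#' @param yamnayaAlpha CHG-side ancestry fraction of Yamnaya (default 0.5).
#' @param basalAlpha optional basal-Eurasian ancestry fraction into EF; 0
#'   (default) disables the edge.
#' @param Ne,genTime,ancestralFreq see [DemographyModel()].
#' @return A [DemographyModel-class] with a default sampling spec:
#'   10 diploid outgroup samples, 4 diploid EF, 1 pseudo-haploid sample per
#'   hunter-gatherer tip, 3 pseudo-haploid EHG and 4 pseudo-haploid Yamnaya.
#' @examples
#' m <- buildPreset("jones2015")
#' leafPopulations(m)
#' @export
buildPreset <- function(name,
                        whgSplitYears = 45000,
                        chgEfSplitYears = 25000,
                        outgroupSplitYears = 100000,
                        ehgSplitYears = 20000,
                        tipSplitYears = 17000,
                        admixYears = 5000,
                        yamnayaAlpha = 0.5,
                        basalAlpha = 0,
                        Ne = 10000,
                        genTime = 29,
                        ancestralFreq = list(dist = "uniform",
                                             min = 0.05, max = 0.95)) {
  known <- c("jones2015")
  if (!name %in% known) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(known, collapse = ", ")))
  }
  t0 <- outgroupSplitYears
  t1 <- whgSplitYears
  t2 <- chgEfSplitYears
  tE <- ehgSplitYears
  tT <- tipSplitYears
  tA <- admixYears
  if (!(t0 >= t1 && t1 >= max(t2, tE) && t2 >= tT && tE >= tT && tT >= tA)) {
    stop("preset split times must nest: outgroup >= WHG split >= CHG-EF/EHG splits >= tip splits >= admixture date")
  }
  e <- function(parent, child, duration) {
    data.frame(parent = parent, child = child,
               drift = NA_real_, duration = duration)
  }
  edges <- rbind(
    e("Root", "Outgroup", t0),            # outgroup drifts to the present
    e("Root", "Eurasia", t0 - t1),
    # WHG/EHG side
    e("Eurasia", "WHGanc", t1 - tE),
    e("WHGanc", "WHG", tE - tT),
    e("WHG", "Bichon", tT),
    e("WHG", "Loschbour", tT),
    e("WHGanc", "EHGanc", tE - tA),
    e("EHGanc", "EHG", tA),
    # CHG/EF side
    e("Eurasia", "CEF", t1 - t2),
    e("CEF", "CHG", t2 - tT),
    e("CHG", "Kotias", tT),
    e("CHG", "Satsurblia", tT),
    e("CHG", "CHGsteppe", tT - tA),
    e("CEF", "EF", t2)
  )
  admixture <- data.frame(target = "YamnayaAnc", sourceA = "CHGsteppe",
                          sourceB = "EHGanc", alpha = yamnayaAlpha)
  edges <- rbind(edges, e("YamnayaAnc", "Yamnaya", tA))
  if (basalAlpha > 0) {
    # optional basal-Eurasian contribution into EF: re-route EF through an
    # admixed ancestor drawing basalAlpha from a deep lineage
    edges <- edges[!(edges$parent == "CEF" & edges$child == "EF"), ]
    edges <- rbind(edges,
                   e("Root", "Basal", t0 - t2),
                   e("CEF", "EFsrc", 0),
                   e("EFanc", "EF", t2))
    admixture <- rbind(admixture,
                       data.frame(target = "EFanc", sourceA = "Basal",
                                  sourceB = "EFsrc", alpha = basalAlpha))
  }
  sampling <- data.frame(
    population = c("Outgroup", "EF", "Bichon", "Loschbour",
                   "Kotias", "Satsurblia", "EHG", "Yamnaya"),
    nDiploid   = c(10, 4, 0, 0, 0, 0, 0, 0),
    nPseudo    = c(0, 0, 1, 1, 1, 1, 3, 4)
  )
  DemographyModel(edges = edges, admixture = admixture, Ne = Ne,
                  genTime = genTime, ancestralFreq = ancestralFreq,
                  sampling = sampling)
}

#' Read or write a demography config file
#'
#' The YAML dialect has top-level keys \code{ne}, \code{gen_time},
#' \code{ancestral_freq}, \code{edges} (list of \code{parent}/\code{child}
#' plus either \code{drift} or \code{time_years}), \code{admixture}
#' (\code{target}/\code{sourceA}/\code{sourceB}/\code{alpha}) and
#' \code{sampling} (\code{population}/\code{n_diploid}/\code{n_pseudohaploid}).
#' \code{writeDemography()} emits the same dialect, so write/read round-trips.
#'
#' @param path file path.
#' @param model a [DemographyModel-class] (writer).
#' @return \code{readDemography()} returns a [DemographyModel-class];
#'   \code{writeDemography()} returns \code{path} invisibly.
#' @export
readDemography <- function(path) {
  cfg <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(cfg$edges, function(x) {
    data.frame(parent = x$parent, child = x$child,
               drift = if (is.null(x$drift)) NA_real_ else x$drift,
               duration = if (is.null(x$time_years)) NA_real_ else x$time_years)
  }))
  admixture <- if (length(cfg$admixture)) {
    do.call(rbind, lapply(cfg$admixture, function(x) {
      data.frame(target = x$target, sourceA = x$sourceA,
                 sourceB = x$sourceB, alpha = x$alpha)
    }))
  } else emptyAdmixture()
  sampling <- if (length(cfg$sampling)) {
    do.call(rbind, lapply(cfg$sampling, function(x) {
      data.frame(population = x$population,
                 nDiploid = as.integer(x$n_diploid),
                 nPseudo = as.integer(x$n_pseudohaploid))
    }))
  } else emptySampling()
  af <- cfg$ancestral_freq
  if (is.null(af)) af <- list(dist = "uniform", min = 0.05, max = 0.95)
  DemographyModel(edges = edges, admixture = admixture,
                  Ne = if (is.null(cfg$ne)) 10000 else cfg$ne,
                  genTime = if (is.null(cfg$gen_time)) 29 else cfg$gen_time,
                  ancestralFreq = af, sampling = sampling)
}

#' @rdname readDemography
#' @export
writeDemography <- function(model, path) {
  ed <- model@edges
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    x <- list(parent = ed$parent[i], child = ed$child[i])
    if (!is.na(ed$drift[i])) x$drift <- ed$drift[i]
    if (!is.na(ed$duration[i])) x$time_years <- ed$duration[i]
    x
  })
  ad <- model@admixture
  admixture <- lapply(seq_len(nrow(ad)), function(i) {
    list(target = ad$target[i], sourceA = ad$sourceA[i],
         sourceB = ad$sourceB[i], alpha = ad$alpha[i])
  })
  sp <- model@sampling
  sampling <- lapply(seq_len(nrow(sp)), function(i) {
    list(population = sp$population[i],
         n_diploid = sp$nDiploid[i],
         n_pseudohaploid = sp$nPseudo[i])
  })
  yaml::write_yaml(list(ne = model@Ne, gen_time = model@genTime,
                        ancestral_freq = model@ancestralFreq,
                        edges = edges, admixture = admixture,
                        sampling = sampling), path)
  invisible(path)
}

# Analytic moments of the ancestral frequency distribution.
ancestralMoments <- function(spec) {
  if (spec$dist == "uniform") {
    a <- spec$min
    b <- spec$max
    list(m1 = (a + b) / 2, m2 = (a^2 + a * b + b^2) / 3)
  } else if (spec$dist == "beta") {
    s1 <- spec$shape1
    s2 <- spec$shape2
    m1 <- s1 / (s1 + s2)
    list(m1 = m1, m2 = m1 * (s1 + 1) / (s1 + s2 + 1))
  } else {
    stop(sprintf("unknown ancestral frequency distribution '%s'", spec$dist))
  }
}

drawAncestral <- function(spec, n) {
  if (spec$dist == "uniform") {
    runif(n, spec$min, spec$max)
  } else if (spec$dist == "beta") {
    rbeta(n, spec$shape1, spec$shape2)
  } else {
    stop(sprintf("unknown ancestral frequency distribution '%s'", spec$dist))
  }
}
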