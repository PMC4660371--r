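## Exact moment propagation: the oracle for expected f-statistics.

#' Expected allele-frequency moments under a demographic model
#'
#' Propagates \eqn{E[p_X]} and \eqn{E[p_X p_Y]} exactly through the population
#' graph.  Drift on a branch leaves the mean and all cross moments unchanged
#' and inflates the own second moment,
#' \eqn{E[p^2] \leftarrow E[p^2] + d\,(E[p] - E[p^2])}; siblings inherit the
#' parent's \eqn{E[p^2]} as their cross moment; an admixed population
#' \eqn{M = \alpha A + (1-\alpha) B} combines moments linearly and
#' bilinearly.  Expected f-statistics are linear combinations of the table
#' ([expectedF2()] and friends), making this an exact oracle for the
#' Monte-Carlo simulator.
#'
#' @param model a [DemographyModel-class].
#' @return A [MomentTable-class] covering every population (internal nodes
#'   included).
#' @examples
#' m <- DemographyModel(
#'   edges = data.frame(parent = "R", child = c("A", "B"), drift = 0.01))
#' mt <- expectedFMoments(m)
#' expectedF2(mt, "A", "B")   # 2 * 0.01 * E[p0 (1 - p0)]
#' @export
expectedFMoments <- function(model) {
  ts <- topoSortModel(model@edges, model@admixture)
  pops <- ts$order
  n <- length(pops)
  drift <- effectiveDrift(model)
  am <- ancestralMoments(model@ancestralFreq)
  m1 <- setNames(numeric(n), pops)
  m2 <- matrix(0, n, n, dimnames = list(pops, pops))
  done <- character(0)
  for (node in pops) {
    ev <- ts$events[[node]]
    if (ev$type == "root") {
      m1[node] <- am$m1
      m2[node, node] <- am$m2
    } else if (ev$type == "edge") {
      e <- model@edges[ev$edge, ]
      par <- e$parent
      d <- drift[[node]]
      m1[node] <- m1[par]
      m2[node, done] <- m2[par, done]
      m2[done, node] <- m2[done, par]
      m2[node, node] <- m2[par, par] + d * (m1[par] - m2[par, par])
    } else {
      a <- model@admixture[ev$admix, ]
      al <- a$alpha
      sA <- a$sourceA
      sB <- a$sourceB
      m1[node] <- al * m1[sA] + (1 - al) * m1[sB]
      m2[node, done] <- al * m2[sA, done] + (1 - al) * m2[sB, done]
      m2[done, node] <- m2[node, done]
      m2[node, node] <- al^2 * m2[sA, sA] +
        2 * al * (1 - al) * m2[sA, sB] + (1 - al)^2 * m2[sB, sB]
    }
    done <- c(done, node)
  }
  new("MomentTable", pops = pops, m1 = m1, m2 = m2)
}

setMethod("show", "MomentTable", function(object) {
  cat(sprintf("MomentTable over %d populations\n", length(object@pops)))
  cat("  E[p]: "); print(round(object@m1, 4))
})

checkPops <- function(mt, pops) {
  miss <- setdiff(pops, mt@pops)
  if (length(miss)) {
    stop(sprintf("unknown population(s): %s", paste(miss, collapse = ", ")))
  }
}

#' Expected f-statistics from a moment table
#'
#' \code{expectedF2(A,B)} \eqn{= E[(p_A - p_B)^2]},
#' \code{expectedF3(C;A,B)} \eqn{= E[(p_C - p_A)(p_C - p_B)]},
#' \code{expectedF4(W,X;Y,Z)} \eqn{= E[(p_W - p_X)(p_Y - p_Z)]},
#' all evaluated exactly from the second-moment table.
#'
#' @param mt a [MomentTable-class] from [expectedFMoments()].
#' @param A,B,C,W,X,Y,Z population names.
#' @return Expected statistic value (numeric scalar).
#' @export
expectedF2 <- function(mt, A, B) {
  checkPops(mt, c(A, B))
  mt@m2[A, A] + mt@m2[B, B] - 2 * mt@m2[A, B]
}

#' @rdname expectedF2
#' @export
expectedF3 <- function(mt, C, A, B) {
  checkPops(mt, c(C, A, B))
  mt@m2[C, C] - mt@m2[C, A] - mt@m2[C, B] + mt@m2[A, B]
}

#' @rdname expectedF2
#' @export
expectedF4 <- function(mt, W, X, Y, Z) {
  checkPops(mt, c(W, X, Y, Z))
  mt@m2[W, Y] - mt@m2[W, Z] - mt@m2[X, Y] + mt@m2[X, Z]
}
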