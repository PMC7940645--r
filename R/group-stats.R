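# Permutation inference between diagnostic groups on network-level
# statistics. The null is built by reshuffling subject labels with group
# sizes preserved and recomputing the whole network statistic (correlation
# onward) per permutation.

#' Registered network statistics
#'
#' Each statistic maps one group's subject-by-ROI matrix to a scalar via
#' correlation, distance transform and persistence or graph metrics:
#' \describe{
#'   \item{sipAUC}{SIP area under the Betti-0 curve (1 + total MST weight).}
#'   \item{cpl}{characteristic path length of the edge-filtered graph.}
#'   \item{nd}{network diameter of the edge-filtered graph.}
#'   \item{ecMean}{mean eigenvector centrality over scored nodes.}
#' }
#'
#' @return Character vector of statistic names.
#' @export
networkStatistics <- function() c("sipAUC", "cpl", "nd", "ecMean")

# Correlation -> distance on a plain subjects-x-ROI matrix (fast path; the
# same arithmetic as pearsonMatrix + toDistance without S4 validation).
.corDistance <- function(X, mode = "absolute") {
  r <- stats::cor(X)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  d <- if (mode == "signed") (1 - r) / 2 else 1 - abs(r)
  diag(d) <- 0
  d
}

# Build the scalar statistic closure used by the permutation engine.
.makeStatistic <- function(name, options = list()) {
  name <- match.arg(name, networkStatistics())
  mode <- if (is.null(options$mode)) "absolute" else options$mode
  threshold <- if (is.null(options$threshold)) 0.5 else options$threshold
  toGraph <- function(X) {
    d <- .corDistance(X, mode)
    filterEdges(DistanceMatrix(d), threshold = threshold)
  }
  switch(name,
    sipAUC = function(X) 1 + .mstTotal(.corDistance(X, mode)),
    cpl = function(X) characteristicPathLength(toGraph(X))$value,
    nd = function(X) networkDiameter(toGraph(X))$value,
    ecMean = function(X) {
      sc <- suppressWarnings(eigenvectorCentrality(toGraph(X)))
      mean(sc, na.rm = TRUE)
    })
}

#' Evaluate a registered network statistic on one group
#'
#' @param x an \linkS4class{UptakeMatrix}.
#' @param statistic one of \code{\link{networkStatistics}}.
#' @param options list of statistic options: \code{threshold} (edge filter
#'   for cpl/nd/ecMean, default 0.5) and \code{mode} (distance transform,
#'   default \code{"absolute"}).
#' @return Scalar statistic value.
#' @export
networkStatistic <- function(x, statistic = "sipAUC", options = list()) {
  stopifnot(is(x, "UptakeMatrix"))
  .makeStatistic(statistic, options)(uptakeValues(x))
}

#' Two-group permutation test on a network statistic
#'
#' Pools subjects from both groups, reshuffles group labels preserving the
#' group sizes, and recomputes the statistic from scratch (correlation
#' onward) for each permutation. Two-sided add-one p-value:
#' \eqn{p = (1 + \#\{|null| \ge |obs|\}) / (1 + B)}, never exactly 0.
#'
#' @param a,b \linkS4class{UptakeMatrix} objects with identical ROI names.
#' @param statistic one of \code{\link{networkStatistics}}.
#' @param nPermutations number of label permutations (>= 1); 10,000 gives
#'   stable p-values near the 0.001 significance level.
#' @param seed RNG seed for the permutation stream.
#' @param options statistic options, see \code{\link{networkStatistic}}.
#' @return A \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(a, b, statistic = "sipAUC",
                            nPermutations = 10000L, seed = 1L,
                            options = list()) {
  stopifnot(is(a, "UptakeMatrix"), is(b, "UptakeMatrix"))
  if (!identical(roiNames(a), roiNames(b)))
    stop("both groups must share identical ROI names (same order)")
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 1L) stop("nPermutations must be at least 1")
  f <- .makeStatistic(statistic, options)
  Xa <- uptakeValues(a)
  Xb <- uptakeValues(b)
  na <- nrow(Xa)
  pooled <- rbind(Xa, Xb)
  nTot <- nrow(pooled)
  obs <- f(Xa) - f(Xb)
  if (is.na(obs))
    stop(sprintf("statistic '%s' is undefined on the observed groups", statistic))
  null <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(k) {
      idx <- sample.int(nTot)
      f(pooled[idx[seq_len(na)], , drop = FALSE]) -
        f(pooled[idx[-seq_len(na)], , drop = FALSE])
    }, numeric(1))
  })
  if (anyNA(null))
    stop(sprintf("statistic '%s' was undefined in %d permutation(s)",
                 statistic, sum(is.na(null))))
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + nPermutations)
  new("PermutationResult",
      metricName = statistic,
      groupPair = c(groupLabel(a), groupLabel(b)),
      observedDifference = obs, nullDraws = null, pValue = p,
      nPermutations = nPermutations, seed = as.integer(seed))
}

#' Pairwise group comparison table
#'
#' One row per pathway x statistic x group pair, with observed values per
#' group, their difference, the permutation p-value and a significance flag
#' at the fixed threshold (no multiplicity adjustment beyond it by default;
#' optional Bonferroni/BH columns are marked extensions).
#'
#' @param groups named list of \linkS4class{UptakeMatrix}, >= 2 groups, all
#'   sharing the full ROI set.
#' @param pathways named list of \linkS4class{Pathway} objects.
#' @param statistics character vector from \code{\link{networkStatistics}}.
#' @param nPermutations permutations per test.
#' @param seed master seed; each cell uses a deterministic sub-seed.
#' @param alpha fixed significance threshold for the flag column.
#' @param options statistic options, see \code{\link{networkStatistic}}.
#' @param adjust also append \code{pBonferroni} and \code{pBH} columns
#'   (extensions, off by default).
#' @return data.frame with columns pathway, statistic, group1, group2,
#'   value1, value2, difference, pValue, significant.
#' @export
pairwiseComparisonTable <- function(groups, pathways,
                                    statistics = c("sipAUC", "cpl"),
                                    nPermutations = 10000L, seed = 1L,
                                    alpha = 0.001, options = list(),
                                    adjust = FALSE) {
  stopifnot(length(groups) >= 2L, length(pathways) >= 1L)
  if (is(pathways, "Pathway")) pathways <- list(pathways)
  pairs <- utils::combn(names(groups), 2L)
  rows <- list()
  cell <- 0L
  for (pw in pathways) {
    sub <- lapply(groups, extractPathway, pathway = pw)
    for (st in statistics) {
      for (k in seq_len(ncol(pairs))) {
        g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
        cell <- cell + 1L
        res <- permutationTest(sub[[g1]], sub[[g2]], statistic = st,
                               nPermutations = nPermutations,
                               seed = .groupSeed(seed, cell),
                               options = options)
        rows[[cell]] <- data.frame(
          pathway = pw@name, statistic = st, group1 = g1, group2 = g2,
          value1 = networkStatistic(sub[[g1]], st, options),
          value2 = networkStatistic(sub[[g2]], st, options),
          difference = observedDifference(res),
          pValue = pValue(res),
          significant = pValue(res) < alpha)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) {
    out$pBonferroni <- stats::p.adjust(out$pValue, "bonferroni")
    out$pBH <- stats::p.adjust(out$pValue, "BH")
  }
  out
}
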