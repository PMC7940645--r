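# Weighted graph-theory indices on the edge-filtered connectivity network.
# Path lengths use the dissimilarity d as edge length; eigenvector
# centrality uses the similarity 1 - d as edge weight.

#' Edge-filter a distance matrix into a weighted graph
#'
#' Two retain rules: \code{"threshold"} keeps all pairs with
#' \eqn{d_{ij} \le} \code{threshold}; \code{"density"} keeps the strongest
#' (smallest-distance) fraction of pairs. The rule applied is recorded on
#' the returned graph.
#'
#' @param dist a \linkS4class{DistanceMatrix}.
#' @param threshold distance threshold in (0, 1] (rule \code{"threshold"}).
#' @param rule \code{"threshold"} or \code{"density"}.
#' @param density fraction of strongest edges to retain (rule
#'   \code{"density"}), in (0, 1].
#' @return A \linkS4class{WeightedGraph}.
#' @export
filterEdges <- function(dist, threshold = 0.5,
                        rule = c("threshold", "density"), density = 0.2) {
  stopifnot(is(dist, "DistanceMatrix"))
  rule <- match.arg(rule)
  d <- distValues(dist)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  if (rule == "threshold") {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold > 1)
      stop("threshold must lie in (0, 1]")
    keep <- w <= threshold
    label <- sprintf("threshold<=%.4g", threshold)
  } else {
    if (!is.numeric(density) || length(density) != 1L ||
        density <= 0 || density > 1)
      stop("density must lie in (0, 1]")
    m <- ceiling(density * length(w))
    ord <- order(w, idx[, 1L], idx[, 2L])
    keep <- seq_along(w) %in% ord[seq_len(m)]
    label <- sprintf("density=%.4g", density)
  }
  if (any(keep & w == 0))
    stop("coincident ROIs (zero distance) cannot form a weighted edge")
  edges <- data.frame(from = rownames(d)[idx[keep, 1L]],
                      to = rownames(d)[idx[keep, 2L]],
                      length = w[keep])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("WeightedGraph", nodes = rownames(d), edges = edges,
      retainRule = label)
}

# igraph view of a WeightedGraph; isolated nodes kept.
.asIgraph <- function(g) {
  igraph::graph_from_data_frame(g@edges, directed = FALSE,
                                vertices = data.frame(name = g@nodes))
}

# All-pairs weighted shortest-path matrix (edge length = dissimilarity).
.pathLengths <- function(g) {
  ig <- .asIgraph(g)
  igraph::distances(ig, weights = igraph::E(ig)$length)
}

#' Characteristic path length (CPL)
#'
#' Mean weighted shortest-path length over all connected ROI pairs.
#' Disconnected pairs are excluded from the mean and counted alongside
#' rather than imputed, so the value is undefined (NA) only when no pair is
#' connected.
#'
#' @param g a \linkS4class{WeightedGraph} with >= 2 nodes.
#' @return List with \code{value} (NA if no connected pair) and
#'   \code{nUnreachablePairs}.
#' @export
characteristicPathLength <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  if (length(g@nodes) < 2L) stop("CPL needs at least 2 nodes")
  sp <- .pathLengths(g)[upper.tri(diag(length(g@nodes)))]
  finite <- is.finite(sp)
  list(value = if (any(finite)) mean(sp[finite]) else NA_real_,
       nUnreachablePairs = sum(!finite))
}

#' Network diameter (ND)
#'
#' Maximum finite weighted shortest-path length; infinite (disconnected)
#' pairs are excluded and counted.
#'
#' @param g a \linkS4class{WeightedGraph} with >= 2 nodes.
#' @return List with \code{value} (NA if no connected pair) and
#'   \code{nUnreachablePairs}.
#' @export
networkDiameter <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  if (length(g@nodes) < 2L) stop("network diameter needs at least 2 nodes")
  sp <- .pathLengths(g)[upper.tri(diag(length(g@nodes)))]
  finite <- is.finite(sp)
  list(value = if (any(finite)) max(sp[finite]) else NA_real_,
       nUnreachablePairs = sum(!finite))
}

#' Eigenvector centrality (EC)
#'
#' Principal eigenvector of the similarity-weighted adjacency (weight =
#' 1 - length), computed on the largest connected component when the graph
#' is disconnected (with a warning). Scores are nonnegative, normalised to
#' unit maximum; nodes outside the scored component get NA.
#'
#' @param g a \linkS4class{WeightedGraph} with >= 1 edge.
#' @return Named numeric vector of centrality scores over all nodes.
#' @export
eigenvectorCentrality <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  if (!nrow(g@edges)) stop("eigenvector centrality needs a non-empty graph")
  ig <- .asIgraph(g)
  comp <- igraph::components(ig)
  keep <- g@nodes
  if (comp$no > 1L) {
    warning("graph is disconnected; scoring the largest component only")
    big <- which.max(comp$csize)
    keep <- g@nodes[comp$membership[g@nodes] == big]
  }
  a <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  e <- g@edges[g@edges$from %in% keep & g@edges$to %in% keep, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    a[e$from[k], e$to[k]] <- 1 - e$length[k]
    a[e$to[k], e$from[k]] <- 1 - e$length[k]
  }
  es <- eigen(a, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (sum(v) < 0) v <- -v       # Perron vector: fix sign deterministically
  v <- pmax(v, 0)
  v <- v / max(v)
  out <- rep(NA_real_, length(g@nodes))
  names(out) <- g@nodes
  out[keep] <- v
  out
}
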