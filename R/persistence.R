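# Zero-dimensional persistent homology of a graph filtration.
#
# Everything flows from one sweep: sort ROI pairs by dissimilarity and merge
# components bottom-up. The MST edge weights are exactly the component merge
# thresholds, so the Betti-0 breakpoints, the barcode deaths, the
# single-linkage merge heights and the SIP AUC are all computed from the
# same Kruskal pass -- never from a sampled lambda grid.

# Kruskal MST with deterministic tie order (weight, then smaller index,
# then larger index). Returns edges in acceptance order.
.mstKruskal <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 ROIs for a spanning tree")
  idx <- which(upper.tri(d), arr.ind = TRUE)  # row < col, column-major
  w <- d[upper.tri(d)]
  ord <- order(w, idx[, 1L], idx[, 2L])
  fi <- idx[ord, 1L]; fj <- idx[ord, 2L]; fw <- w[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ei <- integer(n - 1L); ej <- integer(n - 1L); ew <- numeric(n - 1L)
  got <- 0L
  for (k in seq_along(fw)) {
    ra <- find(fi[k]); rb <- find(fj[k])
    if (ra != rb) {
      parent[rb] <- ra
      got <- got + 1L
      ei[got] <- fi[k]; ej[got] <- fj[k]; ew[got] <- fw[k]
      if (got == n - 1L) break
    }
  }
  data.frame(i = ei, j = ej, weight = ew)
}

# Total MST weight only, via vectorised Prim (dense O(n^2)); the total is
# tie-invariant, so it always equals sum(.mstKruskal(d)$weight). Hot path
# for permutation testing, where only the SIP AUC scalar is needed.
.mstTotal <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 ROIs for a spanning tree")
  intree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[, 1L]
  best[1L] <- Inf
  total <- 0
  for (k in seq_len(n - 1L)) {
    v <- which.min(best)
    total <- total + best[[v]]
    intree[v] <- TRUE
    best <- pmin(best, d[, v])
    best[intree] <- Inf
  }
  total
}

# Single-linkage ultrametric + merge tree from the ascending MST edges.
# Components merge left-to-right by smallest member index, which fixes the
# dendrogram leaf order deterministically.
.singleLinkageSweep <- function(d, mst) {
  n <- nrow(d)
  labels <- rownames(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  members <- as.list(seq_len(n))      # root -> member indices
  code <- rep(NA_integer_, n)         # root -> merge-step index
  sld <- matrix(0, n, n, dimnames = dimnames(d))
  hmerge <- matrix(0L, n - 1L, 2L)
  hheight <- numeric(n - 1L)
  ev_lambda <- numeric(n - 1L)
  ev_a <- character(n - 1L); ev_b <- character(n - 1L)
  ev_sa <- integer(n - 1L); ev_sb <- integer(n - 1L)
  for (s in seq_len(n - 1L)) {
    ra <- find(mst$i[s]); rb <- find(mst$j[s])
    if (min(members[[rb]]) < min(members[[ra]])) { tmp <- ra; ra <- rb; rb <- tmp }
    ma <- members[[ra]]; mb <- members[[rb]]
    w <- mst$weight[s]
    sld[ma, mb] <- w
    sld[mb, ma] <- w
    hmerge[s, 1L] <- if (is.na(code[ra])) -ma[1L] else code[ra]
    hmerge[s, 2L] <- if (is.na(code[rb])) -mb[1L] else code[rb]
    hheight[s] <- w
    ev_lambda[s] <- w
    ev_a[s] <- labels[min(ma)]; ev_b[s] <- labels[min(mb)]
    ev_sa[s] <- length(ma); ev_sb[s] <- length(mb)
    parent[rb] <- ra
    members[[ra]] <- c(ma, mb)
    code[ra] <- s
  }
  list(sld = sld, hmerge = hmerge, hheight = hheight,
       merges = data.frame(lambda = ev_lambda, step = seq_len(n - 1L),
                           componentA = ev_a, sizeA = ev_sa,
                           componentB = ev_b, sizeB = ev_sb))
}

# Leaf order of an hclust merge matrix (iterative depth-first traversal).
.hclustOrder <- function(merge) {
  stack <- nrow(merge)
  out <- integer(0)
  while (length(stack)) {
    k <- stack[1L]
    stack <- stack[-1L]
    if (k < 0) out <- c(out, -k)
    else stack <- c(merge[k, 1L], merge[k, 2L], stack)
  }
  out
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with a deterministic tie order (weight, then smaller
#' ROI index, then larger). Under exact ties the edge set may be non-unique,
#' but the total weight, the Betti-0 curve, the barcode and the
#' single-linkage ultrametric are tie-invariant.
#'
#' @param dist a \linkS4class{DistanceMatrix} with >= 2 ROIs.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (ROI names), sorted by ascending weight.
#' @export
computeMST <- function(dist) {
  stopifnot(is(dist, "DistanceMatrix"))
  d <- distValues(dist)
  mst <- .mstKruskal(d)
  data.frame(from = rownames(d)[mst$i], to = rownames(d)[mst$j],
             weight = mst$weight)
}

#' Exact Betti-0 curve of the filtration
#'
#' Component count of the thresholded network (edge present iff
#' \eqn{d_{ij} \le \lambda}) as a function of the filtration value. The
#' breakpoints are exactly the distinct MST edge weights; the count drops by
#' the number of MST edges sharing each value.
#'
#' @param dist a \linkS4class{DistanceMatrix}.
#' @param ceiling upper end of the filtration range; the default 1 makes the
#'   AUC comparable across networks of equal size. Use \code{"max"} for the
#'   largest observed merge value instead.
#' @return A \linkS4class{Betti0Curve}.
#' @export
betti0Curve <- function(dist, ceiling = 1) {
  stopifnot(is(dist, "DistanceMatrix"))
  d <- distValues(dist)
  .betti0FromWeights(.mstKruskal(d)$weight, nrow(d), ceiling)
}

.betti0FromWeights <- function(weights, n, ceiling = 1) {
  if (identical(ceiling, "max")) ceiling <- max(weights)
  runs <- rle(sort(weights))
  new("Betti0Curve",
      breakpoints = runs$values,
      counts = as.integer(c(n, n - cumsum(runs$lengths))),
      ceiling = as.numeric(ceiling))
}

#' Full zero-dimensional persistence analysis of one network
#'
#' One Kruskal sweep yields the MST, the exact Betti-0 curve, the barcode
#' (one bar per ROI; the last surviving component's death is recorded at the
#' filtration ceiling), the single-linkage ultrametric with its merge tree,
#' and the SIP AUC. The identity \code{sipAUC == 1 + sum(MST weights)} is
#' verified at construction.
#'
#' @param dist a \linkS4class{DistanceMatrix} with >= 2 ROIs.
#' @param ceiling filtration ceiling, 1 by default (or \code{"max"}).
#' @return A \linkS4class{PersistenceResult}.
#' @examples
#' d <- matrix(c(0, .1, .4, .1, 0, .3, .4, .3, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' ph <- persistentHomology(DistanceMatrix(d))
#' sipAUC(ph)
#' @export
persistentHomology <- function(dist, ceiling = 1) {
  stopifnot(is(dist, "DistanceMatrix"))
  d <- distValues(dist)
  n <- nrow(d)
  if (n < 2L) stop("persistence needs at least 2 ROIs")
  mst <- .mstKruskal(d)
  if (identical(ceiling, "max")) ceiling <- max(mst$weight)
  if (max(mst$weight) > ceiling)
    stop("filtration ceiling is below the largest merge value")
  betti <- .betti0FromWeights(mst$weight, n, ceiling)
  sl <- .singleLinkageSweep(d, mst)
  bars <- data.frame(birth = rep(0, n),
                     death = c(sort(mst$weight), ceiling))
  auc <- sipAUC(betti)
  new("PersistenceResult",
      betti = betti, bars = bars,
      mst = data.frame(from = rownames(d)[mst$i], to = rownames(d)[mst$j],
                       weight = mst$weight),
      sld = sl$sld, merges = sl$merges,
      hmerge = sl$hmerge, hheight = sl$hheight, auc = auc)
}

#' Single-linkage clustering of a distance matrix
#'
#' Convenience wrapper returning the ultrametric and merge tree only.
#'
#' @param dist a \linkS4class{DistanceMatrix} with >= 2 ROIs.
#' @return List with elements \code{sld} (minimax path ultrametric matrix)
#'   and \code{mergeTree} (data.frame of merge events ordered by lambda).
#' @export
singleLinkage <- function(dist) {
  ph <- persistentHomology(dist)
  list(sld = singleLinkageMatrix(ph), mergeTree = mergeTree(ph))
}

#' @rdname asHclust
#' @export
setMethod("asHclust", "PersistenceResult", function(x) {
  structure(list(merge = x@hmerge, height = x@hheight,
                 order = .hclustOrder(x@hmerge),
                 labels = rownames(x@sld), method = "single",
                 call = match.call(), dist.method = "1-|r|"),
            class = "hclust")
})

#' Export the single-linkage dendrogram as Newick
#'
#' Branch lengths are scaled so that the depth of each internal node equals
#' its merge height, making the written tree ultrametric in filtration units.
#'
#' @param x a \linkS4class{PersistenceResult}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeNewick <- function(x, path) {
  stopifnot(is(x, "PersistenceResult"))
  phy <- ape::as.phylo(asHclust(x))
  phy$edge.length <- phy$edge.length * 2  # as.phylo halves hclust heights
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Thresholded network snapshot
#'
#' All ROI pairs with \eqn{d_{ij} \le \lambda}, plus connected-component
#' labels -- the abstract form of the filtration-snapshot network maps.
#'
#' @param dist a \linkS4class{DistanceMatrix}.
#' @param lambda filtration value in [0, 1].
#' @return List with \code{edges} (data.frame from, to, weight) and
#'   \code{components} (named integer vector of component labels).
#' @export
snapshotGraph <- function(dist, lambda) {
  stopifnot(is(dist, "DistanceMatrix"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  d <- distValues(dist)
  n <- nrow(d)
  idx <- which(upper.tri(d) & d <= lambda, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  comp <- .componentsFromEdges(n, idx[, 1L], idx[, 2L])
  names(comp) <- rownames(d)
  list(edges = data.frame(from = rownames(d)[idx[, 1L]],
                          to = rownames(d)[idx[, 2L]],
                          weight = d[idx]),
       components = comp)
}

#' Write the Betti-0 curve as CSV
#'
#' One row per constant interval: \code{lambda_from, lambda_to, betti0}.
#'
#' @param x a \linkS4class{PersistenceResult} or \linkS4class{Betti0Curve}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeBettiCSV <- function(x, path) {
  curve <- if (is(x, "PersistenceResult")) bettiCurve(x) else x
  stopifnot(is(curve, "Betti0Curve"))
  edges <- c(0, curve@breakpoints, curve@ceiling)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("lambda_from,lambda_to,betti0", con)
  for (k in seq_along(curve@counts))
    writeLines(paste(.fmtNum(edges[k]), .fmtNum(edges[k + 1L]),
                     curve@counts[k], sep = ","), con)
  invisible(path)
}

#' Write the barcode as CSV
#'
#' @param x a \linkS4class{PersistenceResult}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeBarcodeCSV <- function(x, path) {
  stopifnot(is(x, "PersistenceResult"))
  bars <- barcode(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("bar,birth,death", con)
  for (k in seq_len(nrow(bars)))
    writeLines(paste(k, .fmtNum(bars$birth[k]), .fmtNum(bars$death[k]),
                     sep = ","), con)
  invisible(path)
}

#' Write a filtration snapshot as CSV
#'
#' Edge list with a component-label column; isolated ROIs appear as rows
#' with empty \code{to} so every component is represented.
#'
#' @param dist a \linkS4class{DistanceMatrix}.
#' @param lambda filtration value in [0, 1].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeSnapshotCSV <- function(dist, lambda, path) {
  snap <- snapshotGraph(dist, lambda)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("from,to,weight,component", con)
  e <- snap$edges
  for (k in seq_len(nrow(e)))
    writeLines(paste(e$from[k], e$to[k], .fmtNum(e$weight[k]),
                     snap$components[[e$from[k]]], sep = ","), con)
  isolated <- names(snap$components)[
    !(names(snap$components) %in% c(e$from, e$to))]
  for (r in isolated)
    writeLines(paste(r, "", "", snap$components[[r]], sep = ","), con)
  invisible(path)
}
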