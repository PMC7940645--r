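# Independent oracles and fixture builders. These deliberately use naive,
# exhaustive algorithms (or unrelated library routines) so they share no
# code with the package's implementations.

# The worked 4-node network used throughout: hand-checkable distances.
worked4 <- function() {
  nm <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(nm, nm))
  d["A", "B"] <- 0.1; d["B", "C"] <- 0.3; d["A", "C"] <- 0.4
  d["C", "D"] <- 0.5; d["B", "D"] <- 0.8; d["A", "D"] <- 0.9
  DistanceMatrix(d + t(d))
}

# Random dissimilarity in [0,1], zero diagonal; caller controls the seed.
randomDistance <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  DistanceMatrix(d + t(d))
}

# Brute-force minimum spanning tree total: try every (n-1)-subset of edges,
# keep the cheapest one that spans.
bruteMSTTotal <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    lab <- seq_len(n)
    for (e in comb) {
      a <- lab[pairs[e, 1]]; b <- lab[pairs[e, 2]]
      lab[lab == b] <- a
    }
    if (length(unique(lab)) == 1L)
      best <- min(best, sum(d[pairs[comb, , drop = FALSE]]))
  }
  best
}

# Exhaustive minimax path distance: enumerate every simple path i -> j and
# take the minimum over paths of the maximum edge weight.
enumMinimaxSLD <- function(d) {
  n <- nrow(d)
  out <- matrix(0, n, n, dimnames = dimnames(d))
  walk <- function(current, target, visited, maxw) {
    if (current == target) return(maxw)
    best <- Inf
    for (nxt in setdiff(seq_len(n), visited)) {
      v <- walk(nxt, target, c(visited, nxt), max(maxw, d[current, nxt]))
      best <- min(best, v)
    }
    best
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- walk(i, j, i, 0)
  }
  out
}

# Independent connected-component counter: label propagation to fixpoint.
labelPropComponents <- function(n, from, to) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_along(from)) {
      lo <- min(lab[from[k]], lab[to[k]])
      if (lab[from[k]] != lo || lab[to[k]] != lo) {
        lab[lab == lab[from[k]]] <- lo
        lab[lab == lab[to[k]]] <- lo
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
}

# Brute-force all-pairs shortest paths: Floyd-Warshall relaxation over
# every intermediate node (no priority queue, no igraph).
bruteShortestPaths <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges$from[k], edges$to[k]] <- edges$length[k]
    D[edges$to[k], edges$from[k]] <- edges$length[k]
  }
  for (v in seq_len(n))
    D <- pmin(D, outer(D[, v], D[v, ], "+"))
  D
}

# A small uptake table with known values for correlation oracles.
smallUptake <- function() {
  vals <- cbind(x = c(1, 2, 4, 5, 9),
                y = c(2, 1, 5, 8, 7),
                z = c(9, 7, 5, 3, 1))
  UptakeMatrix(vals, groupLabel = "toy")
}

# Two-pass naive Pearson correlation (explicit sums, no stats::cor).
naivePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}
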