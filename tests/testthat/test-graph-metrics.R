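# Weighted graph indices on the edge-filtered network.

test_that("edge filtering retains the pairs at or below the threshold", {
  dm <- worked4()
  g <- filterEdges(dm, 0.5)
  expect_equal(nrow(graphEdges(g)), 4L)
  key <- paste(graphEdges(g)$from, graphEdges(g)$to)
  expect_setequal(key, c("A B", "A C", "B C", "C D"))
  expect_setequal(graphEdges(g)$length, c(0.1, 0.4, 0.3, 0.5))

  expect_equal(nrow(graphEdges(filterEdges(dm, 1))), 6L)       # complete
  expect_equal(nrow(graphEdges(filterEdges(dm, 0.05))), 0L)    # below min d
  expect_error(filterEdges(dm, 0), "\\(0, 1\\]")
  expect_error(filterEdges(dm, 1.2), "\\(0, 1\\]")
})

test_that("density-based filtering keeps the strongest fraction of pairs", {
  dm <- worked4()
  g <- filterEdges(dm, rule = "density", density = 0.5)
  expect_equal(nrow(graphEdges(g)), 3L)  # ceiling(0.5 * 6)
  expect_setequal(graphEdges(g)$length, c(0.1, 0.3, 0.4))
  expect_match(g@retainRule, "density")
})

test_that("CPL and ND reproduce the hand-computed complete-graph values", {
  g <- filterEdges(worked4(), 1)
  # shortest paths: AB=.1 AC=.4 AD=.9 BC=.3 BD=.8 CD=.5 (direct edges win)
  expect_equal(characteristicPathLength(g)$value, 0.5)
  expect_equal(networkDiameter(g)$value, 0.9)
  expect_equal(characteristicPathLength(g)$nUnreachablePairs, 0L)
})

test_that("CPL and ND closed forms hold on simple graphs", {
  # two nodes, one edge
  d2 <- DistanceMatrix(matrix(c(0, 0.7, 0.7, 0), 2, 2))
  g2 <- filterEdges(d2, 1)
  expect_equal(characteristicPathLength(g2)$value, 0.7)
  expect_equal(networkDiameter(g2)$value, 0.7)

  # path graph a-b-c with unit-ish lengths: CPL = (1+1+2)/3 in length units
  nm <- c("a", "b", "c")
  d <- matrix(1, 3, 3, dimnames = list(nm, nm))
  d["a", "b"] <- d["b", "a"] <- 0.4
  d["b", "c"] <- d["c", "b"] <- 0.4
  diag(d) <- 0
  g3 <- filterEdges(DistanceMatrix(d), 0.4)
  expect_equal(characteristicPathLength(g3)$value, (0.4 + 0.4 + 0.8) / 3)
  expect_equal(networkDiameter(g3)$value, 0.8)

  # star graph with four unit-weight spokes: diameter 2 spokes
  nm <- c("hub", "s1", "s2", "s3", "s4")
  d <- matrix(1, 5, 5, dimnames = list(nm, nm))
  d["hub", -1] <- d[-1, "hub"] <- 0.5
  diag(d) <- 0
  gs <- filterEdges(DistanceMatrix(d), 0.5)
  expect_equal(networkDiameter(gs)$value, 1.0)
})

test_that("disconnected pairs are excluded and counted, never imputed", {
  dm <- worked4()
  g <- filterEdges(dm, 0.35)  # edges AB (.1), BC (.3); D isolated
  cpl <- characteristicPathLength(g)
  expect_equal(cpl$value, (0.1 + 0.3 + 0.4) / 3)
  expect_equal(cpl$nUnreachablePairs, 3L)
  nd <- networkDiameter(g)
  expect_equal(nd$value, 0.4)

  # empty graph: undefined, reported as NA, not 0
  g0 <- filterEdges(dm, 0.05)
  expect_true(is.na(characteristicPathLength(g0)$value))
  expect_equal(characteristicPathLength(g0)$nUnreachablePairs, 6L)
})

test_that("CPL and ND agree with a brute-force all-pairs oracle on random graphs", {
  set.seed(61)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    dm <- randomDistance(n)
    th <- runif(1, 0.3, 1)
    g <- filterEdges(dm, th)
    if (!nrow(graphEdges(g))) next
    D <- bruteShortestPaths(graphNodes(g), graphEdges(g))
    sp <- D[upper.tri(D)]
    finite <- is.finite(sp)
    cpl <- characteristicPathLength(g)
    nd <- networkDiameter(g)
    if (any(finite)) {
      expect_equal(cpl$value, mean(sp[finite]), tolerance = 1e-12)
      expect_equal(nd$value, max(sp[finite]), tolerance = 1e-12)
    } else {
      expect_true(is.na(cpl$value))
    }
    expect_equal(cpl$nUnreachablePairs, sum(!finite))
    # CPL <= ND whenever defined
    if (any(finite)) expect_lte(cpl$value, nd$value)
  }
})

test_that("removing edges never decreases CPL over still-connected pairs", {
  set.seed(62)
  for (rep in 1:20) {
    dm <- randomDistance(8)
    g_loose <- filterEdges(dm, 0.9)
    g_tight <- filterEdges(dm, 0.6)
    if (!nrow(graphEdges(g_tight))) next
    Dl <- bruteShortestPaths(graphNodes(g_loose), graphEdges(g_loose))
    Dt <- bruteShortestPaths(graphNodes(g_tight), graphEdges(g_tight))
    still <- is.finite(Dt[upper.tri(Dt)])
    if (!any(still)) next
    expect_true(all(Dt[upper.tri(Dt)][still] >= Dl[upper.tri(Dl)][still] - 1e-12))
  }
})

test_that("eigenvector centrality respects symmetry, dominance and the eigen-equation", {
  # complete graph with equal weights: all scores equal 1
  d <- matrix(0.4, 5, 5); diag(d) <- 0
  g <- filterEdges(DistanceMatrix(d), 1)
  ec <- eigenvectorCentrality(g)
  expect_equal(unname(ec), rep(1, 5), tolerance = 1e-10)

  # star graph: the hub dominates
  nm <- c("hub", "s1", "s2", "s3")
  ds <- matrix(1, 4, 4, dimnames = list(nm, nm))
  ds["hub", -1] <- ds[-1, "hub"] <- 0.3
  diag(ds) <- 0
  ecs <- eigenvectorCentrality(filterEdges(DistanceMatrix(ds), 0.3))
  expect_equal(names(which.max(ecs)), "hub")
  expect_equal(unname(ecs["hub"]), 1)

  # random graphs: scores match a dense eigen-decomposition oracle and
  # satisfy the eigen-equation residual bound
  set.seed(63)
  for (rep in 1:10) {
    dm <- randomDistance(6)
    g <- filterEdges(dm, 0.95)
    comp <- igraph::components(phnet:::.asIgraph(g))
    if (comp$no > 1) next
    ec <- eigenvectorCentrality(g)
    a <- matrix(0, 6, 6, dimnames = list(graphNodes(g), graphNodes(g)))
    e <- graphEdges(g)
    for (k in seq_len(nrow(e))) {
      a[e$from[k], e$to[k]] <- a[e$to[k], e$from[k]] <- 1 - e$length[k]
    }
    es <- eigen(a, symmetric = TRUE)
    vref <- abs(es$vectors[, 1]) / max(abs(es$vectors[, 1]))
    expect_equal(unname(ec), unname(vref), tolerance = 1e-8)
    mu <- es$values[1]
    v <- ec / sqrt(sum(ec^2))
    expect_lt(sqrt(sum((a %*% v - mu * v)^2)), 1e-8)
  }
})

test_that("eigenvector centrality on a disconnected graph warns and scores the largest component", {
  dm <- worked4()
  g <- filterEdges(dm, 0.35)  # A-B-C connected, D isolated
  expect_warning(ec <- eigenvectorCentrality(g), "disconnected")
  expect_true(is.na(ec["D"]))
  expect_equal(sum(!is.na(ec)), 3L)
  expect_error(eigenvectorCentrality(filterEdges(dm, 0.05)), "non-empty")
})
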