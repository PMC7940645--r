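# Zero-dimensional persistence: MST, Betti-0, barcode, single linkage, SIP.

test_that("the worked 4-node network reproduces all hand-derived values", {
  dm <- worked4()
  ph <- persistentHomology(dm)

  mst <- mstEdges(ph)
  expect_equal(sort(mst$weight), c(0.1, 0.3, 0.5))
  expect_equal(sum(mst$weight), 0.9)

  # component count 4 on [0, .1), 3 on [.1, .3), 2 on [.3, .5), 1 on [.5, 1]
  expect_equal(bettiAt(ph, c(0, 0.05, 0.1, 0.2, 0.3, 0.45, 0.5, 1)),
               c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L))
  expect_equal(bettiCurve(ph)@breakpoints, c(0.1, 0.3, 0.5))

  expect_equal(sipAUC(ph), 1.9)               # 4(.1)+3(.2)+2(.2)+1(.5)
  expect_equal(sipAUC(ph), 1 + sum(mst$weight))

  bars <- barcode(ph)
  expect_true(all(bars$birth == 0))
  expect_equal(sort(bars$death), c(0.1, 0.3, 0.5, 1))

  sld <- singleLinkageMatrix(ph)
  expect_equal(sld["A", "B"], 0.1)
  expect_equal(unname(sld["A", "C"]), 0.3)
  expect_equal(unname(sld["B", "C"]), 0.3)
  expect_equal(unname(sld[c("A", "B", "C"), "D"]), rep(0.5, 3))
})

test_that("MST handles trivial and degenerate inputs", {
  d2 <- DistanceMatrix(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  mst <- computeMST(d2)
  expect_equal(nrow(mst), 1L)
  expect_equal(mst$weight, 0.3)

  # all-equal weights: any tree works, total is (n-1)*w
  for (n in c(3, 5, 8)) {
    d <- matrix(0.4, n, n); diag(d) <- 0
    expect_equal(sum(computeMST(DistanceMatrix(d))$weight), (n - 1) * 0.4)
  }

  expect_error(computeMST(DistanceMatrix(matrix(0, 1, 1))), "at least 2")
})

test_that("MST total weight matches exhaustive spanning-tree enumeration", {
  expect_equal(sum(mstEdges(persistentHomology(worked4()))$weight),
               bruteMSTTotal(distValues(worked4())))
  set.seed(41)
  for (rep in 1:8) {
    dm <- randomDistance(sample(4:6, 1))
    expect_equal(sum(computeMST(dm)$weight), bruteMSTTotal(distValues(dm)),
                 tolerance = 1e-12)
  }
})

test_that("Betti-0 counts match an independent component count at random thresholds", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    dm <- randomDistance(n)
    lam <- runif(1)
    d <- distValues(dm)
    idx <- which(upper.tri(d) & d <= lam, arr.ind = TRUE)
    expect_identical(bettiAt(betti0Curve(dm), lam),
                     labelPropComponents(n, idx[, 1], idx[, 2]))
  }
})

test_that("Betti-0 curve handles degenerate distance matrices", {
  # all distances zero: one component for every lambda >= 0
  dz <- DistanceMatrix(matrix(0, 5, 5))
  expect_equal(bettiAt(betti0Curve(dz), c(0, 0.5, 1)), c(1L, 1L, 1L))
  expect_equal(sipAUC(betti0Curve(dz)), 1)

  # identity correlation: all off-diagonal d = 1, n components until 1
  d1 <- matrix(1, 6, 6); diag(d1) <- 0
  curve <- betti0Curve(DistanceMatrix(d1))
  expect_equal(bettiAt(curve, c(0, 0.99, 1)), c(6L, 6L, 1L))
  expect_equal(sipAUC(curve), 6)  # the ceiling case: AUC = n
})

test_that("single-linkage ultrametric equals exhaustive minimax-path enumeration", {
  set.seed(43)
  for (n in c(4, 5, 6, 7)) {
    dm <- randomDistance(n)
    expect_equal(singleLinkageMatrix(persistentHomology(dm)),
                 enumMinimaxSLD(distValues(dm)), tolerance = 1e-12)
  }
})

test_that("single linkage agrees with hclust cophenetic distances", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(4:15, 1)
    dm <- randomDistance(n)
    mine <- singleLinkageMatrix(persistentHomology(dm))
    ref <- as.matrix(stats::cophenetic(
      stats::hclust(stats::as.dist(distValues(dm)), method = "single")))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
  }
})

test_that("single linkage is a fixed point on ultrametric input and ends at the MST max", {
  dm <- worked4()
  sld1 <- singleLinkageMatrix(persistentHomology(dm))
  sld2 <- singleLinkageMatrix(persistentHomology(DistanceMatrix(sld1)))
  expect_equal(sld1, sld2)

  set.seed(45)
  for (rep in 1:5) {
    dm <- randomDistance(8)
    ph <- persistentHomology(dm)
    expect_lte(max(abs(singleLinkageMatrix(ph))), max(mstEdges(ph)$weight) + 1e-15)
    expect_equal(max(singleLinkageMatrix(ph)), max(mstEdges(ph)$weight))
    # sld <= d entrywise
    expect_true(all(singleLinkageMatrix(ph) <= distValues(dm) + 1e-15))
  }
})

test_that("ultrametric inequality holds exactly for every triple", {
  set.seed(46)
  dm <- randomDistance(9)
  sld <- singleLinkageMatrix(persistentHomology(dm))
  n <- nrow(sld)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(sld[i, k], max(sld[i, j], sld[j, k]))
})

test_that("sipAUC - 1 equals the total MST weight on random matrices", {
  set.seed(47)
  for (rep in 1:200) {
    dm <- randomDistance(sample(4:20, 1))
    ph <- persistentHomology(dm)
    expect_lt(abs(sipAUC(ph) - 1 - sum(mstEdges(ph)$weight)), 1e-9)
  }
})

test_that("barcode deaths, MST weights and merge heights agree as multisets", {
  set.seed(48)
  for (rep in 1:30) {
    dm <- randomDistance(sample(4:15, 1))
    ph <- persistentHomology(dm)
    w <- sort(mstEdges(ph)$weight)
    n <- length(w) + 1
    expect_equal(sort(barcode(ph)$death)[1:(n - 1)], w)
    expect_equal(sort(mergeTree(ph)$lambda), w)
    expect_equal(sort(asHclust(ph)$height), w)
  }
})

test_that("decreasing any distance never increases sipAUC, and scaling is equivariant", {
  set.seed(49)
  for (rep in 1:20) {
    dm <- randomDistance(8)
    d <- distValues(dm)
    auc <- sipAUC(persistentHomology(dm))
    # decrease one off-diagonal entry
    idx <- which(upper.tri(d), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 1), ]
    d2 <- d
    d2[pick[1], pick[2]] <- d2[pick[2], pick[1]] <- d[pick[1], pick[2]] * runif(1)
    expect_lte(sipAUC(persistentHomology(DistanceMatrix(d2))), auc + 1e-12)
    # scale all distances by c: MST total scales by c
    cc <- runif(1, 0.1, 1)
    auc_scaled <- sipAUC(persistentHomology(DistanceMatrix(d * cc)))
    expect_equal(auc_scaled - 1, cc * (auc - 1), tolerance = 1e-12)
  }
})

test_that("snapshot graphs threshold edges and label components correctly", {
  dm <- worked4()
  s0 <- snapshotGraph(dm, 0)
  expect_equal(nrow(s0$edges), 0L)
  expect_equal(unname(s0$components), 1:4)

  s25 <- snapshotGraph(dm, 0.25)
  expect_equal(nrow(s25$edges), 1L)
  expect_equal(s25$edges$from, "A")
  expect_equal(s25$edges$to, "B")
  expect_equal(unname(s25$components), c(1L, 1L, 2L, 3L))

  s1 <- snapshotGraph(dm, 1)
  expect_equal(nrow(s1$edges), 6L)  # complete graph
  expect_true(all(s1$components == 1L))

  expect_error(snapshotGraph(dm, 1.5), "\\[0, 1\\]")
  expect_error(snapshotGraph(dm, -0.1), "\\[0, 1\\]")
})

test_that("fast Prim total equals the Kruskal tree total", {
  set.seed(50)
  for (rep in 1:50) {
    dm <- randomDistance(sample(2:15, 1))
    d <- distValues(dm)
    expect_equal(phnet:::.mstTotal(d), sum(phnet:::.mstKruskal(d)$weight),
                 tolerance = 1e-12)
  }
})

test_that("Newick export round-trips leaf names and ultrametric depths", {
  dm <- worked4()
  ph <- persistentHomology(dm)
  path <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(ph, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("A", "B", "C", "D"))
  # root-to-leaf depth equals the final merge height
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(0.5, 4), tolerance = 1e-12)
})

test_that("the filtration ceiling is configurable and caps the last bar", {
  dm <- worked4()
  ph_max <- persistentHomology(dm, ceiling = "max")
  expect_equal(max(barcode(ph_max)$death), 0.5)
  expect_equal(sipAUC(ph_max), 4 * 0.1 + 3 * 0.2 + 2 * 0.2)
  expect_error(persistentHomology(dm, ceiling = 0.4), "ceiling")
})
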