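test_that("correlation distance matches hand-computed Pearson cases", {
  r <- Raster(rbind(c(1, 0, 1, 0),
                    c(1, 0, 1, 0),
                    c(0, 1, 0, 1),
                    c(1, 1, 0, 0)), fps = 4)
  d <- correlationDistance(r)
  expect_equal(d[1, 2], 0)                 # identical rows
  expect_equal(d[1, 3], 2)                 # perfect anticorrelation
  expect_equal(d[1, 4], 1)                 # r = 0 by direct evaluation
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 4))
})

test_that("zero-variance neurons are excluded and reported", {
  r <- Raster(rbind(c(1, 0, 1, 0),
                    c(0, 0, 0, 0),        # silent
                    c(1, 1, 1, 1),        # saturated
                    c(0, 1, 0, 1)), fps = 4)
  d <- correlationDistance(r)
  expect_equal(attr(d, "excluded"), c(2L, 3L))
  expect_equal(attr(d, "neurons"), c(1L, 4L))
  expect_equal(dim(d), c(2L, 2L))
})

test_that("fuzzy graph gives unit weight to nearest neighbors and valid unions", {
  # 3 equidistant points, k = 2: fully connected with equal unit weights
  D <- matrix(1, 3, 3); diag(D) <- 0
  g <- fuzzyKnnGraph(D, 2)
  w <- g@weights
  expect_equal(w[upper.tri(w)], rep(1, 3))

  set.seed(21)
  X <- matrix(rnorm(40), 10, 4)
  D <- as.matrix(dist(X))
  g <- fuzzyKnnGraph(D, 4)
  w <- g@weights
  expect_true(validObject(g))
  # every node's edge to its nearest neighbor has union weight exactly 1
  for (i in 1:10) {
    d <- D[i, ]; d[i] <- Inf
    expect_equal(w[i, which.min(d)], 1)
  }
  expect_error(fuzzyKnnGraph(D, 10), "nNeighbors")
  expect_error(fuzzyKnnGraph(D, 1), "nNeighbors")
})

test_that("probabilistic union lies in [max(wij, wji), 1]", {
  set.seed(4)
  a <- runif(200); b <- runif(200)
  u <- a + b - a * b
  expect_true(all(u >= pmax(a, b) - 1e-12))
  expect_true(all(u <= 1 + 1e-12))
})

test_that("modularity matrix rows vanish and clique modularity is exact", {
  set.seed(8)
  W <- matrix(runif(49), 7, 7); W <- (W + t(W)) / 2; diag(W) <- 0
  g <- adjacencyGraph(W)
  B <- modularityMatrix(g)
  expect_lt(max(abs(rowSums(B@entries))), 1e-9)
  Bg <- modularityMatrix(g, group = 1:7)       # full group: reduces to B
  expect_lt(max(abs(rowSums(Bg@entries))), 1e-9)
  Bsub <- modularityMatrix(g, group = c(2L, 5L, 6L))
  expect_equal(dim(Bsub@entries), c(3L, 3L))

  tri <- adjacencyGraph(cliqueUnion(c(3, 3)))
  expect_equal(modularityScore(tri, rep(1:2, each = 3)), 0.5)
  expect_error(modularityMatrix(adjacencyGraph(matrix(0, 3, 3))), "no edges")
})

test_that("community detection recovers cliques and leaves K1 whole", {
  g <- adjacencyGraph(cliqueUnion(c(4, 4)))
  asg <- detectCommunities(g, consensusRuns = 5, seed = 2)
  expect_equal(nEnsembles(asg), 2L)
  expect_equal(adjustedAgreement(ensembleLabels(asg), rep(1:2, each = 4)), 1)
  expect_equal(modularityQ(asg), oracleQ(g@weights, oraclePartition(g@weights)),
               tolerance = 1e-9)

  cg <- adjacencyGraph(completeGraph(6))
  asg <- detectCommunities(cg, consensusRuns = 5, seed = 2)
  expect_equal(nEnsembles(asg), 1L)            # no positive-gain split exists
})

test_that("detection is deterministic per seed and permutation-equivariant", {
  A <- plantedGraph(c(5, 5, 5), pin = 1, pout = 0.08, seed = 14)
  g <- adjacencyGraph(A)
  a1 <- detectCommunities(g, consensusRuns = 10, seed = 3)
  a2 <- detectCommunities(g, consensusRuns = 10, seed = 3)
  expect_identical(ensembleLabels(a1), ensembleLabels(a2))

  set.seed(31)
  p <- sample(15)
  gp <- adjacencyGraph(A[p, p])
  ap <- detectCommunities(gp, consensusRuns = 10, seed = 3)
  expect_equal(adjustedAgreement(ensembleLabels(ap),
                                 ensembleLabels(a1)[p]), 1)
})

test_that("planted ensembles in a synthetic raster are recovered", {
  out <- generateRaster(smallSynth(K = 3L, seed = 55L))
  asg <- detectEnsembles(out$raster, nNeighbors = 8, consensusRuns = 10,
                         seed = 7)
  ok <- !is.na(ensembleLabels(asg))
  expect_gte(adjustedAgreement(ensembleLabels(asg)[ok],
                               out$truth$labels[ok]), 0.9)
  expect_equal(nEnsembles(asg), 3L)
})

test_that("sortRaster groups by first-activation order and is invertible", {
  m <- rbind(c(0, 0, 1, 0, 0, 0),    # ensemble 1, first active frame 3
             c(0, 0, 0, 1, 0, 0),
             c(1, 0, 0, 0, 0, 0),    # ensemble 2, first active frame 1
             c(0, 1, 0, 0, 0, 0))
  r <- Raster(m, fps = 4)
  asg <- new("EnsembleAssignment", labels = c(1L, 1L, 2L, 2L),
             nEnsembles = 2L, modularityQ = 0, order = integer(0),
             excluded = integer(0))
  s <- sortRaster(r, asg)
  expect_equal(s$communityOrder, c(2L, 1L))    # ensemble 2 fires first
  expect_equal(s$permutation, c(3L, 4L, 1L, 2L))
  expect_equal(activityMatrix(s$raster), m[s$permutation, ])
  # applying the inverse permutation recovers the original raster
  inv <- order(s$permutation)
  expect_equal(activityMatrix(subRaster(s$raster, inv)), m)

  # already sorted raster -> identity permutation
  s2 <- sortRaster(s$raster, new("EnsembleAssignment",
                                 labels = asg@labels[s$permutation],
                                 nEnsembles = 2L, modularityQ = 0,
                                 order = integer(0), excluded = integer(0)))
  expect_equal(s2$permutation, 1:4)
  # unlabeled (excluded) neurons go last
  asgNA <- new("EnsembleAssignment", labels = c(1L, NA, 2L, 2L),
               nEnsembles = 2L, modularityQ = 0, order = integer(0),
               excluded = 2L)
  expect_equal(sortRaster(r, asgNA)$permutation[4], 2L)
  expect_error(sortRaster(subRaster(r, 1:2), asg), "covers")
})

test_that("spectral embedding obeys its shape, determinism and spacing contract", {
  out <- generateRaster(smallSynth(K = 2L, nm = 10L, F = 400L, seed = 77L))
  co <- embedVectors(out$raster, nNeighbors = 6, nComponents = 2, seed = 1)
  expect_equal(dim(co), c(20L, 2L))
  co3 <- embedVectors(out$raster, nNeighbors = 6, nComponents = 3, seed = 1)
  expect_equal(ncol(co3), 3L)
  expect_identical(co, embedVectors(out$raster, nNeighbors = 6,
                                    nComponents = 2, seed = 1))
  # default minimum point spacing is 0.1
  expect_equal(formals(embedVectors)$minDist, 0.1)
  pd <- dist(co)
  expect_equal(min(pd[pd > 0]), 0.1, tolerance = 1e-9)
  expect_error(embedVectors(matrix(rnorm(12), 3, 4), nNeighbors = 6),
               "at least")
})
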