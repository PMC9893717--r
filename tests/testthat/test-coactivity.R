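test_that("coactivity is the per-frame active count and conserves events", {
  r <- Raster(rbind(c(0, 0, 1, 0), c(0, 0, 1, 0), c(0, 0, 1, 0)), fps = 4)
  expect_equal(coactivity(r), c(0L, 0L, 3L, 0L))
  expect_equal(coactivity(Raster(matrix(0L, 4, 6), fps = 4)), rep(0L, 6))
  set.seed(2)
  r <- Raster(matrix(rbinom(200, 1, 0.3), 10, 20), fps = 4)
  expect_equal(sum(coactivity(r)), sum(activityMatrix(r)))
})

test_that("runs test reproduces the closed form and rejects degeneracy", {
  ht <- runsTest(rep(c(2, 0), 5))            # strictly alternating, n1=n2=5
  expect_equal(unname(ht$estimate["T"]), 10)
  expect_equal(unname(ht$estimate["Tbar"]), 6)
  expect_equal(unname(ht$estimate["s_T"]), sqrt(20 / 9), tolerance = 1e-12)
  expect_equal(unname(ht$statistic), 4 / sqrt(20 / 9), tolerance = 1e-12)
  expect_equal(unname(ht$statistic), 2.683, tolerance = 1e-3)
  expect_equal(ht$p.value, 2 * pnorm(-4 / sqrt(20 / 9)), tolerance = 1e-12)
  expect_error(runsTest(rep(3, 10)), "degenerate")
  expect_error(runsTest(c(1, 1, 1)), "degenerate")
})

test_that("runs statistic is invariant under adding a constant", {
  set.seed(5)
  x <- rpois(300, 4)
  expect_equal(runsTest(x)$statistic, runsTest(x + 17.3)$statistic)
})

test_that("both surrogate classes conserve per-neuron event counts", {
  out <- generateRaster(smallSynth(K = 2L, nm = 6L, F = 300L, seed = 44L))
  r <- out$raster
  for (fn in c(surrogateType1, surrogateType2)) {
    s <- fn(r, seed = 9L)
    expect_equal(rowSums(activityMatrix(s)), rowSums(activityMatrix(r)))
    expect_equal(sum(activityMatrix(s)), sum(activityMatrix(r)))
    expect_equal(frameRate(s), frameRate(r))
  }
  # an always-active neuron admits only one configuration
  m <- rbind(rep(1L, 20), rbinom(20, 1, 0.4))
  r2 <- Raster(m, fps = 4)
  expect_equal(activityMatrix(surrogateType1(r2, seed = 1))[1, ], m[1, ])
})

test_that("type-2 surrogates preserve interval multisets and permute orders", {
  m <- matrix(0L, 1, 10)
  m[1, c(3, 6, 7)] <- 1L                     # intervals {3, 1}
  r <- Raster(m, fps = 4)
  seen <- character(0)
  for (s in 1:60) {
    ev <- which(activityMatrix(surrogateType2(r, seed = s))[1, ] == 1L)
    expect_equal(sort(diff(ev)), c(1, 3))    # multiset conserved
    seen <- union(seen, paste(diff(ev), collapse = ","))
  }
  expect_setequal(seen, c("3,1", "1,3"))     # permuted order is reachable

  out <- generateRaster(smallSynth(K = 2L, nm = 6L, F = 400L, seed = 13L))
  s2 <- surrogateType2(out$raster, seed = 5L)
  for (i in seq_len(nNeurons(out$raster))) {
    a <- which(activityMatrix(out$raster)[i, ] == 1L)
    b <- which(activityMatrix(s2)[i, ] == 1L)
    expect_equal(sort(diff(b)), sort(diff(a)))
  }
})

test_that("error-rate estimation is reproducible and calibrated under the null", {
  out <- generateRaster(smallSynth(K = 2L, nm = 10L, F = 800L, seed = 17L))
  r <- out$raster
  a <- estimateErrorRates(r, M = 10, seed = 3L)
  b <- estimateErrorRates(r, M = 10, seed = 3L)
  expect_identical(a[c("alphaHat", "betaHat")], b[c("alphaHat", "betaHat")])
  expect_error(estimateErrorRates(r, M = 0), "M must be")

  # each surrogate is independently re-creatable from its sub-seed
  s5 <- surrogateType1(r, seed = a$subSeeds1[5])
  expect_equal(.runsRejectsOracle(coactivity(s5)), a$rejectType1[5])
  t7 <- surrogateType2(r, seed = a$subSeeds2[7])
  expect_equal(.runsRejectsOracle(coactivity(t7)), a$rejectType2[7])
  # distinct base seeds draw distinct surrogate populations
  expect_false(identical(a$subSeeds1,
                         estimateErrorRates(r, M = 10, seed = 4L)$subSeeds1))

  # type-1 rejection rate approaches the nominal level
  rep <- estimateErrorRates(r, M = 400, seed = 1L)
  expect_lt(abs(rep$alphaHat - 0.05), 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("peak detection matches the worked toy and its invariances", {
  x <- c(rep(1, 9), 9)
  expect_equal(which(peakFlags(detectPeaks(x, 1.0, 2))), 10L)
  expect_false(any(peakFlags(detectPeaks(x, 1.0, 3))))
  expect_false(any(peakFlags(detectPeaks(rep(4, 50), 0.2, 2))))
  set.seed(6)
  y <- rpois(200, 3)
  expect_identical(peakFlags(detectPeaks(y, 0.2, 2)),
                   peakFlags(detectPeaks(3.7 * y, 0.2, 2)))
  expect_error(detectPeaks(y, 0, 2), "windowFraction")
  expect_error(detectPeaks(y, 1.3, 2), "windowFraction")
})

test_that("per-ensemble peaks cover planted epochs and flags imply activity", {
  out <- generateRaster(smallSynth(K = 3L, nm = 8L, F = 1500L, seed = 21L))
  asg <- new("EnsembleAssignment", labels = out$truth$labels,
             nEnsembles = 3L, modularityQ = 0, order = integer(0),
             excluded = integer(0))
  ps <- ensemblePeaks(out$raster, asg)
  expect_length(ps, 3L)
  expect_true(all(vapply(ps, function(p) sum(peakFlags(p)) > 0, NA)))
  # flags only where the ensemble coactivity is non-zero
  for (p in ps) expect_true(all(p@coactivity[peakFlags(p)] > 0))
  # >= 90% of planted epochs have their peak frame flagged
  covered <- 0L; totalEpochs <- 0L
  for (g in 1:3) {
    ep <- out$truth$epochs[out$truth$epochs$ensemble == g, ]
    co <- ps[[g]]@coactivity
    for (i in seq_len(nrow(ep))) {
      w <- ep$start[i]:ep$end[i]
      totalEpochs <- totalEpochs + 1L
      if (peakFlags(ps[[g]])[w[which.max(co[w])]]) covered <- covered + 1L
    }
  }
  expect_gte(covered / totalEpochs, 0.9)
})

test_that("ensembles with degenerate coactivity yield empty sets and a warning", {
  m <- rbind(c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1),  # constant sum = 1
             c(1, 1, 0, 0, 1, 0), c(0, 1, 1, 0, 1, 1))
  r <- Raster(m, fps = 4)
  asg <- new("EnsembleAssignment", labels = c(1L, 1L, 2L, 2L),
             nEnsembles = 2L, modularityQ = 0, order = integer(0),
             excluded = integer(0))
  ws <- capture_warnings(ps <- ensemblePeaks(r, asg))
  expect_match(ws, "not significant", all = TRUE)
  expect_gte(length(ws), 1L)
  expect_false(any(peakFlags(ps[[1]])))
  expect_false(ps[[1]]@significant)
})
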