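mkPeak <- function(id, flags) {
  new("PeakSet", ensembleId = as.integer(id), flags = flags,
      coactivity = as.numeric(flags), threshold = rep(0.5, length(flags)),
      windowFraction = 0.2, nSd = 2, runsP = 0.001, significant = TRUE)
}

flagsAt <- function(n, at) { f <- rep(FALSE, n); f[at] <- TRUE; f }

test_that("activation events merge runs and order by frame", {
  ps <- list(mkPeak(1, flagsAt(20, 3:5)))
  ev <- activationSequence(ps)
  expect_equal(ev$frame, 3L)                  # run collapses to its onset
  expect_equal(ev$ensemble, 1L)

  ps <- list(mkPeak(1, flagsAt(20, c(3, 15))), mkPeak(2, flagsAt(20, 10)))
  ev <- activationSequence(ps)
  expect_equal(ev$frame, c(3L, 10L, 15L))
  expect_equal(ev$ensemble, c(1L, 2L, 1L))

  expect_warning(ev0 <- activationSequence(list(mkPeak(1, rep(FALSE, 5)))),
                 "empty")
  expect_equal(nrow(ev0), 0L)
  expect_warning(activationSequence(list(mkPeak(1, flagsAt(9, 4)),
                                         mkPeak(2, flagsAt(9, 4)))),
                 "simultaneous")
})

test_that("transition graph counts edges and bookkeeps self-loops", {
  ev <- data.frame(frame = c(1, 5, 9, 13), ensemble = c(1, 2, 3, 1))
  tg <- buildTransitionGraph(ev)
  expect_equal(tg@edges$count, c(1L, 1L, 1L))
  expect_setequal(paste(tg@edges$from, tg@edges$to),
                  c("1 2", "2 3", "3 1"))
  expect_equal(sum(tg@selfLoops), 0L)

  ev <- data.frame(frame = c(1, 5, 9), ensemble = c(1, 1, 2))
  tg <- buildTransitionGraph(ev)
  expect_equal(tg@selfLoops[1], 1L)
  expect_equal(tg@edges, data.frame(from = 1L, to = 2L, count = 1L))
})

test_that("totals are conserved and invariant under frame shifts", {
  set.seed(12)
  for (rep in 1:5) {
    lab <- sample(1:4, 30, replace = TRUE)
    ev <- data.frame(frame = cumsum(sample(1:5, 30, TRUE)), ensemble = lab)
    tg <- buildTransitionGraph(ev, 4)
    expect_equal(sum(tg@edges$count) + sum(tg@selfLoops), nrow(ev) - 1L)
    evShift <- transform(ev, frame = frame + 1000L)
    tgs <- buildTransitionGraph(evShift, 4)
    expect_identical(tg@edges, tgs@edges)
    expect_identical(tg@selfLoops, tgs@selfLoops)
  }
})

test_that("graph metrics match hand counts", {
  ring <- buildTransitionGraph(
    data.frame(frame = 1:4, ensemble = c(1, 2, 3, 1)))
  m <- graphMetrics(ring)
  expect_equal(m$totalTransitions, 3L)
  expect_equal(m$maxEdgeShare, 1 / 3)

  rep5 <- buildTransitionGraph(
    data.frame(frame = 1:6, ensemble = rep(c(1, 2), 3)))
  expect_equal(graphMetrics(rep5)$maxEdgeShare,
               3 / 5)                          # A->B x3 of 5 transitions
  single <- buildTransitionGraph(
    data.frame(frame = c(1, 2), ensemble = c(1, 2)))
  expect_equal(graphMetrics(single)$maxEdgeShare, 1)

  empty <- buildTransitionGraph(data.frame(frame = integer(0),
                                           ensemble = integer(0)))
  me <- graphMetrics(empty)
  expect_equal(me$totalTransitions, 0L)
  expect_equal(me$maxEdgeShare, 0)
})

test_that("edge-list export round-trips, DOT and GraphML are well-formed", {
  ev <- data.frame(frame = c(1, 4, 8, 12, 16, 20),
                   ensemble = c(1, 2, 2, 3, 1, 2))
  tg <- buildTransitionGraph(ev, 3)
  f <- withr::local_tempfile()
  exportGraph(tg, f, "edgelist")
  tg2 <- importEdgeList(f, 3)
  expect_identical(tg@edges, tg2@edges)
  expect_identical(tg@selfLoops, tg2@selfLoops)

  # empty graph: header-only file
  fe <- withr::local_tempfile()
  exportGraph(buildTransitionGraph(data.frame(frame = integer(0),
                                              ensemble = integer(0))),
              fe, "edgelist")
  expect_equal(readLines(fe), "from\tto\tcount")

  fd <- withr::local_tempfile(fileext = ".dot")
  exportGraph(tg, fd, "dot")
  dot <- readLines(fd)
  expect_true(any(grepl("digraph", dot)))
  expect_equal(sum(grepl("\\{", dot)), sum(grepl("\\}", dot)))

  fg <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(tg, fg, "graphml")
  gr <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::gsize(gr), nrow(tg@edges) + sum(tg@selfLoops > 0))
  expect_true("count" %in% igraph::edge_attr_names(gr))
  expect_error(exportGraph(tg, f, "gexf"), "arg")
})

test_that("planted sequences are recovered as activation events", {
  cfg <- synthConfig(nNeurons = 18, nFrames = 800, fps = 4,
                     membership = split(1:18, rep(1:3, each = 6)),
                     epochLength = 15, gapLength = 15,
                     sequence = c(1, 2, 3), pActive = 1, pBackground = 0,
                     seed = 2L)
  out <- generateRaster(cfg)
  asg <- new("EnsembleAssignment", labels = out$truth$labels,
             nEnsembles = 3L, modularityQ = 0, order = integer(0),
             excluded = integer(0))
  ev <- activationSequence(ensemblePeaks(out$raster, asg))
  sched <- out$truth$epochs$ensemble
  expect_equal(ev$ensemble, sched[seq_len(nrow(ev))])
  tg <- buildTransitionGraph(ev, 3)
  expect_equal(sum(tg@edges$count) + sum(tg@selfLoops), nrow(ev) - 1L)
})
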