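#' Coactivity time series
#'
#' Per-frame number of simultaneously active neurons: the column sums of the
#' raster. Its sum equals the total event count of the raster.
#'
#' @param raster a [Raster-class].
#' @return Integer vector of length `nFrames(raster)`.
#' @export
coactivity <- function(raster) {
  stopifnot(is(raster, "Raster"))
  as.integer(colSums(activityMatrix(raster)))
}

#' Wald-Wolfowitz runs test around the mean
#'
#' Tests whether a series fluctuates randomly about its mean. The series is
#' dichotomized around its arithmetic mean (values exactly equal to the mean
#' are dropped, the classical convention), `T` is the number of maximal
#' same-sign runs, and the statistic
#' `Z = (T - Tbar) / s_T` with `Tbar = 2 n1 n2 / (n1 + n2) + 1` and
#' `s_T^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1 + n2)^2 (n1 + n2 - 1))`
#' is referred to the standard normal, two-tailed. A structured (clumped)
#' coactivity series produces far fewer runs than expected and a large
#' negative `Z`.
#'
#' @param series numeric vector (e.g. a coactivity series).
#' @return An object of class `"htest"` with `statistic` (Z), `p.value`, and
#'   `estimate` containing `T`, `Tbar`, `s_T`, `n1`, `n2`.
#' @examples
#' runsTest(rep(c(2, 0), 5))  # strictly alternating: T = 10, Z ~ 2.683
#' @export
runsTest <- function(series) {
  x <- as.numeric(series)
  m <- mean(x)
  s <- sign(x - m)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L)
    stop("degenerate series: constant relative to its mean")
  T <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  Tbar <- 2 * n1 * n2 / n + 1
  sT2 <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / (n^2 * (n - 1))
  sT <- sqrt(sT2)
  Z <- (T - Tbar) / sT
  p <- 2 * stats::pnorm(-abs(Z))
  structure(list(
    statistic = c(Z = Z),
    p.value = min(p, 1),
    estimate = c(T = T, Tbar = Tbar, s_T = sT, n1 = n1, n2 = n2),
    alternative = "series is not a random fluctuation around its mean",
    method = "Wald-Wolfowitz runs test (dichotomized around the mean)",
    data.name = deparse(substitute(series))),
    class = "htest")
}

# Event-level surrogate cores. Both operate on per-neuron 1-based frame
# vectors and consume the current RNG stream, so the Raster-returning
# wrappers and the fast error-rate loop draw identical surrogates.
.type1Events <- function(framesList, F) {
  lapply(framesList, function(fr) {
    k <- length(fr)
    if (k == 0L || k == F) fr else sample.int(F, k)
  })
}

.type2Events <- function(framesList, F) {
  lapply(framesList, function(fr) {
    k <- length(fr)
    if (k == 0L) return(fr)
    if (k == 1L) return(sample.int(F, 1L))
    iv <- diff(sort(fr))
    if (length(iv) > 1L) iv <- sample(iv)
    span <- sum(iv)
    start <- sample.int(F - span, 1L)
    start + cumsum(c(0L, iv))
  })
}

.rowFrames <- function(raster) {
  a <- activityMatrix(raster)
  lapply(seq_len(nrow(a)), function(i) which(a[i, ] == 1L))
}

.rasterFromEvents <- function(framesList, F, fps, neuronIds = character(0)) {
  m <- matrix(0L, length(framesList), F)
  for (i in seq_along(framesList)) m[i, framesList[[i]]] <- 1L
  Raster(m, fps, neuronIds)
}

#' Uniform-permutation (type 1) surrogate raster
#'
#' Redraws each neuron's active frames uniformly without replacement over the
#' whole recording, preserving per-neuron event counts, N, F and the frame
#' rate, but destroying all temporal structure. Used to estimate the type-I
#' error of the runs test: the null hypothesis is true for these surrogates.
#'
#' @param raster a [Raster-class].
#' @param seed RNG seed.
#' @return A surrogate [Raster-class].
#' @export
surrogateType1 <- function(raster, seed = 1L) {
  stopifnot(is(raster, "Raster"))
  set.seed(seed)
  .rasterFromEvents(.type1Events(.rowFrames(raster), nFrames(raster)),
                    nFrames(raster), raster@fps, raster@neuronIds)
}

#' Interval-preserving (type 2) surrogate raster
#'
#' Preserves, per neuron, the multiset of inter-event intervals: the interval
#' order is randomly permuted and the first event is placed uniformly in the
#' feasible offset range (neurons with fewer than 2 events are placed
#' uniformly). The per-neuron burst structure survives, so the summed
#' coactivity remains non-random: the null hypothesis is false for these
#' surrogates, which estimates the type-II error of the runs test.
#'
#' @inheritParams surrogateType1
#' @return A surrogate [Raster-class].
#' @export
surrogateType2 <- function(raster, seed = 1L) {
  stopifnot(is(raster, "Raster"))
  set.seed(seed)
  .rasterFromEvents(.type2Events(.rowFrames(raster), nFrames(raster)),
                    nFrames(raster), raster@fps, raster@neuronIds)
}

# TRUE iff the runs test rejects at alphaLevel; degenerate series -> FALSE
# (conservative for both error rates).
.runsRejects <- function(x, alphaLevel) {
  tryCatch(runsTest(x)$p.value < alphaLevel, error = function(e) FALSE)
}

#' Estimate runs-test error rates with surrogate rasters
#'
#' Draws `M` type-1 and `M` type-2 surrogates of the raster and runs the runs
#' test on each surrogate's coactivity series. `alphaHat` is the fraction of
#' type-1 surrogates (null true) on which the test rejects; `betaHat` is the
#' fraction of type-2 surrogates (null false) on which it fails to reject.
#' Each surrogate runs on its own sub-seed, drawn up front from a master RNG
#' stream seeded with `seed` (`subSeeds1[i]` for type 1, `subSeeds2[i]` for
#' type 2, both returned in the report), so the report is reproducible, base
#' seeds give independent surrogate populations, and surrogate `i` is
#' independently re-creatable as `surrogateType1(raster, subSeeds1[i])` /
#' `surrogateType2(raster, subSeeds2[i])`.
#'
#' @param raster a structured [Raster-class].
#' @param M number of surrogates per class.
#' @param alphaLevel nominal two-tailed significance level.
#' @param seed base RNG seed.
#' @return A list of class `"surrogateErrorReport"` with `M`, `alphaHat`,
#'   `betaHat`, `alphaLevel`, `seed`, the per-surrogate rejection flags, and
#'   the per-surrogate sub-seeds.
#' @export
estimateErrorRates <- function(raster, M = 1000L, alphaLevel = 0.05,
                               seed = 1L) {
  stopifnot(is(raster, "Raster"))
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  F <- nFrames(raster)
  framesList <- .rowFrames(raster)
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2L * M)
  rej1 <- logical(M); rej2 <- logical(M)
  for (i in seq_len(M)) {
    set.seed(subSeeds[i])
    ev <- .type1Events(framesList, F)
    rej1[i] <- .runsRejects(tabulate(unlist(ev), F), alphaLevel)
  }
  for (i in seq_len(M)) {
    set.seed(subSeeds[M + i])
    ev <- .type2Events(framesList, F)
    rej2[i] <- .runsRejects(tabulate(unlist(ev), F), alphaLevel)
  }
  structure(list(M = M, alphaHat = mean(rej1), betaHat = mean(!rej2),
                 alphaLevel = alphaLevel, seed = as.integer(seed),
                 rejectType1 = rej1, rejectType2 = rej2,
                 subSeeds1 = subSeeds[seq_len(M)],
                 subSeeds2 = subSeeds[M + seq_len(M)]),
            class = "surrogateErrorReport")
}

#' @export
print.surrogateErrorReport <- function(x, ...) {
  cat(sprintf(
    "Surrogate error report (M = %d, alpha = %g, seed = %d):\n  alphaHat = %.4f  betaHat = %.4f\n",
    x$M, x$alphaLevel, x$seed, x$alphaHat, x$betaHat))
  invisible(x)
}

#' Detect significant coactivity peaks with a dynamic threshold
#'
#' A window of `round(windowFraction * F)` frames slides one frame at a time;
#' a frame is flagged when its coactivity strictly exceeds the local mean plus
#' `nSd` local (population) standard deviations of the full-width window
#' centered on it (windows are clamped to the series, so edge frames use the
#' first/last window). A tiny relative tolerance guards the strict comparison
#' against floating-point round-off.
#'
#' @param series numeric coactivity series (or a [Raster-class], whose
#'   coactivity is used).
#' @param windowFraction window size as a fraction of the series length, in
#'   `(0, 1]`; typical values are 0.05, 0.10 or 0.20.
#' @param nSd threshold multiplier (>= 2 commonly).
#' @param ensembleId optional id recorded in the result.
#' @return A [PeakSet-class].
#' @export
detectPeaks <- function(series, windowFraction = 0.2, nSd = 2,
                        ensembleId = NA_integer_) {
  if (is(series, "Raster")) series <- coactivity(series)
  x <- as.numeric(series)
  F <- length(x)
  if (windowFraction <= 0 || windowFraction > 1)
    stop("windowFraction must lie in (0, 1]")
  if (nSd <= 0) stop("nSd must be positive")
  w <- as.integer(round(windowFraction * F))
  if (w < 2L) stop("window must span at least 2 frames after rounding")
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  starts <- pmin(pmax(seq_len(F) - (w - 1L) %/% 2L, 1L), F - w + 1L)
  ends <- starts + w - 1L
  mu <- (cs[ends + 1L] - cs[starts]) / w
  v <- pmax((cs2[ends + 1L] - cs2[starts]) / w - mu^2, 0)
  thr <- mu + nSd * sqrt(v)
  flags <- x > thr + 1e-9 * pmax(1, abs(thr))
  new("PeakSet", ensembleId = as.integer(ensembleId), flags = flags,
      coactivity = x, threshold = thr, windowFraction = windowFraction,
      nSd = nSd, runsP = NA_real_, significant = NA)
}

#' Significant coactivity peaks per ensemble
#'
#' For every detected ensemble, builds the ensemble subraster, requires the
#' runs test to reject randomness of its coactivity at `alphaLevel`
#' (otherwise the ensemble yields an empty [PeakSet-class] and a warning),
#' and then applies [detectPeaks()] to the ensemble coactivity.
#'
#' @param raster a [Raster-class].
#' @param assignment an [EnsembleAssignment-class] over the raster's neurons.
#' @param windowFraction,nSd peak-detection parameters.
#' @param alphaLevel runs-test significance level.
#' @return Named list of [PeakSet-class], one per ensemble id.
#' @export
ensemblePeaks <- function(raster, assignment, windowFraction = 0.2, nSd = 2,
                          alphaLevel = 0.05) {
  stopifnot(is(raster, "Raster"), is(assignment, "EnsembleAssignment"))
  if (length(assignment@labels) != nNeurons(raster))
    stop("assignment/raster size mismatch")
  out <- vector("list", assignment@nEnsembles)
  names(out) <- as.character(seq_len(assignment@nEnsembles))
  for (g in seq_len(assignment@nEnsembles)) {
    members <- which(assignment@labels == g)
    co <- coactivity(subRaster(raster, members))
    ht <- tryCatch(runsTest(co), error = function(e) NULL)
    if (is.null(ht) || ht$p.value >= alphaLevel) {
      warning("ensemble ", g, ": coactivity not significant under the runs ",
              "test; returning an empty peak set", call. = FALSE)
      out[[g]] <- new("PeakSet", ensembleId = g,
                      flags = rep(FALSE, length(co)),
                      coactivity = as.numeric(co),
                      threshold = rep(NA_real_, length(co)),
                      windowFraction = windowFraction, nSd = nSd,
                      runsP = if (is.null(ht)) NA_real_ else ht$p.value,
                      significant = FALSE)
    } else {
      ps <- detectPeaks(co, windowFraction, nSd, ensembleId = g)
      ps@runsP <- ht$p.value
      ps@significant <- TRUE
      out[[g]] <- ps
    }
  }
  out
}
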