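#' Sliding-window ensemble firing rate
#'
#' Events of all the (sub)raster's neurons summed in a sliding window of
#' `windowSeconds`, divided by the window duration: events per second, one
#' value per window start frame (`F - windowFrames + 1` points, sliding by
#' one frame).
#'
#' @param raster a [Raster-class] (typically an ensemble subraster).
#' @param windowSeconds window duration in seconds (default 1 s).
#' @return Numeric rate series with attributes `fps` and `windowSeconds`.
#' @export
firingRate <- function(raster, windowSeconds = 1) {
  stopifnot(is(raster, "Raster"))
  wf <- as.integer(round(windowSeconds * raster@fps))
  F <- nFrames(raster)
  if (wf < 1L) stop("window shorter than one frame")
  if (wf > F) stop("window longer than the recording")
  co <- colSums(activityMatrix(raster))
  cs <- cumsum(c(0, co))
  counts <- cs[(wf + 1L):(F + 1L)] - cs[seq_len(F - wf + 1L)]
  structure(counts / windowSeconds, fps = raster@fps,
            windowSeconds = windowSeconds)
}

#' Fixed-radius recurrence matrix
#'
#' Delay-embeds the series into `embeddingDimension`-dimensional state
#' vectors (dimension 1 means the scalar values themselves) and marks a
#' recurrence at `(i, j)` whenever the Euclidean distance between states `i`
#' and `j` is at most `epsilon`. The matrix is symmetric with a unit
#' diagonal.
#'
#' @param series numeric series (e.g. from [firingRate()]).
#' @param epsilon fixed neighborhood radius (> 0); default 1.5.
#' @param embeddingDimension,embeddingDelay delay-embedding parameters.
#' @return A [RecurrencePlot-class].
#' @export
recurrenceMatrix <- function(series, epsilon = 1.5, embeddingDimension = 1L,
                             embeddingDelay = 1L) {
  x <- as.numeric(series)
  if (epsilon <= 0) stop("epsilon must be positive")
  d <- as.integer(embeddingDimension); tau <- as.integer(embeddingDelay)
  if (d < 1L || tau < 1L) stop("embedding dimension and delay must be >= 1")
  n <- length(x) - (d - 1L) * tau
  if (n < 2L) stop("fewer than 2 state vectors after embedding")
  X <- vapply(seq_len(d), function(j) x[seq_len(n) + (j - 1L) * tau],
              numeric(n))
  if (is.null(dim(X))) X <- matrix(X, nrow = n)
  P <- as.matrix(stats::dist(X)) <= epsilon
  storage.mode(P) <- "integer"
  diag(P) <- 1L
  dimnames(P) <- NULL
  new("RecurrencePlot", P = P, epsilon = epsilon,
      embeddingDimension = d, embeddingDelay = tau)
}

# Run lengths of 1s along every diagonal (offsets -n+1 .. n-1, optionally
# skipping the line of identity) and along columns; plus vertical 0-runs.
.diagonalRuns <- function(P, includeLoi) {
  n <- nrow(P)
  lens <- integer(0)
  offs <- (-(n - 1L)):(n - 1L)
  if (!includeLoi) offs <- offs[offs != 0L]
  for (k in offs) {
    i <- if (k >= 0) seq_len(n - k) else seq(1L - k, n)
    v <- P[cbind(i, i + k)]
    r <- rle(v)
    lens <- c(lens, r$lengths[r$values == 1L])
  }
  lens
}

.verticalRuns <- function(P, value) {
  lens <- integer(0)
  for (j in seq_len(ncol(P))) {
    r <- rle(P[, j])
    lens <- c(lens, r$lengths[r$values == value])
  }
  lens
}

#' Recurrence quantification measures
#'
#' Computes the five scalar measures from a recurrence matrix:
#' * `RR` — recurrence rate, `sum(P) / n^2`;
#' * `DET` — fraction of recurrence points on diagonal lines of length
#'   `>= minLine` (the main diagonal is included iff `includeLoi`; when it is
#'   excluded, its points are removed from both numerator and denominator);
#' * `DIV` — inverse length of the longest diagonal line;
#' * `LAM` — laminarity, the DET analogue over vertical lines (always over
#'   the full matrix);
#' * `W` — mean length of the maximal vertical runs of zeros ("white"
#'   vertical lines), an estimator of recurrence times (0 when the matrix has
#'   no zeros).
#'
#' @param plot a [RecurrencePlot-class].
#' @param minLine minimum line length counted for DET and LAM (default 2).
#' @param includeLoi include the line of identity in RR/DET/DIV (default
#'   TRUE, matching the plain sum over all matrix entries; FALSE gives the
#'   common Theiler-window practice).
#' @return An [RQAMeasures-class].
#' @export
rqaMeasures <- function(plot, minLine = 2L, includeLoi = TRUE) {
  stopifnot(is(plot, "RecurrencePlot"))
  P <- plot@P
  n <- nrow(P)
  minLine <- as.integer(minLine)
  total <- sum(P)
  dlens <- .diagonalRuns(P, includeLoi)
  dTotal <- if (includeLoi) total else total - n
  dHist <- if (length(dlens)) tabulate(dlens, n) else numeric(n)
  long <- which(seq_len(n) >= minLine)
  det <- if (dTotal > 0) sum(long * dHist[long]) / dTotal else 0
  maxDiag <- if (length(dlens)) max(dlens) else 0L
  div <- if (maxDiag > 0) 1 / maxDiag else NA_real_
  vlens <- .verticalRuns(P, 1L)
  vHist <- if (length(vlens)) tabulate(vlens, n) else numeric(n)
  lam <- if (total > 0) sum(long * vHist[long]) / total else 0
  wlens <- .verticalRuns(P, 0L)
  wHist <- if (length(wlens)) tabulate(wlens, n) else numeric(n)
  wMean <- if (length(wlens)) mean(wlens) else 0
  new("RQAMeasures", rr = total / n^2, det = det, div = div, lam = lam,
      wMean = wMean, diagonalHist = as.numeric(dHist),
      verticalHist = as.numeric(vHist), whiteHist = as.numeric(wHist),
      minLine = minLine, includeLoi = includeLoi)
}

#' Recurrence analysis of every ensemble in a raster
#'
#' For each ensemble, computes the 1-s sliding-window firing rate of its
#' subraster, the fixed-radius recurrence matrix, and the five RQA measures.
#'
#' @param raster a [Raster-class].
#' @param assignment an [EnsembleAssignment-class].
#' @param epsilon fixed recurrence radius.
#' @param windowSeconds firing-rate window in seconds.
#' @param minLine,includeLoi passed to [rqaMeasures()].
#' @return data.frame with one row per ensemble: `ensemble`, `n` (series
#'   length), `RR`, `DET`, `DIV`, `LAM`, `W`.
#' @export
rqaTable <- function(raster, assignment, epsilon = 1.5, windowSeconds = 1,
                     minLine = 2L, includeLoi = TRUE) {
  stopifnot(is(raster, "Raster"), is(assignment, "EnsembleAssignment"))
  rows <- lapply(seq_len(assignment@nEnsembles), function(g) {
    sub <- subRaster(raster, which(assignment@labels == g))
    rate <- firingRate(sub, windowSeconds)
    m <- rqaMeasures(recurrenceMatrix(rate, epsilon), minLine, includeLoi)
    data.frame(ensemble = g, n = length(rate), RR = m@rr, DET = m@det,
               DIV = m@div, LAM = m@lam, W = m@wMean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
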