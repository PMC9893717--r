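#' @import methods
NULL

#' Binary activity raster
#'
#' An N x F binary matrix of inferred neuronal activity: rows are neurons
#' (activity vectors), columns are movie frames (population vectors). A value
#' of 1 at `[i, t]` marks an inferred activity event of neuron `i` at frame
#' `t`. The acquisition frame rate travels with the matrix so that downstream
#' analyses (firing rates, window sizes in seconds) stay in physical units.
#'
#' @slot activity integer matrix of 0/1 values, neurons x frames.
#' @slot fps acquisition frame rate in frames per second (positive scalar).
#' @slot neuronIds character labels for the neurons (length N, or empty).
#'
#' @seealso [Raster()], [loadRaster()], [subRaster()]
#' @export
setClass("Raster",
  representation(activity = "matrix", fps = "numeric", neuronIds = "character"),
  validity = function(object) {
    a <- object@activity
    if (!is.numeric(a) && !is.integer(a))
      return("activity must be a numeric/integer matrix")
    if (nrow(a) < 1L || ncol(a) < 1L)
      return("raster needs at least 1 neuron and 1 frame")
    bad <- which(!(a == 0L | a == 1L))
    if (length(bad)) {
      i <- ((bad[1L] - 1L) %% nrow(a)) + 1L
      j <- ((bad[1L] - 1L) %/% nrow(a)) + 1L
      return(sprintf("non-binary value %s at neuron %d, frame %d",
                     format(a[bad[1L]]), i, j))
    }
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      return("fps must be a single positive number")
    if (length(object@neuronIds) &&
        length(object@neuronIds) != nrow(a))
      return("neuronIds length must match the number of neurons")
    TRUE
  }
)

#' Construct a Raster
#'
#' @param activity matrix of 0/1 values (neurons x frames).
#' @param fps frame rate in frames per second.
#' @param neuronIds optional character labels, one per neuron.
#' @return A validated [Raster-class] object.
#' @examples
#' r <- Raster(rbind(c(1, 0, 1), c(0, 1, 0)), fps = 4)
#' nNeurons(r)
#' @export
Raster <- function(activity, fps, neuronIds = character(0)) {
  m <- as.matrix(activity)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  new("Raster", activity = m, fps = as.numeric(fps),
      neuronIds = as.character(neuronIds))
}

#' Weighted functional-connectivity graph
#'
#' Symmetric N x N matrix of edge weights in `[0, 1]`; each weight is the
#' fuzzy-union membership strength of the connection between two neurons'
#' activity vectors (the probability that the two nodes are functionally
#' connected). No self-loops.
#'
#' @slot weights symmetric numeric matrix, entries in `[0, 1]`, zero diagonal.
#' @slot excluded indices (into the original raster) of zero-variance neurons
#'   that were left out of graph construction.
#' @export
setClass("AdjacencyGraph",
  representation(weights = "matrix", excluded = "integer"),
  validity = function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (max(abs(w - t(w))) > 1e-8) return("weights must be symmetric")
    if (any(w < -1e-12) || any(w > 1 + 1e-9))
      return("weights must lie in [0, 1]")
    if (any(abs(diag(w)) > 1e-12)) return("self-loops are not allowed")
    TRUE
  }
)

adjacencyGraph <- function(weights, excluded = integer(0)) {
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  new("AdjacencyGraph", weights = w, excluded = as.integer(excluded))
}

#' Modularity matrix of a weighted graph
#'
#' The full modularity matrix `B = A - k k' / (2m)` or, for a node subset `g`,
#' the generalized matrix `B(g)_ij = B_ij - delta_ij * sum_{k in g} B_ik` used
#' during recursive spectral bisection.
#'
#' @slot entries the (possibly group-restricted) matrix.
#' @slot degrees weighted node degrees of the full graph.
#' @slot totalWeight total edge weight m of the full graph.
#' @slot group node indices of the restriction (empty = full matrix).
#' @export
setClass("ModularityMatrix",
  representation(entries = "matrix", degrees = "numeric",
                 totalWeight = "numeric", group = "integer"))

#' Ensemble assignment of neurons
#'
#' Community labels over the neurons of a raster, together with the modularity
#' score of the partition. Labels are contiguous integers starting at 1;
#' neurons excluded from graph construction (zero-variance rows) carry `NA`.
#'
#' @slot labels integer vector, one label per neuron (`NA` = excluded).
#' @slot nEnsembles number of communities.
#' @slot modularityQ modularity of the partition on the original graph.
#' @slot order community ids ordered by first appearance in time (filled by
#'   [sortRaster()]; empty before sorting).
#' @slot excluded indices of neurons excluded from graph construction.
#' @export
setClass("EnsembleAssignment",
  representation(labels = "integer", nEnsembles = "integer",
                 modularityQ = "numeric", order = "integer",
                 excluded = "integer"),
  validity = function(object) {
    lab <- object@labels[!is.na(object@labels)]
    if (length(lab)) {
      if (min(lab) < 1L || max(lab) != object@nEnsembles ||
          !all(seq_len(object@nEnsembles) %in% lab))
        return("labels must be contiguous integers 1..nEnsembles")
    }
    if (!is.finite(object@modularityQ)) return("modularityQ must be finite")
    TRUE
  }
)

#' Significant-coactivity flags for one series
#'
#' Per-frame significance marks produced by the sliding-window dynamic
#' threshold, together with the coactivity values and the local threshold used,
#' so results can be audited and exported.
#'
#' @slot ensembleId ensemble the flags belong to (`NA` for a whole raster).
#' @slot flags logical vector, one per frame.
#' @slot coactivity the per-frame coactivity counts the flags refer to.
#' @slot threshold the local dynamic threshold per frame.
#' @slot windowFraction sliding-window size as a fraction of the series.
#' @slot nSd threshold multiplier (number of local standard deviations).
#' @slot runsP p-value of the runs test gating this series (`NA` if not run
#'   or degenerate).
#' @slot significant whether the runs test rejected randomness for the series.
#' @export
setClass("PeakSet",
  representation(ensembleId = "integer", flags = "logical",
                 coactivity = "numeric", threshold = "numeric",
                 windowFraction = "numeric", nSd = "numeric",
                 runsP = "numeric", significant = "logical"),
  validity = function(object) {
    if (length(object@flags) != length(object@coactivity))
      return("flags and coactivity must have equal length")
    if (object@windowFraction <= 0 || object@windowFraction > 1)
      return("windowFraction must lie in (0, 1]")
    if (object@nSd <= 0) return("nSd must be positive")
    TRUE
  }
)

#' Directed ensemble transition graph
#'
#' Nodes are ensembles; a directed edge `(from, to)` counts how many times a
#' significant activation of `from` was immediately followed by one of `to`.
#' Auto-recurrences (same ensemble twice in a row) are bookkept separately in
#' `selfLoops` and excluded from transition totals and drawings.
#'
#' @slot nodes integer ensemble ids present.
#' @slot edges data.frame with integer columns `from`, `to`, `count`.
#' @slot selfLoops integer vector of auto-recurrence counts per node
#'   (same order as `nodes`).
#' @export
setClass("TransitionGraph",
  representation(nodes = "integer", edges = "data.frame",
                 selfLoops = "integer"),
  validity = function(object) {
    e <- object@edges
    if (!all(c("from", "to", "count") %in% names(e)))
      return("edges needs columns from, to, count")
    if (nrow(e) && any(e$count < 1)) return("edge counts must be >= 1")
    if (nrow(e) && any(e$from == e$to))
      return("self-loops belong in selfLoops, not edges")
    if (length(object@selfLoops) != length(object@nodes))
      return("selfLoops must align with nodes")
    TRUE
  }
)

#' Recurrence plot
#'
#' Binary n x n matrix marking pairs of time points whose (optionally
#' delay-embedded) states lie within a fixed Euclidean radius epsilon.
#'
#' @slot P integer 0/1 matrix, symmetric with unit diagonal.
#' @slot epsilon fixed neighborhood radius.
#' @slot embeddingDimension delay-embedding dimension (1 = scalar series).
#' @slot embeddingDelay delay between embedding coordinates, in samples.
#' @export
setClass("RecurrencePlot",
  representation(P = "matrix", epsilon = "numeric",
                 embeddingDimension = "integer", embeddingDelay = "integer"),
  validity = function(object) {
    P <- object@P
    if (nrow(P) != ncol(P)) return("P must be square")
    if (any(!(P == 0L | P == 1L))) return("P must be binary")
    if (any(P != t(P))) return("P must be symmetric")
    if (object@epsilon <= 0) return("epsilon must be positive")
    TRUE
  }
)

#' Recurrence quantification measures
#'
#' The five scalar recurrence measures with their audit histograms: recurrence
#' rate (RR), determinism (DET, fraction of recurrence points on diagonal
#' lines of length >= minLine), divergence (DIV, inverse longest diagonal),
#' laminarity (LAM, analogous to DET over vertical lines), and mean white
#' vertical line length (W, a recurrence-time estimator).
#'
#' @slot rr,det,div,lam,wMean the five scalar measures.
#' @slot diagonalHist counts of maximal diagonal 1-runs by length.
#' @slot verticalHist counts of maximal vertical 1-runs by length.
#' @slot whiteHist counts of maximal vertical 0-runs by length.
#' @slot minLine minimum line length counted for DET and LAM.
#' @slot includeLoi whether the line of identity was included.
#' @export
setClass("RQAMeasures",
  representation(rr = "numeric", det = "numeric", div = "numeric",
                 lam = "numeric", wMean = "numeric",
                 diagonalHist = "numeric", verticalHist = "numeric",
                 whiteHist = "numeric", minLine = "integer",
                 includeLoi = "logical"))

#' Synthetic raster configuration
#'
#' Full description of a planted-ensemble raster: a partition of (some of the)
#' neurons into K ensembles, an ordered activation sequence over ensemble
#' labels realized as epochs separated by silent gaps, a per-frame activation
#' probability for members inside their ensemble's epochs, and a Bernoulli
#' background firing probability everywhere else.
#'
#' @slot nNeurons,nFrames,fps raster dimensions and frame rate.
#' @slot membership list of K disjoint integer vectors of member neurons;
#'   neurons in no group are background-only.
#' @slot epochLength frames per activation epoch.
#' @slot gapLength silent frames between consecutive epochs.
#' @slot sequence ordered ensemble labels of the planted temporal sequence
#'   (repeated cyclically to fill the recording).
#' @slot pActive per-frame activation probability of a member inside its
#'   ensemble's epochs.
#' @slot pBackground per-neuron per-frame background firing probability.
#' @slot seed RNG seed making generation bit-reproducible.
#' @slot name preset name or "custom".
#' @export
setClass("SynthConfig",
  representation(nNeurons = "integer", nFrames = "integer", fps = "numeric",
                 membership = "list", epochLength = "integer",
                 gapLength = "integer", sequence = "integer",
                 pActive = "numeric", pBackground = "numeric",
                 seed = "integer", name = "character"),
  validity = function(object) {
    K <- length(object@membership)
    if (K < 1L) return("need at least one ensemble")
    mem <- unlist(object@membership)
    if (anyDuplicated(mem)) return("membership groups must be disjoint")
    if (length(mem) && (min(mem) < 1L || max(mem) > object@nNeurons))
      return("membership references unknown neuron")
    if (object@epochLength < 1L) return("epochLength must be >= 1")
    if (object@gapLength < 0L) return("gapLength must be >= 0")
    if (!length(object@sequence)) return("sequence must be non-empty")
    if (any(object@sequence < 1L | object@sequence > K))
      return("sequence labels must reference ensembles 1..K")
    if (object@pActive < 0 || object@pActive > 1 ||
        object@pBackground < 0 || object@pBackground > 1)
      return("probabilities must lie in [0, 1]")
    if (object@fps <= 0) return("fps must be positive")
    TRUE
  }
)
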