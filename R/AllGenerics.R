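#' @describeIn Raster-class number of neurons (rows).
#' @param object,x a `Raster`.
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))

#' @describeIn Raster-class number of frames (columns).
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @describeIn Raster-class acquisition frame rate in frames per second.
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @describeIn Raster-class the underlying 0/1 integer matrix.
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))

#' Ensemble labels of an assignment
#' @param object an `EnsembleAssignment`.
#' @return integer vector of per-neuron labels (`NA` for excluded neurons).
#' @export
setGeneric("ensembleLabels", function(object) standardGeneric("ensembleLabels"))

#' Number of detected ensembles
#' @param object an `EnsembleAssignment`.
#' @export
setGeneric("nEnsembles", function(object) standardGeneric("nEnsembles"))

#' Modularity score of a partition
#' @param object an `EnsembleAssignment`.
#' @export
setGeneric("modularityQ", function(object) standardGeneric("modularityQ"))

#' Per-frame significance flags of a peak set
#' @param object a `PeakSet`.
#' @export
setGeneric("peakFlags", function(object) standardGeneric("peakFlags"))

#' Recurrence matrix of a recurrence plot
#' @param object a `RecurrencePlot`.
#' @export
setGeneric("recurrenceData", function(object) standardGeneric("recurrenceData"))

setMethod("nNeurons", "Raster", function(object) nrow(object@activity))
setMethod("nFrames", "Raster", function(object) ncol(object@activity))
setMethod("frameRate", "Raster", function(object) object@fps)
setMethod("activityMatrix", "Raster", function(object) object@activity)

setMethod("ensembleLabels", "EnsembleAssignment", function(object) object@labels)
setMethod("nEnsembles", "EnsembleAssignment", function(object) object@nEnsembles)
setMethod("modularityQ", "EnsembleAssignment", function(object) object@modularityQ)
setMethod("peakFlags", "PeakSet", function(object) object@flags)
setMethod("recurrenceData", "RecurrencePlot", function(object) object@P)

#' @describeIn Raster-class dimensions `c(neurons, frames)`.
#' @export
setMethod("dim", "Raster", function(x) dim(x@activity))

#' @describeIn Raster-class restrict to a subset of neurons, frames unchanged.
#' @param i neuron indices (1-based).
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "Raster", function(x, i, j, ..., drop = FALSE) {
  subRaster(x, i)
})

setMethod("show", "Raster", function(object) {
  cat(sprintf("Raster: %d neurons x %d frames at %g fps (%d events, %.2f%% active)\n",
              nNeurons(object), nFrames(object), object@fps,
              sum(object@activity),
              100 * mean(object@activity)))
})

setMethod("show", "AdjacencyGraph", function(object) {
  w <- object@weights
  cat(sprintf("AdjacencyGraph: %d nodes, %d weighted edges (total weight %.3f)",
              nrow(w), sum(w[upper.tri(w)] > 0), sum(w) / 2))
  if (length(object@excluded))
    cat(sprintf("; %d zero-variance neurons excluded", length(object@excluded)))
  cat("\n")
})

setMethod("show", "EnsembleAssignment", function(object) {
  cat(sprintf("EnsembleAssignment: %d ensembles over %d neurons, Q = %.4f\n",
              object@nEnsembles, length(object@labels), object@modularityQ))
  tab <- table(object@labels)
  cat("  sizes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (length(object@excluded))
    cat("  excluded (zero-variance):", length(object@excluded), "neurons\n")
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet%s: %d/%d frames flagged (window %.0f%%, %g SD%s)\n",
              if (is.na(object@ensembleId)) "" else
                sprintf(" [ensemble %d]", object@ensembleId),
              sum(object@flags), length(object@flags),
              100 * object@windowFraction, object@nSd,
              if (isTRUE(object@significant)) "" else "; runs test not significant"))
})

setMethod("show", "TransitionGraph", function(object) {
  cat(sprintf("TransitionGraph: %d nodes, %d directed edges, %d transitions (+%d self-loops)\n",
              length(object@nodes), nrow(object@edges),
              sum(object@edges$count), sum(object@selfLoops)))
})

setMethod("show", "RecurrencePlot", function(object) {
  n <- nrow(object@P)
  cat(sprintf("RecurrencePlot: %d x %d, epsilon = %g, d = %d, delay = %d, RR = %.4f\n",
              n, n, object@epsilon, object@embeddingDimension,
              object@embeddingDelay, mean(object@P)))
})

setMethod("show", "RQAMeasures", function(object) {
  cat(sprintf(
    "RQAMeasures (minLine = %d, LOI %s):\n  RR = %.4f  DET = %.4f  DIV = %.4f  LAM = %.4f  W = %.3f\n",
    object@minLine, if (object@includeLoi) "included" else "excluded",
    object@rr, object@det, object@div, object@lam, object@wMean))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig '%s': %d neurons, %d frames at %g fps, K = %d\n",
              object@name, object@nNeurons, object@nFrames, object@fps,
              length(object@membership)))
  cat(sprintf("  epoch %d + gap %d frames, sequence length %d, pActive = %g, pBackground = %g, seed = %d\n",
              object@epochLength, object@gapLength, length(object@sequence),
              object@pActive, object@pBackground, object@seed))
})
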