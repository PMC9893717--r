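#' Assemble a pipeline configuration
#'
#' Collects every tunable of the full analysis into one validated list. The
#' input is either a raster file (`path` + `format` + `fps`) or a synthetic
#' configuration (`preset` name or a [SynthConfig-class]).
#'
#' @param input list describing the raster source: either
#'   `list(path =, format =, fps =)` or `list(preset =)` /
#'   `list(config = <SynthConfig>)`.
#' @param nNeighbors fuzzy-graph neighborhood size.
#' @param consensusRuns consensus detection runs.
#' @param windowFraction,nSd,alphaLevel peak-detection parameters.
#' @param surrogates number of surrogates per class for the error report
#'   (0 skips the report).
#' @param epsilon,windowSeconds,minLine,includeLoi recurrence parameters.
#' @param seed master seed for every stochastic stage.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(input, nNeighbors = 10L, consensusRuns = 20L,
                           windowFraction = 0.2, nSd = 2, alphaLevel = 0.05,
                           surrogates = 0L, epsilon = 1.5, windowSeconds = 1,
                           minLine = 2L, includeLoi = TRUE, seed = 1L) {
  cfg <- list(input = input, nNeighbors = as.integer(nNeighbors),
              consensusRuns = as.integer(consensusRuns),
              windowFraction = windowFraction, nSd = nSd,
              alphaLevel = alphaLevel, surrogates = as.integer(surrogates),
              epsilon = epsilon, windowSeconds = windowSeconds,
              minLine = as.integer(minLine), includeLoi = includeLoi,
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipelineConfig()].
#' @return A `"pipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  args <- x[setdiff(names(x), "input")]
  do.call(pipelineConfig, c(list(input = x$input), args))
}

.resolveInput <- function(input, seed) {
  if (!is.null(input$path)) {
    if (!file.exists(input$path)) stop("missing input path: ", input$path)
    list(raster = loadRaster(input$path, input$format %||% "matrix",
                             fps = input$fps),
         truth = NULL)
  } else if (!is.null(input$config)) {
    generateRaster(input$config)
  } else if (!is.null(input$preset)) {
    generateRaster(presetConfig(input$preset, seed = seed))
  } else stop("pipeline input must supply a path, a preset, or a config")
}

#' Run the full ensemble-analysis pipeline
#'
#' Executes, in order: ensemble detection (correlation distances, fuzzy
#' nearest-neighbor graph, consensus modularity clustering), per-ensemble
#' runs-test-gated peak detection (with an optional surrogate error report),
#' the ensemble transition graph, and per-ensemble recurrence analysis. When
#' `outDir` is given, every table is written as CSV/TSV alongside a JSON
#' manifest recording the seed and every tunable, so a rerun with the same
#' configuration reproduces the outputs byte for byte.
#'
#' @param config a `"pipelineConfig"` list (see [pipelineConfig()] /
#'   [readPipelineConfig()]).
#' @param outDir optional output directory, created if needed.
#' @param verbose print stage progress.
#' @return A list with `raster`, `truth`, `assignment`, `sorted`,
#'   `peakSets`, `errorReport`, `sequence`, `transitions`, `metrics`,
#'   `rqa`, and `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  say("stage: input")
  inp <- stage("input", .resolveInput(config$input, config$seed))
  raster <- inp$raster

  say("stage: ensembles")
  assignment <- stage("ensembles",
    detectEnsembles(raster, config$nNeighbors, config$consensusRuns,
                    seed = config$seed))
  sorted <- stage("ensembles", sortRaster(raster, assignment))

  say("stage: coactivity")
  peakSets <- stage("coactivity", withCallingHandlers(
    ensemblePeaks(raster, assignment, config$windowFraction, config$nSd,
                  config$alphaLevel),
    warning = function(w) { say("  ", conditionMessage(w))
                            invokeRestart("muffleWarning") }))
  errorReport <- if (config$surrogates > 0L)
    stage("coactivity",
          estimateErrorRates(raster, config$surrogates, config$alphaLevel,
                             seed = config$seed))
  else NULL

  say("stage: transitions")
  sequence <- stage("transitions", suppressWarnings(
    activationSequence(peakSets)))
  transitions <- stage("transitions",
    buildTransitionGraph(sequence, assignment@nEnsembles))
  metrics <- graphMetrics(transitions)

  say("stage: rqa")
  rqa <- stage("rqa",
    rqaTable(raster, assignment, config$epsilon, config$windowSeconds,
             config$minLine, config$includeLoi))

  manifest <- list(
    package = "ensembleScope",
    version = as.character(utils::packageVersion("ensembleScope")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "input")],
    nNeurons = nNeurons(raster), nFrames = nFrames(raster),
    fps = frameRate(raster),
    nEnsembles = assignment@nEnsembles,
    modularityQ = assignment@modularityQ,
    totalTransitions = metrics$totalTransitions)

  res <- list(raster = raster, truth = inp$truth, assignment = assignment,
              sorted = sorted, peakSets = peakSets,
              errorReport = errorReport, sequence = sequence,
              transitions = transitions, metrics = metrics, rqa = rqa,
              manifest = manifest)
  if (!is.null(outDir)) .writePipelineOutputs(res, config, outDir)
  res
}

.writePipelineOutputs <- function(res, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  # 0-based neuron/ensemble ids in files, matching the raster file formats
  asg <- res$assignment
  utils::write.csv(data.frame(
    neuron_id = seq_along(asg@labels) - 1L,
    ensemble_id = ifelse(is.na(asg@labels), NA_integer_, asg@labels - 1L)),
    p("assignment.csv"), row.names = FALSE)
  peaks <- do.call(rbind, lapply(res$peakSets, function(ps)
    data.frame(frame = seq_along(ps@flags) - 1L,
               ensemble_id = ps@ensembleId - 1L,
               coactivity = ps@coactivity, threshold = ps@threshold,
               flagged = ps@flags)))
  utils::write.csv(peaks, p("peaks.csv"), row.names = FALSE)
  if (!is.null(res$errorReport))
    utils::write.csv(data.frame(
      M = res$errorReport$M, alpha_hat = res$errorReport$alphaHat,
      beta_hat = res$errorReport$betaHat,
      alpha_level = res$errorReport$alphaLevel,
      seed = res$errorReport$seed),
      p("error_report.csv"), row.names = FALSE)
  exportGraph(res$transitions, p("transitions.tsv"), "edgelist")
  exportGraph(res$transitions, p("transitions.dot"), "dot")
  exportGraph(res$transitions, p("transitions.graphml"), "graphml")
  utils::write.csv(res$rqa, p("rqa.csv"), row.names = FALSE)
  saveRaster(res$sorted$raster, p("sorted_raster.txt"), "matrix")
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Write a synthetic preset raster and its ground truth to disk
#'
#' Generates the preset raster and writes it in both file formats plus the
#' ground-truth labels and epoch schedule as CSV (0-based ids, matching the
#' file conventions).
#'
#' @param preset preset name (see [presetConfig()]).
#' @param seed RNG seed.
#' @param outDir output directory, created if needed.
#' @return The generated list from [generateRaster()], invisibly.
#' @export
simulateRaster <- function(preset, seed = 1L, outDir) {
  out <- generateRaster(presetConfig(preset, seed = seed))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  saveRaster(out$raster, file.path(outDir, "raster_matrix.txt"), "matrix")
  saveRaster(out$raster, file.path(outDir, "raster_events.txt"), "events")
  tr <- out$truth
  utils::write.csv(data.frame(
    neuron_id = seq_along(tr$labels) - 1L,
    ensemble_id = ifelse(is.na(tr$labels), NA_integer_, tr$labels - 1L)),
    file.path(outDir, "truth_labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    frame = seq_along(tr$epochSchedule) - 1L,
    ensemble_id = ifelse(is.na(tr$epochSchedule), NA_integer_,
                         tr$epochSchedule - 1L)),
    file.path(outDir, "truth_schedule.csv"), row.names = FALSE)
  invisible(out)
}
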