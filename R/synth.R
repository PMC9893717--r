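#' Build a synthetic-raster configuration
#'
#' Describes a raster with known ground truth: K disjoint ensembles whose
#' members fire with probability `pActive` inside their ensemble's scheduled
#' activation epochs, over Bernoulli background firing with probability
#' `pBackground`. Epochs follow the planted `sequence` of ensemble labels,
#' repeated cyclically with a silent gap after every epoch, until the
#' recording is filled.
#'
#' @param nNeurons,nFrames,fps raster dimensions and frame rate.
#' @param membership list of disjoint integer vectors (one per ensemble);
#'   neurons in no group are background-only.
#' @param epochLength frames per activation epoch.
#' @param gapLength silent frames after each epoch (default: one epoch, which
#'   keeps coactivity peaks of consecutive epochs separable).
#' @param sequence ordered ensemble labels of the planted temporal sequence.
#' @param pActive per-frame member activation probability inside epochs.
#' @param pBackground per-neuron per-frame background firing probability.
#' @param seed RNG seed.
#' @param name configuration label.
#' @return A validated [SynthConfig-class].
#' @export
synthConfig <- function(nNeurons, nFrames, fps = 4, membership,
                        epochLength = 20L, gapLength = epochLength,
                        sequence = seq_along(membership),
                        pActive = 0.9, pBackground = 0.02,
                        seed = 1L, name = "custom") {
  new("SynthConfig",
      nNeurons = as.integer(nNeurons), nFrames = as.integer(nFrames),
      fps = as.numeric(fps), membership = lapply(membership, as.integer),
      epochLength = as.integer(epochLength), gapLength = as.integer(gapLength),
      sequence = as.integer(sequence), pActive = as.numeric(pActive),
      pBackground = as.numeric(pBackground), seed = as.integer(seed),
      name = as.character(name))
}

.evenMembership <- function(nMembers, K, offset = 0L) {
  split(offset + seq_len(nMembers * K), rep(seq_len(K), each = nMembers))
}

#' Condition-like synthetic presets
#'
#' Fixed configurations encoding the qualitative contrasts between the four
#' experimental conditions the pipeline is meant to discriminate. The numeric
#' constants are implementation choices of the generator, not claims about any
#' particular dataset; tests assert only the orderings these presets plant.
#'
#' * `control_like` — six balanced ensembles of 10 neurons, a varied
#'   many-transition sequence, moderate background (0.02).
#' * `decorticated_like` — eight large, nearly isolated ensembles in a
#'   strictly unidirectional ring, the lowest background of the four presets,
#'   and seconds-long epochs sampled at a higher frame rate (the slow,
#'   near-isolated dynamics of deafferented tissue relative to acquisition).
#' * `parkinsonian_like` — few ensembles with regular epoch timing and a
#'   single dominant alternating transition pair (half of the planted
#'   sequence's transitions, see [sequenceDominance()]).
#' * `dyskinetic_like` — the most ensembles (small ones), the densest
#'   sequence (shortest gaps), and the highest background.
#'
#' @param name one of `"control_like"`, `"decorticated_like"`,
#'   `"parkinsonian_like"`, `"dyskinetic_like"`.
#' @param seed RNG seed stored in the configuration.
#' @return A [SynthConfig-class].
#' @export
presetConfig <- function(name = c("control_like", "decorticated_like",
                                  "parkinsonian_like", "dyskinetic_like"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    control_like = synthConfig(
      nNeurons = 60L, nFrames = 3000L, fps = 4,
      membership = .evenMembership(10L, 6L),
      epochLength = 20L, gapLength = 14L,
      sequence = c(1, 2, 3, 4, 5, 6, 2, 4, 6, 1, 3, 5, 3, 6, 2, 5, 1, 4),
      pActive = 0.9, pBackground = 0.02, seed = seed, name = name),
    decorticated_like = synthConfig(
      nNeurons = 200L, nFrames = 3000L, fps = 16,
      membership = .evenMembership(25L, 8L),
      epochLength = 80L, gapLength = 40L,
      sequence = 1:8,
      pActive = 0.9, pBackground = 0.015, seed = seed, name = name),
    parkinsonian_like = synthConfig(
      nNeurons = 30L, nFrames = 3000L, fps = 4,
      membership = .evenMembership(10L, 3L),
      epochLength = 10L, gapLength = 10L,
      sequence = c(rep(c(1, 2), 10), 3),
      pActive = 0.9, pBackground = 0.02, seed = seed, name = name),
    dyskinetic_like = synthConfig(
      nNeurons = 46L, nFrames = 3000L, fps = 4,
      membership = .evenMembership(4L, 10L),
      epochLength = 20L, gapLength = 6L,
      sequence = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                   2, 4, 6, 8, 10, 1, 3, 5, 7, 9,
                   5, 1, 6, 2, 7, 3, 8, 4, 9, 10),
      pActive = 0.9, pBackground = 0.03, seed = seed, name = name))
}

#' Generate a synthetic raster with planted ground truth
#'
#' Deterministic given `config@seed`. Within each scheduled epoch of ensemble
#' `e`, each member of `e` fires per-frame with probability `pActive`;
#' everywhere else every neuron fires with probability `pBackground`.
#'
#' @param config a [SynthConfig-class].
#' @return A list with components:
#' \describe{
#'   \item{raster}{the generated [Raster-class];}
#'   \item{truth}{a list with `labels` (per-neuron planted ensemble, `NA` for
#'     background-only neurons), `epochSchedule` (per-frame active ensemble
#'     label, `NA` when silent), `epochs` (data.frame ensemble/start/end),
#'     and `plantedTransitions` (data.frame of consecutive realized epoch
#'     label pairs).}
#' }
#' @examples
#' cfg <- synthConfig(6, 120, membership = list(1:3, 4:6), epochLength = 10,
#'                    sequence = c(1, 2), pActive = 1, pBackground = 0)
#' out <- generateRaster(cfg)
#' table(out$truth$epochSchedule, useNA = "ifany")
#' @export
generateRaster <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  N <- config@nNeurons; F <- config@nFrames
  K <- length(config@membership)
  set.seed(config@seed)

  # realized epoch schedule: sequence repeated cyclically, gap after each epoch
  sched <- rep(NA_integer_, F)
  epochs <- list(); pos <- 1L; k <- 0L
  while (pos <= F) {
    lab <- config@sequence[(k %% length(config@sequence)) + 1L]
    e <- min(pos + config@epochLength - 1L, F)
    sched[pos:e] <- lab
    epochs[[length(epochs) + 1L]] <- c(lab, pos, e)
    pos <- e + 1L + config@gapLength
    k <- k + 1L
  }
  epochs <- as.data.frame(do.call(rbind, epochs))
  names(epochs) <- c("ensemble", "start", "end")

  p <- matrix(config@pBackground, N, F)
  for (i in seq_len(nrow(epochs))) {
    mem <- config@membership[[epochs$ensemble[i]]]
    p[mem, epochs$start[i]:epochs$end[i]] <- config@pActive
  }
  m <- matrix(as.integer(stats::runif(N * F) < p), N, F)

  labels <- rep(NA_integer_, N)
  for (g in seq_len(K)) labels[config@membership[[g]]] <- g
  lab <- epochs$ensemble
  trans <- if (length(lab) > 1L)
    data.frame(from = lab[-length(lab)], to = lab[-1L])
  else data.frame(from = integer(0), to = integer(0))

  list(raster = Raster(m, fps = config@fps),
       truth = list(labels = labels, epochSchedule = sched,
                    epochs = epochs, plantedTransitions = trans))
}

#' Dominant ordered-pair share of a planted sequence
#'
#' Fraction of the consecutive label pairs of `config@sequence` (as written,
#' before cyclic repetition) accounted for by the most frequent ordered pair.
#' A value of 0.5 or more marks a sequence dominated by a single recurrent
#' transition.
#'
#' @param config a [SynthConfig-class].
#' @return Scalar in `[0, 1]` (0 for a length-1 sequence).
#' @export
sequenceDominance <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  s <- config@sequence
  if (length(s) < 2L) return(0)
  pair <- paste(s[-length(s)], s[-1L])
  max(table(pair)) / (length(s) - 1L)
}

#' Serialize or restore a synthetic configuration
#'
#' Round-trips a [SynthConfig-class] through a YAML file (the same format the
#' pipeline configuration uses for its `synth` input block).
#'
#' @param config a [SynthConfig-class].
#' @param path YAML file.
#' @return `writeSynthConfig` returns `path` invisibly; `readSynthConfig`
#'   returns the restored [SynthConfig-class].
#' @export
writeSynthConfig <- function(config, path) {
  yaml::write_yaml(list(
    nNeurons = config@nNeurons, nFrames = config@nFrames, fps = config@fps,
    membership = lapply(config@membership, as.integer),
    epochLength = config@epochLength, gapLength = config@gapLength,
    sequence = as.integer(config@sequence), pActive = config@pActive,
    pBackground = config@pBackground, seed = config@seed,
    name = config@name), path)
  invisible(path)
}

#' @rdname writeSynthConfig
#' @export
readSynthConfig <- function(path) {
  x <- yaml::read_yaml(path)
  synthConfig(x$nNeurons, x$nFrames, x$fps, x$membership, x$epochLength,
              x$gapLength, unlist(x$sequence), x$pActive, x$pBackground,
              x$seed, x$name)
}
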