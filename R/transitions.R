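#' Ensemble activation sequence from peak sets
#'
#' Merges each ensemble's consecutive flagged frames into a single activation
#' event anchored at the run's first frame (onset convention), then merges
#' events from all ensembles in frame order. Simultaneous onsets of distinct
#' ensembles at the same frame are ordered by ensemble id and reported with a
#' warning.
#'
#' @param peakSets list of [PeakSet-class] (e.g. from [ensemblePeaks()]).
#' @return data.frame with integer columns `frame` and `ensemble`, ordered by
#'   frame; zero rows (with a warning) when all peak sets are empty.
#' @export
activationSequence <- function(peakSets) {
  events <- list()
  for (ps in peakSets) {
    stopifnot(is(ps, "PeakSet"))
    f <- ps@flags
    if (!any(f)) next
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onsets <- starts[r$values]
    events[[length(events) + 1L]] <-
      data.frame(frame = onsets, ensemble = rep(ps@ensembleId, length(onsets)))
  }
  if (!length(events)) {
    warning("all peak sets are empty: empty activation sequence",
            call. = FALSE)
    return(data.frame(frame = integer(0), ensemble = integer(0)))
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$frame, ev$ensemble), , drop = FALSE]
  if (anyDuplicated(ev$frame))
    warning("simultaneous onsets of distinct ensembles at frame(s) ",
            paste(unique(ev$frame[duplicated(ev$frame)]), collapse = ", "),
            "; ordered by ensemble id", call. = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Build the directed ensemble transition graph
#'
#' Every consecutive pair of activation events with different labels
#' increments the directed edge `(from, to)`; identical consecutive labels
#' increment the node's auto-recurrence count instead (self-loops are
#' bookkept separately and excluded from transition totals and drawings).
#'
#' @param sequence data.frame from [activationSequence()].
#' @param nEnsembles optional number of ensembles (nodes); defaults to the
#'   largest label seen.
#' @return A [TransitionGraph-class].
#' @export
buildTransitionGraph <- function(sequence, nEnsembles = NULL) {
  lab <- as.integer(sequence$ensemble)
  K <- as.integer(nEnsembles %||% if (length(lab)) max(lab) else 0L)
  nodes <- seq_len(K)
  selfLoops <- integer(K)
  counts <- list()
  if (length(lab) > 1L) {
    from <- lab[-length(lab)]; to <- lab[-1L]
    same <- from == to
    for (g in nodes) selfLoops[g] <- sum(same & from == g)
    if (any(!same)) {
      tab <- table(from[!same], to[!same])
      idx <- which(tab > 0, arr.ind = TRUE)
      counts <- data.frame(
        from = as.integer(rownames(tab)[idx[, 1]]),
        to = as.integer(colnames(tab)[idx[, 2]]),
        count = as.integer(tab[idx]))
      counts <- counts[order(counts$from, counts$to), , drop = FALSE]
      rownames(counts) <- NULL
    }
  }
  if (!is.data.frame(counts))
    counts <- data.frame(from = integer(0), to = integer(0),
                         count = integer(0))
  new("TransitionGraph", nodes = nodes, edges = counts,
      selfLoops = selfLoops)
}

#' Summary metrics of a transition graph
#'
#' @param graph a [TransitionGraph-class].
#' @return A list with `nNodes`, `nDistinctEdges`, `totalTransitions` (sum of
#'   edge counts, self-loops excluded), `maxEdgeShare` (largest edge count
#'   over total transitions, 0 for an empty graph), and `selfLoopTotal`.
#' @export
graphMetrics <- function(graph) {
  stopifnot(is(graph, "TransitionGraph"))
  tot <- sum(graph@edges$count)
  list(nNodes = length(graph@nodes),
       nDistinctEdges = nrow(graph@edges),
       totalTransitions = tot,
       maxEdgeShare = if (tot > 0) max(graph@edges$count) / tot else 0,
       selfLoopTotal = sum(graph@selfLoops))
}

.toIgraph <- function(graph) {
  e <- graph@edges
  sl <- which(graph@selfLoops > 0)
  if (length(sl))
    e <- rbind(e, data.frame(from = sl, to = sl,
                             count = graph@selfLoops[sl]))
  igraph::graph_from_data_frame(
    transform(e, from = as.character(from), to = as.character(to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph@nodes)))
}

#' Export a transition graph
#'
#' `edgelist` writes tab-separated `from`, `to`, `count` rows (header line
#' included; self-loops appear as rows with `from == to`, so the edge list
#' round-trips through [importEdgeList()] exactly). `dot` and `graphml`
#' delegate to igraph and carry the count as an edge attribute.
#'
#' @param graph a [TransitionGraph-class].
#' @param path output file.
#' @param format `"edgelist"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(graph, path, format = c("edgelist", "dot", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(graph, "TransitionGraph"))
  if (format == "edgelist") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("from\tto\tcount", con)
    e <- graph@edges
    sl <- which(graph@selfLoops > 0)
    if (length(sl))
      e <- rbind(e, data.frame(from = sl, to = sl,
                               count = graph@selfLoops[sl]))
    if (nrow(e)) {
      e <- e[order(e$from, e$to), , drop = FALSE]
      writeLines(sprintf("%d\t%d\t%d", e$from, e$to, e$count), con)
    }
  } else {
    igraph::write_graph(.toIgraph(graph), path, format = format)
  }
  invisible(path)
}

#' Read a transition graph back from an edge list
#'
#' @param path file written by [exportGraph()] with `format = "edgelist"`.
#' @param nEnsembles optional node count (defaults to the largest id seen).
#' @return A [TransitionGraph-class].
#' @export
importEdgeList <- function(path, nEnsembles = NULL) {
  d <- utils::read.delim(path, header = TRUE)
  K <- as.integer(nEnsembles %||%
                    if (nrow(d)) max(d$from, d$to) else 0L)
  selfLoops <- integer(K)
  loops <- d$from == d$to
  for (i in which(loops)) selfLoops[d$from[i]] <- d$count[i]
  e <- d[!loops, , drop = FALSE]
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new("TransitionGraph", nodes = seq_len(K),
      edges = data.frame(from = as.integer(e$from), to = as.integer(e$to),
                         count = as.integer(e$count)),
      selfLoops = selfLoops)
}
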