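#' Load a binary raster from a text file
#'
#' Two plain-text layouts are supported. `matrix`: one row per neuron, 0/1
#' cells separated by commas or whitespace. `events`: header lines
#' `#N=<int>`, `#F=<int>`, `#fps=<float>` followed by one
#' `neuron<TAB>frame` record per event, with 0-based indices; duplicate
#' events collapse to a single 1.
#'
#' @param path file to read.
#' @param format `"matrix"` or `"events"`.
#' @param fps frame rate in frames per second. Required for `matrix` files
#'   (the matrix itself carries no rate); for `events` files it overrides the
#'   header value when given.
#' @return A validated [Raster-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("1 0 1", "0 1 0"), f)
#' loadRaster(f, "matrix", fps = 4)
#' @export
loadRaster <- function(path, format = c("matrix", "events"), fps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty raster file: ", path)
  if (format == "matrix") {
    if (is.null(fps)) stop("fps must be supplied for matrix-format rasters")
    rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.numeric)
    nc <- lengths(rows)
    if (length(unique(nc)) != 1L)
      stop("ragged matrix file: rows have differing frame counts")
    m <- do.call(rbind, rows)
    bad <- which(!(m %in% c(0, 1) & !is.na(m)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-binary value at row %d, column %d of %s",
                   bad[1, 1], bad[1, 2], path))
    Raster(m, fps = fps)
  } else {
    hdr <- grep("^#", lines, value = TRUE)
    getHdr <- function(key) {
      h <- grep(paste0("#", key, "="), hdr, value = TRUE, fixed = TRUE)
      if (!length(h)) stop("events header is missing #", key, "=")
      as.numeric(sub(paste0(".*#", key, "="), "", h[1L]))
    }
    N <- as.integer(getHdr("N")); F <- as.integer(getHdr("F"))
    fileFps <- tryCatch(getHdr("fps"), error = function(e) NA_real_)
    if (is.null(fps)) fps <- fileFps
    if (is.na(fps)) stop("no fps in header and none supplied")
    recs <- lines[!grepl("^#", lines)]
    m <- matrix(0L, N, F)
    if (length(recs)) {
      parts <- do.call(rbind, strsplit(trimws(recs), "[\t[:space:]]+"))
      nrn <- as.integer(parts[, 1]); frm <- as.integer(parts[, 2])
      out <- which(nrn < 0L | nrn >= N | frm < 0L | frm >= F)
      if (length(out))
        stop(sprintf("event (%d, %d) out of declared bounds N=%d, F=%d",
                     nrn[out[1L]], frm[out[1L]], N, F))
      m[cbind(nrn + 1L, frm + 1L)] <- 1L  # duplicates collapse
    }
    Raster(m, fps = fps)
  }
}

#' Write a raster to a text file
#'
#' Inverse of [loadRaster()]: `load(save(r))` reproduces `r` bit-exactly in
#' both formats. Event records use 0-based indices; the events header carries
#' N, F and fps.
#'
#' @param raster a [Raster-class].
#' @param path file to write.
#' @param format `"matrix"` or `"events"`.
#' @return `path`, invisibly.
#' @export
saveRaster <- function(raster, path, format = c("matrix", "events")) {
  format <- match.arg(format)
  stopifnot(is(raster, "Raster"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  if (format == "matrix") {
    writeLines(apply(raster@activity, 1L, paste, collapse = " "), con)
  } else {
    writeLines(sprintf("#N=%d", nNeurons(raster)), con)
    writeLines(sprintf("#F=%d", nFrames(raster)), con)
    writeLines(sprintf("#fps=%s", format(raster@fps, digits = 15)), con)
    ev <- which(raster@activity == 1L, arr.ind = TRUE)
    if (nrow(ev)) {
      ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
      writeLines(sprintf("%d\t%d", ev[, 1] - 1L, ev[, 2] - 1L), con)
    }
  }
  invisible(path)
}

#' Restrict a raster to a subset of neurons
#'
#' Keeps the frame axis and frame rate; rows are returned in the order of
#' `neurons`. Used to build per-ensemble subrasters.
#'
#' @param raster a [Raster-class].
#' @param neurons non-empty vector of 1-based neuron indices.
#' @return A [Raster-class] with `length(neurons)` rows.
#' @export
subRaster <- function(raster, neurons) {
  stopifnot(is(raster, "Raster"))
  neurons <- as.integer(neurons)
  if (!length(neurons)) stop("neuron subset must be non-empty")
  if (any(neurons < 1L | neurons > nNeurons(raster)))
    stop("neuron index out of range 1..", nNeurons(raster))
  ids <- if (length(raster@neuronIds)) raster@neuronIds[neurons] else character(0)
  Raster(raster@activity[neurons, , drop = FALSE], raster@fps, ids)
}
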