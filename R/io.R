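#' Read and write trace and track tables
#'
#' Traces are stored as CSV with columns `trace_id`, `vertex_index`,
#' `x_um`, `y_um`; tracks with columns `track_id`, `frame`, `t_min`,
#' `x_um`, `y_um` (an optional `treatment_time` column is preserved).
#'
#' @param traces,tracks Data frames in the package's tidy layouts.
#' @param path File path.
#' @return Readers return the validated data frame; writers return the
#'   path invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_traces_csv <- function(traces, path) {
  need <- c("trace_id", "vertex_index", "x_um", "y_um")
  stopifnot(all(need %in% names(traces)))
  write.csv(traces[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path)
  need <- c("trace_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("trace CSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df <- df[order(df$trace_id, df$vertex_index), ]
  class(df) <- c("neurite_traces", "data.frame")
  df
}

#' @rdname trace_io
#' @export
write_tracks_csv <- function(tracks, path) {
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  stopifnot(all(need %in% names(tracks)))
  keep <- c(need, intersect("treatment_time", names(tracks)))
  write.csv(tracks[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("track CSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df[order(df$track_id, df$frame), ]
}

#' Read and write single-channel images as 32-bit float TIFF
#'
#' TIFF float storage covers `[0, 1]`, so images are divided by
#' `intensity_scale` on write and multiplied back on read; pass the same
#' scale to both (e.g. the photon budget for count images).
#'
#' @param img Numeric matrix in the package's `[ix, iy]` convention.
#' @param path File path.
#' @param intensity_scale Intensity divisor; defaults to 1 (image already
#'   in `[0, 1]`).
#' @return `read_image_tiff` returns the matrix; the writer returns the
#'   path invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_image_tiff <- function(img, path, intensity_scale = 1) {
  stopifnot_scalar_pos(intensity_scale, "intensity_scale")
  x <- pmin(pmax(img / intensity_scale, 0), 1)
  # tiff expects row = image row (y); transpose from [ix, iy]
  tiff::writeTIFF(t(x), path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname image_io
#' @export
read_image_tiff <- function(path, intensity_scale = 1) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  t(x) * intensity_scale
}

#' Write a ground-truth JSON sidecar
#'
#' @param truth A list of ground-truth values (parameter objects are
#'   unclassed).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(rapply(list(truth), unclass, how = "list")[[1]],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
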