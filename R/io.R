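#' Read a multi-page TIFF movie
#'
#' @param path TIFF file (grayscale, one page per frame).
#' @param frame_rate_hz,pixel_size_um acquisition metadata (not stored in the
#'   TIFF).
#' @return a [fluorescence_movie()].
#' @export
read_movie <- function(path, frame_rate_hz = 20, pixel_size_um = 7.68) {
  if (!file.exists(path)) stop("read_movie: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!length(pages)) stop("read_movie: no frames in ", path)
  d <- dim(pages[[1]])
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), d)) {
      stop("read_movie: frame ", k, " has inconsistent dimensions")
    }
  }
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  fluorescence_movie(frames, frame_rate_hz, pixel_size_um)
}

#' Write a movie as 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and stored as uint16 (values must fit
#' in 0..65535); a movie with integer-valued intensities round-trips
#' bit-exactly through [read_movie()].
#'
#' @param movie a [fluorescence_movie()].
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_movie <- function(movie, path, force = FALSE) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  if (file.exists(path) && !force) {
    stop("write_movie: ", path, " exists (use force = TRUE)")
  }
  v <- round(movie$frames)
  if (any(v < 0) || any(v > 65535)) {
    stop("write_movie: intensities outside the uint16 range")
  }
  pages <- lapply(seq_len(dim(v)[1]), function(t) v[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an event catalog as CSV
#'
#' One row per event: `onset_s`, `duration_s`, `n_voxels`, `peak_dff`,
#' `restricted_area_um2`, `region`. An empty catalog yields a valid CSV with
#' a header only.
#'
#' @param catalog an `event_catalog`.
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_catalog <- function(catalog, path, force = FALSE) {
  stopifnot(inherits(catalog, "event_catalog"))
  if (file.exists(path) && !force) {
    stop("write_catalog: ", path, " exists (use force = TRUE)")
  }
  df <- catalog_table(catalog)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tabulate an event catalog
#'
#' @param catalog an `event_catalog`.
#' @return data.frame with one row per event.
#' @export
catalog_table <- function(catalog) {
  if (!length(catalog$events)) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      n_voxels = integer(0), peak_dff = numeric(0),
                      restricted_area_um2 = numeric(0),
                      region = character(0)))
  }
  do.call(rbind, lapply(catalog$events, function(ev) {
    data.frame(onset_s = (ev$onset_frame - 1) / catalog$frame_rate_hz,
               duration_s = ev$duration_s,
               n_voxels = ev$n_voxels,
               peak_dff = ev$peak_dff,
               restricted_area_um2 = ev$restricted_area_um2,
               region = ev$region)
  }))
}

# format numerics at full double precision so CSV round trips are lossless
full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write ROI positions and traces as CSV
#'
#' Positions go to `<stem>_positions.csv` (`cell_id`, `x_um`, `y_um`) and
#' traces to `<stem>_traces.csv` (one column per cell, one row per frame),
#' both at full double precision so numeric payloads round-trip losslessly.
#'
#' @param traces a [roi_trace_set()].
#' @param stem output path stem.
#' @param force overwrite existing files.
#' @return the two paths, invisibly.
#' @export
write_traces <- function(traces, stem, force = FALSE) {
  stopifnot(inherits(traces, "roi_trace_set"))
  p_pos <- paste0(stem, "_positions.csv")
  p_tr <- paste0(stem, "_traces.csv")
  for (p in c(p_pos, p_tr)) {
    if (file.exists(p) && !force) stop("write_traces: ", p, " exists")
  }
  pos <- data.frame(cell_id = traces$cell_ids,
                    x_um = traces$positions[, 1],
                    y_um = traces$positions[, 2])
  write.csv(full_precision(pos), p_pos, row.names = FALSE)
  tr <- as.data.frame(t(traces$traces))
  names(tr) <- paste0("cell_", traces$cell_ids)
  write.csv(full_precision(tr), p_tr, row.names = FALSE)
  invisible(c(positions = p_pos, traces = p_tr))
}

#' Read ROI positions and traces written by [write_traces()]
#'
#' @param stem path stem used at write time.
#' @param frame_rate_hz,application_time_s,baseline_span_s recording
#'   metadata (not stored in the CSVs).
#' @return a [roi_trace_set()].
#' @export
read_traces <- function(stem, frame_rate_hz, application_time_s,
                        baseline_span_s = 2700) {
  p_pos <- paste0(stem, "_positions.csv")
  p_tr <- paste0(stem, "_traces.csv")
  for (p in c(p_pos, p_tr)) {
    if (!file.exists(p)) stop("read_traces: file not found: ", p)
  }
  pos <- read.csv(p_pos)
  need <- c("cell_id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(pos))
  if (length(missing_cols)) {
    stop("read_traces: positions file missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tr <- as.matrix(read.csv(p_tr))
  roi_trace_set(cell_ids = pos$cell_id,
                positions = cbind(pos$x_um, pos$y_um),
                traces = t(tr), frame_rate_hz = frame_rate_hz,
                application_time_s = application_time_s,
                baseline_span_s = baseline_span_s)
}
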