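#' Fluorescence movie container
#'
#' A raw wide-field recording: a `T x H x W` array of non-negative intensities
#' (arbitrary units) with its acquisition geometry. Frames are indexed
#' `(t, y, x)`.
#'
#' @param frames numeric array with `dim = c(T, H, W)`.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param pixel_size_um pixel edge length in micrometers.
#' @return an object of class `fluorescence_movie`.
#' @export
fluorescence_movie <- function(frames, frame_rate_hz = 20, pixel_size_um = 7.68) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("fluorescence_movie: frames must be finite and non-negative")
  }
  assert_positive(frame_rate_hz, "frame_rate_hz")
  assert_positive(pixel_size_um, "pixel_size_um")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "fluorescence_movie"
  )
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fluorescence_movie> %d frames, %dx%d px, %.3g Hz, %.3g um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' Per-pixel area in square micrometers
#'
#' The published per-pixel area for a 7.68-um pixel is the rounded integer
#' 59 um^2; `mode = "rounded"` (the default) reproduces that convention so
#' worked examples match printed values bit-exactly, `mode = "exact"` uses the
#' unrounded square.
#'
#' @param pixel_size_um pixel edge length in micrometers.
#' @param mode `"rounded"` (integer um^2) or `"exact"`.
#' @return scalar area in um^2.
#' @export
pixel_area_um2 <- function(pixel_size_um = 7.68, mode = c("rounded", "exact")) {
  mode <- match.arg(mode)
  a <- pixel_size_um^2
  if (mode == "rounded") round(a) else a
}

#' Convert a raw movie to dF/F0 with a moving-average baseline
#'
#' F0 is the per-pixel moving average of the raw intensity over `window`
#' frames. The window is centered and truncated symmetrically at the movie
#' edges, which avoids the onset bias of a trailing window.
#'
#' @param movie a [fluorescence_movie()].
#' @param window moving-average length in frames (default 500).
#' @return an object of class `dff_movie` with fields `dff` (same shape as the
#'   input), `baseline_window_frames`, `frame_rate_hz`, `pixel_size_um`.
#' @export
compute_dff <- function(movie, window = 500L) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  window <- as.integer(window)
  if (window < 2L) stop("compute_dff: window must be >= 2 frames")
  d <- dim(movie$frames)
  nt <- d[1]
  if (nt < window) stop("compute_dff: movie shorter than the baseline window")

  m <- movie$frames
  dim(m) <- c(nt, d[2] * d[3])
  f0 <- moving_average_cols(m, window)
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)[1, ]
    px <- arrayInd(bad[2], d[2:3])
    stop(sprintf(
      "compute_dff: non-positive F0 at pixel (y=%d, x=%d), frame %d; raw movie invalid",
      px[1], px[2], bad[1]))
  }
  dff <- m / f0 - 1
  dim(dff) <- d
  structure(
    list(dff = dff, baseline_window_frames = window,
         frame_rate_hz = movie$frame_rate_hz,
         pixel_size_um = movie$pixel_size_um),
    class = "dff_movie"
  )
}

# Centered moving average down the rows of a matrix, window truncated at the
# edges. Row t averages rows [t - floor((w-1)/2), t + ceiling((w-1)/2)]
# clipped to [1, T].
moving_average_cols <- function(m, window) {
  nt <- nrow(m)
  lo <- pmax(1L, seq_len(nt) - ((window - 1L) %/% 2L))
  hi <- pmin(nt, seq_len(nt) + ((window - 1L) - (window - 1L) %/% 2L))
  cs <- apply(m, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nt)
  cs0 <- rbind(0, cs)
  (cs[hi, , drop = FALSE] - cs0[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Detect network events by thresholded 3D connected components
#'
#' Voxels with dF/F0 below `threshold` are zeroed; the remaining voxels are
#' grouped by connected-component labeling in `(t, y, x)` and components with
#' at least `min_event_size` voxels are returned as network events. The
#' default connectivity treats voxels as connected in time and/or space
#' (26-neighborhood); 6-connectivity (faces only) is selectable.
#'
#' @param dff a `dff_movie` from [compute_dff()] (or any object with fields
#'   `dff`, `frame_rate_hz`, `pixel_size_um`).
#' @param threshold detection threshold as a dF/F0 fraction (default 0.12).
#' @param min_event_size minimum voxels per event (default 300).
#' @param connectivity `"26"` or `"6"`.
#' @return an `event_catalog`: list with `events` (each a `network_event`),
#'   `detection_params`, movie metadata `dims`, `frame_rate_hz`,
#'   `pixel_size_um`. Events are sorted by onset frame.
#' @export
detect_network_events <- function(dff, threshold = 0.12, min_event_size = 300L,
                                  connectivity = c("26", "6")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.list(dff), !is.null(dff$dff))
  a <- dff$dff
  if (!all(is.finite(a))) stop("detect_network_events: dff must be finite")
  d <- dim(a)
  fg <- which(a >= threshold)
  events <- list()
  if (length(fg)) {
    comp <- label_sparse_components(fg - 1L, as.integer(d),
                                    as.integer(connectivity))
    by_comp <- split(fg, comp)
    sizes <- lengths(by_comp)
    keep <- by_comp[sizes >= min_event_size]
    events <- lapply(keep, function(idx) {
      voxels_from_indices(idx, d, a, dff$frame_rate_hz)
    })
    events <- events[order(vapply(events, `[[`, 1L, "onset_frame"))]
    names(events) <- NULL
  }
  structure(
    list(events = events,
         detection_params = list(threshold_dff = threshold,
                                 min_event_size = as.integer(min_event_size),
                                 connectivity = connectivity),
         dims = d, frame_rate_hz = dff$frame_rate_hz,
         pixel_size_um = dff$pixel_size_um),
    class = "event_catalog"
  )
}

# Build a network_event from linear voxel indices into a (T,H,W) array.
voxels_from_indices <- function(idx, d, a, frame_rate_hz) {
  vox <- arrayInd(idx, d)            # columns t, y, x
  colnames(vox) <- c("t", "y", "x")
  onset <- min(vox[, "t"])
  offset <- max(vox[, "t"])
  structure(
    list(voxels = vox,
         voxel_values = a[idx],
         n_voxels = nrow(vox),
         onset_frame = onset, offset_frame = offset,
         duration_s = (offset - onset + 1) / frame_rate_hz,
         peak_dff = max(a[idx]),
         footprint_px = unique(vox[, c("y", "x"), drop = FALSE]),
         restricted_area_um2 = NA_real_,
         region = NA_character_),
    class = "network_event"
  )
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event_catalog> %d events (threshold %.3g, min size %d, %s-connectivity)\n",
              length(x$events), x$detection_params$threshold_dff,
              x$detection_params$min_event_size,
              x$detection_params$connectivity))
  invisible(x)
}

#' Restrict an event's area to pixels near its peak
#'
#' Wide-field optics scatter light, so the suprathreshold footprint
#' overestimates the activated cortical surface. The restricted area counts
#' only the unique pixels whose within-event maximum dF/F0 reaches `fraction`
#' of the event's peak, times the per-pixel area.
#'
#' @param event a `network_event`.
#' @param dff the `dff_movie` the event was detected in (used for pixel size).
#' @param fraction restriction level in (0, 1] (default 0.67).
#' @param area_mode passed to [pixel_area_um2()].
#' @return list with `restricted_area_um2`, `restricted_footprint_px`
#'   (matrix of y, x) and `n_restricted_px`.
#' @export
restrict_event_area <- function(event, dff, fraction = 0.67,
                                area_mode = c("rounded", "exact")) {
  area_mode <- match.arg(area_mode)
  stopifnot(inherits(event, "network_event"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("restrict_event_area: fraction must lie in (0, 1]")
  }
  key <- paste(event$voxels[, "y"], event$voxels[, "x"])
  pixmax <- tapply(event$voxel_values, key, max)
  pass <- names(pixmax)[pixmax >= fraction * event$peak_dff]
  yx <- do.call(rbind, lapply(strsplit(pass, " "), as.integer))
  colnames(yx) <- c("y", "x")
  list(
    restricted_area_um2 = nrow(yx) * pixel_area_um2(dff$pixel_size_um, area_mode),
    restricted_footprint_px = yx,
    n_restricted_px = nrow(yx)
  )
}

#' Annotate a catalog with restricted areas and region labels
#'
#' Computes each event's 67%-of-peak restricted footprint and, when region
#' masks are supplied, assigns the region containing the majority of the
#' restricted footprint pixels (`NA` when no region holds a majority).
#'
#' @param catalog an `event_catalog`.
#' @param dff the source `dff_movie`.
#' @param regions optional named list of `H x W` logical masks.
#' @param fraction,area_mode passed to [restrict_event_area()].
#' @return the catalog with per-event `restricted_area_um2`,
#'   `restricted_footprint_px` and `region` filled in.
#' @export
annotate_catalog <- function(catalog, dff, regions = NULL, fraction = 0.67,
                             area_mode = c("rounded", "exact")) {
  area_mode <- match.arg(area_mode)
  d <- catalog$dims
  if (!is.null(regions)) {
    stopifnot(is.list(regions), !is.null(names(regions)))
    for (m in regions) stopifnot(identical(dim(m), d[2:3]))
  }
  catalog$events <- lapply(catalog$events, function(ev) {
    r <- restrict_event_area(ev, dff, fraction, area_mode)
    ev$restricted_area_um2 <- r$restricted_area_um2
    ev$restricted_footprint_px <- r$restricted_footprint_px
    if (!is.null(regions)) {
      frac_in <- vapply(regions, function(m) {
        mean(m[r$restricted_footprint_px])
      }, numeric(1))
      ev$region <- if (max(frac_in) > 0.5) names(regions)[which.max(frac_in)]
                   else NA_character_
    }
    ev
  })
  catalog
}

#' Event-frequency time course in fixed bins
#'
#' Counts events (by onset) in consecutive `bin_s` bins over the recording and
#' converts counts to Hz. With `region` set, only events assigned that region
#' label by [annotate_catalog()] are counted.
#'
#' @param catalog an `event_catalog`.
#' @param bin_s bin length in seconds (default 300, i.e. 5-min averages).
#' @param region optional region name to filter on.
#' @return data.frame with `bin_start_s`, `bin_end_s`, `n_events`,
#'   `frequency_hz`.
#' @export
event_frequency_timecourse <- function(catalog, bin_s = 300, region = NULL) {
  duration_s <- catalog$dims[1] / catalog$frame_rate_hz
  if (bin_s > duration_s) {
    stop("event_frequency_timecourse: bin longer than the recording")
  }
  nbin <- floor(duration_s / bin_s)
  starts <- (seq_len(nbin) - 1) * bin_s
  events <- catalog$events
  if (!is.null(region)) {
    events <- Filter(function(ev) identical(ev$region, region), events)
  }
  onset_s <- vapply(events, function(ev) (ev$onset_frame - 1) / catalog$frame_rate_hz,
                    numeric(1))
  counts <- if (length(onset_s)) {
    tabulate(findInterval(onset_s, c(starts, nbin * bin_s),
                          rightmost.closed = TRUE), nbins = nbin)
  } else rep(0L, nbin)
  data.frame(bin_start_s = starts, bin_end_s = starts + bin_s,
             n_events = counts, frequency_hz = counts / bin_s)
}

#' Peak parameters for 1D trace event detection
#'
#' @param lowpass_cutoff_hz zero-phase low-pass corner frequency (default 2).
#' @param prominence minimum topographic prominence in dF/F0 units.
#' @param min_peak_height minimum absolute peak height in dF/F0 units.
#' @return a `trace_peak_params` list.
#' @export
trace_peak_params <- function(lowpass_cutoff_hz = 2, prominence, min_peak_height) {
  assert_positive(lowpass_cutoff_hz, "lowpass_cutoff_hz")
  structure(list(lowpass_cutoff_hz = lowpass_cutoff_hz,
                 prominence = prominence,
                 min_peak_height = min_peak_height),
            class = "trace_peak_params")
}

#' Detect events in a 1D dF/F0 trace (awake recordings)
#'
#' Recordings from unanesthetized animals carry high-frequency movement
#' artifacts, so the trace is low-pass filtered (4th-order zero-phase
#' Butterworth) before local maxima with sufficient prominence and height are
#' returned. Parameters are meant to be fixed across the epochs of one
#' recording.
#'
#' @param trace numeric dF/F0 vector.
#' @param frame_rate_hz sampling rate of the trace.
#' @param params a [trace_peak_params()].
#' @return data.frame with `frame`, `time_s`, `amplitude`, `prominence`.
#' @export
detect_trace_peaks <- function(trace, frame_rate_hz, params) {
  stopifnot(inherits(params, "trace_peak_params"))
  nyq <- frame_rate_hz / 2
  if (params$lowpass_cutoff_hz >= nyq) {
    stop("detect_trace_peaks: low-pass cutoff must be below Nyquist")
  }
  bf <- signal::butter(4, params$lowpass_cutoff_hz / nyq, type = "low")
  filt <- as.numeric(signal::filtfilt(bf, trace))
  pk <- find_peaks(filt)
  keep <- pk$prominence >= params$prominence &
          filt[pk$index] >= params$min_peak_height
  data.frame(frame = pk$index[keep],
             time_s = (pk$index[keep] - 1) / frame_rate_hz,
             amplitude = filt[pk$index[keep]],
             prominence = pk$prominence[keep])
}

# Local maxima with topographic prominence. A peak's prominence is its height
# above the higher of the two minima separating it from larger peaks (or from
# the trace ends).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(index = integer(0), prominence = numeric(0)))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    left <- x[1:i]
    higher_l <- which(left > x[i])
    base_l <- if (length(higher_l)) min(x[max(higher_l):i]) else min(left)
    right <- x[i:n]
    higher_r <- which(right > x[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[i] - max(base_l, base_r)
  }, numeric(1))
  list(index = idx, prominence = prom)
}
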