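#' Specification for a synthetic wide-field movie
#'
#' Defines the conditions a synthetic recording emulates: spontaneous network
#' events at a known rate (defaults to the 0.042 Hz baseline frequency typical
#' of immature visual cortex), Gaussian event footprints with a
#' rise-then-decay calcium kernel, and additive Gaussian noise whose SD is at
#' most a third of the 12% detection threshold.
#'
#' Events are spatial Gaussians (SD `event_blob_sigma_um`) multiplied by a
#' temporal kernel that rises linearly over 0.1 s and decays exponentially
#' with time constant `calcium_decay_s`. Event onsets are Poisson in number;
#' onset frames are redrawn until the occupied frame spans are pairwise
#' disjoint, which keeps ground-truth voxel sets non-overlapping.
#'
#' @param height_px,width_px frame size in pixels.
#' @param frame_rate_hz acquisition rate (default 20 Hz).
#' @param pixel_size_um pixel edge (default 7.68 um).
#' @param duration_s recording length in seconds.
#' @param event_rate_hz event rate per region (default 0.042 Hz).
#' @param event_blob_sigma_um spatial SD of an event footprint (default 40 um).
#' @param event_peak_dff peak dF/F0 of an injected event (default 0.30).
#' @param calcium_decay_s decay time constant of the calcium kernel (default 1).
#' @param noise_sd_dff additive Gaussian noise SD in dF/F0 units (default
#'   0.03; must not exceed `threshold/3` for the default 0.12 threshold).
#' @param region_masks optional named list of `H x W` logical masks; events are
#'   injected per region at `event_rate_hz` each.
#' @param application_time_s optional epoch boundary after which the event
#'   rate is multiplied by `post_rate_factor` (emulates a pharmacological
#'   application).
#' @param post_rate_factor rate multiplier after `application_time_s`
#'   (default 1; 0.5 emulates a halving of event frequency).
#' @param n_events optional fixed event count overriding the Poisson draw
#'   (whole-field only).
#' @param seed integer RNG seed.
#' @return a `widefield_synth_spec` list.
#' @export
widefield_synth_spec <- function(height_px = 64, width_px = 64,
                                 frame_rate_hz = 20, pixel_size_um = 7.68,
                                 duration_s = 600, event_rate_hz = 0.042,
                                 event_blob_sigma_um = 40,
                                 event_peak_dff = 0.30, calcium_decay_s = 1,
                                 noise_sd_dff = 0.03, region_masks = NULL,
                                 application_time_s = NULL,
                                 post_rate_factor = 1,
                                 n_events = NULL, seed = 1L) {
  for (nm in c("height_px", "width_px", "frame_rate_hz", "pixel_size_um",
               "duration_s", "event_blob_sigma_um", "event_peak_dff",
               "calcium_decay_s")) {
    assert_positive(get(nm), nm)
  }
  stopifnot(event_rate_hz >= 0, noise_sd_dff >= 0, post_rate_factor >= 0)
  if (noise_sd_dff > 0.12 / 3) {
    stop("widefield_synth_spec: noise_sd_dff exceeds threshold/3 (0.04); ",
         "the emulated regime requires the 12% threshold to be >= 3x the noise SD")
  }
  structure(as.list(environment()), class = "widefield_synth_spec")
}

#' Generate a synthetic wide-field movie with ground truth
#'
#' Builds a raw-intensity movie `F = F0_baseline * (1 + dff) + noise` with a
#' constant `F0_baseline` of 1000 a.u., so that dF/F0 conversion round-trips
#' the injected signal. Ground truth records, per event, the voxels that
#' exceed the 12% threshold after the same moving-average dF/F0 conversion the
#' detector applies (on the noiseless movie), the onset frame, and the
#' injected and recovered peak dF/F0.
#'
#' @param spec a [widefield_synth_spec()].
#' @param threshold_dff threshold used to define ground-truth voxel sets
#'   (default 0.12).
#' @param baseline_window_frames F0 window assumed for the ground-truth
#'   round trip (default 500).
#' @return list with `movie` (a [fluorescence_movie()]) and `ground_truth`
#'   (an `event_catalog` of injected events plus generator metadata).
#' @export
generate_widefield_movie <- function(spec, threshold_dff = 0.12,
                                     baseline_window_frames = 500L) {
  stopifnot(inherits(spec, "widefield_synth_spec"))
  nt <- round(spec$duration_s * spec$frame_rate_hz)
  if (nt < baseline_window_frames) {
    stop("generate_widefield_movie: duration shorter than the baseline window")
  }
  h <- spec$height_px; w <- spec$width_px
  set.seed(spec$seed)

  regions <- spec$region_masks
  if (is.null(regions)) {
    # default region: keep event centers 2 sigma away from the field edge so
    # suprathreshold footprints (radius ~1.35 sigma at the default peak and
    # threshold) are never clipped and ground-truth voxel counts are stable
    margin <- ceiling(2 * spec$event_blob_sigma_um / spec$pixel_size_um)
    m <- matrix(FALSE, h, w)
    if (h > 2 * margin && w > 2 * margin) {
      m[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
    } else {
      m[, ] <- TRUE
    }
    regions <- list(field = m)
  }

  # event span in frames: 0.1 s linear rise + decay to < 2% of peak
  rise_fr <- max(1L, round(0.1 * spec$frame_rate_hz))
  decay_fr <- ceiling(4 * spec$calcium_decay_s * spec$frame_rate_hz)
  span_fr <- rise_fr + decay_fr

  events <- list()
  occupied <- rep(FALSE, nt)
  draw_onsets <- function(n, lo_frame, hi_frame) {
    out <- integer(0)
    for (k in seq_len(n)) {
      cand <- lo_frame:max(lo_frame, hi_frame - span_fr)
      for (try in 1:200) {
        o <- cand[sample.int(length(cand), 1L)]
        sl <- o:min(nt, o + span_fr - 1L)
        if (!any(occupied[sl])) {
          occupied[sl] <<- TRUE
          out <- c(out, o)
          break
        }
      }
    }
    out
  }

  for (rn in names(regions)) {
    mask_px <- which(regions[[rn]], arr.ind = TRUE)
    if (!is.null(spec$n_events)) {
      n_base <- spec$n_events; n_post <- 0L
      t_split <- nt
    } else if (!is.null(spec$application_time_s)) {
      t_split <- round(spec$application_time_s * spec$frame_rate_hz)
      n_base <- rpois(1, spec$event_rate_hz * spec$application_time_s)
      n_post <- rpois(1, spec$event_rate_hz * spec$post_rate_factor *
                        (spec$duration_s - spec$application_time_s))
    } else {
      t_split <- nt
      n_base <- rpois(1, spec$event_rate_hz * spec$duration_s)
      n_post <- 0L
    }
    onsets <- c(draw_onsets(n_base, 1L, t_split),
                if (n_post > 0) draw_onsets(n_post, t_split + 1L, nt))
    for (o in onsets) {
      c_idx <- mask_px[sample(nrow(mask_px), 1L), ]
      events[[length(events) + 1L]] <- list(
        onset_frame = o, center_yx = unname(c_idx), region = rn)
    }
  }
  if (length(events)) {
    events <- events[order(vapply(events, `[[`, 1L, "onset_frame"))]
  }

  # additive construction of the injected dff field
  dff <- array(0, dim = c(nt, h, w))
  sig_px <- spec$event_blob_sigma_um / spec$pixel_size_um
  half_ext <- ceiling(4 * sig_px)
  tau_fr <- spec$calcium_decay_s * spec$frame_rate_hz
  kern_t <- c(seq_len(rise_fr) / rise_fr,
              exp(-(seq_len(decay_fr)) / tau_fr))
  for (ev in events) {
    ys <- max(1L, ev$center_yx[1] - half_ext):min(h, ev$center_yx[1] + half_ext)
    xs <- max(1L, ev$center_yx[2] - half_ext):min(w, ev$center_yx[2] + half_ext)
    g <- outer(exp(-(ys - ev$center_yx[1])^2 / (2 * sig_px^2)),
               exp(-(xs - ev$center_yx[2])^2 / (2 * sig_px^2)))
    ts <- ev$onset_frame:min(nt, ev$onset_frame + length(kern_t) - 1L)
    kt <- kern_t[seq_along(ts)]
    dff[ts, ys, xs] <- dff[ts, ys, xs] +
      spec$event_peak_dff * outer(kt, g)
  }

  f0_base <- 1000
  raw_clean <- f0_base * (1 + dff)
  raw <- raw_clean
  if (spec$noise_sd_dff > 0) {
    raw <- raw + f0_base * spec$noise_sd_dff * rnorm(length(raw))
    raw[raw < 0] <- 0
  }
  movie <- fluorescence_movie(raw, spec$frame_rate_hz, spec$pixel_size_um)

  # ground truth through the detector's own dF/F0 round trip (noiseless)
  clean_movie <- fluorescence_movie(raw_clean, spec$frame_rate_hz,
                                    spec$pixel_size_um)
  clean_dff <- compute_dff(clean_movie, baseline_window_frames)
  gt_events <- lapply(events, function(ev) {
    ts <- ev$onset_frame:min(nt, ev$onset_frame + span_fr - 1L)
    sub <- clean_dff$dff[ts, , , drop = FALSE]
    idx_sub <- which(sub >= threshold_dff)
    vox <- arrayInd(idx_sub, dim(sub))
    vox[, 1] <- vox[, 1] + ev$onset_frame - 1L
    colnames(vox) <- c("t", "y", "x")
    vals <- sub[idx_sub]
    structure(
      list(voxels = vox, voxel_values = vals, n_voxels = nrow(vox),
           onset_frame = if (nrow(vox)) min(vox[, "t"]) else ev$onset_frame,
           offset_frame = if (nrow(vox)) max(vox[, "t"]) else ev$onset_frame,
           duration_s = if (nrow(vox))
             (max(vox[, "t"]) - min(vox[, "t"]) + 1) / spec$frame_rate_hz
             else 0,
           peak_dff = if (nrow(vox)) max(vals) else 0,
           injected_peak_dff = spec$event_peak_dff,
           footprint_px = unique(vox[, c("y", "x"), drop = FALSE]),
           restricted_area_um2 = NA_real_,
           region = ev$region,
           center_yx = ev$center_yx),
      class = "network_event")
  })
  ground_truth <- structure(
    list(events = gt_events,
         detection_params = list(threshold_dff = threshold_dff,
                                 min_event_size = NA_integer_,
                                 connectivity = "ground-truth"),
         dims = c(nt, h, w), frame_rate_hz = spec$frame_rate_hz,
         pixel_size_um = spec$pixel_size_um,
         spec = spec),
    class = "event_catalog")

  list(movie = movie, ground_truth = ground_truth)
}

#' Match detected events to ground truth by voxel-set IoU
#'
#' Greedy one-to-one matching on intersection-over-union of `(t, y, x)` voxel
#' sets, largest IoU first.
#'
#' @param detected,truth `event_catalog` objects over the same movie.
#' @return data.frame with one row per matched pair (`detected_idx`,
#'   `truth_idx`, `iou`) plus attributes `n_unmatched_detected` and
#'   `n_unmatched_truth`.
#' @export
match_events <- function(detected, truth) {
  key <- function(ev, dims) {
    ev$voxels[, "t"] + dims[1] * (ev$voxels[, "y"] - 1L) +
      dims[1] * dims[2] * (ev$voxels[, "x"] - 1L)
  }
  dims <- detected$dims
  dk <- lapply(detected$events, key, dims = dims)
  tk <- lapply(truth$events, key, dims = dims)
  pairs <- expand.grid(d = seq_along(dk), g = seq_along(tk))
  if (nrow(pairs)) {
    pairs$iou <- mapply(function(i, j) {
      inter <- length(intersect(dk[[i]], tk[[j]]))
      if (inter == 0) return(0)
      inter / length(union(dk[[i]], tk[[j]]))
    }, pairs$d, pairs$g)
    pairs <- pairs[pairs$iou > 0, , drop = FALSE]
    pairs <- pairs[order(-pairs$iou), , drop = FALSE]
    used_d <- used_g <- integer(0)
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      if (!(pairs$d[r] %in% used_d) && !(pairs$g[r] %in% used_g)) {
        keep[r] <- TRUE
        used_d <- c(used_d, pairs$d[r]); used_g <- c(used_g, pairs$g[r])
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  } else {
    pairs$iou <- numeric(0)
  }
  out <- data.frame(detected_idx = pairs$d, truth_idx = pairs$g, iou = pairs$iou)
  attr(out, "n_unmatched_detected") <- length(detected$events) - nrow(out)
  attr(out, "n_unmatched_truth") <- length(truth$events) - nrow(out)
  out
}
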