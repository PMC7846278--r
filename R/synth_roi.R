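#' Specification for a synthetic ROI population
#'
#' Emulates a two-photon field of view: cells scattered uniformly in a square
#' field, population events at a Poisson rate in which each cell participates
#' with probability `participation_prob`, distance-structured pairwise
#' correlations that decay with length scale `participation_corr_scale_um`,
#' and an exactly subtractive drop of every pair's target correlation after
#' the application time.
#'
#' Defaults place per-cell event frequency near 0.03 Hz
#' (`shared_event_rate_hz * participation_prob`), the baseline frequency of
#' spontaneous calcium events in immature visual cortex, over a 45-min
#' baseline.
#'
#' @param n_cells number of cells (>= 2).
#' @param fov_um field edge length in micrometers (default 300).
#' @param frame_rate_hz imaging rate (default 5, within the 4-7 Hz range).
#' @param baseline_duration_s baseline epoch length (default 2700 = 45 min).
#' @param post_duration_s post-application epoch length (default 2700).
#' @param shared_event_rate_hz population-event rate (default 0.18).
#' @param participation_prob per-cell participation probability per event
#'   (default 0.175; sparse-participation regime, so that
#'   `rate * participation` matches the 0.03 Hz per-cell frequency while the
#'   epoch holds enough events for stable correlation estimates).
#' @param participation_corr_scale_um correlation decay length (default 100).
#' @param proximal_corr target trace correlation of co-located pairs
#'   (default 0.7).
#' @param distal_corr target trace correlation floor at large distance
#'   (default 0.25).
#' @param subtractive_shift drop applied to every pair's target correlation
#'   after the application time, in correlation units (floored at the
#'   generator's feasibility minimum, effectively 0).
#' @param event_amplitude_dff transient amplitude (default 0.5).
#' @param transient_decay_s calcium transient decay constant (default 2).
#' @param noise_sd additive white-noise SD in dF/F0 units (default 0.05).
#' @param seed integer RNG seed.
#' @return a `roi_synth_spec` list.
#' @export
roi_synth_spec <- function(n_cells = 50, fov_um = 300, frame_rate_hz = 5,
                           baseline_duration_s = 2700, post_duration_s = 2700,
                           shared_event_rate_hz = 0.18,
                           participation_prob = 0.175,
                           participation_corr_scale_um = 100,
                           proximal_corr = 0.7, distal_corr = 0.25,
                           subtractive_shift = 0,
                           event_amplitude_dff = 0.5,
                           transient_decay_s = 2, noise_sd = 0.05,
                           seed = 1L) {
  if (n_cells < 2) stop("roi_synth_spec: n_cells must be >= 2")
  stopifnot(subtractive_shift >= 0, subtractive_shift <= 1,
            participation_prob > 0, participation_prob < 1,
            proximal_corr > distal_corr, noise_sd >= 0)
  assert_positive(fov_um, "fov_um")
  assert_positive(shared_event_rate_hz, "shared_event_rate_hz")
  structure(as.list(environment()), class = "roi_synth_spec")
}

# ---- Gaussian-copula calibration -------------------------------------------
#
# Cells participate in a population event when a latent standard normal
# exceeds qnorm(1 - q). The Pearson correlation of two participation
# indicators is a monotone function of the latent correlation (the
# tetrachoric relation); the Pearson correlation of the resulting calcium
# traces is an affine function of the indicator correlation (shot-noise
# algebra for marked Poisson events with an exponential kernel plus white
# noise). Both maps are inverted so the traces hit a prescribed target
# correlation matrix, which makes an exactly subtractive post-epoch shift
# constructible.

# upper-orthant probability P(Z1 > h, Z2 > h) for a standard bivariate normal
bvn_upper_orthant <- function(h, rho) {
  base <- pnorm(-h)^2
  if (abs(rho) < 1e-12) return(base)
  if (rho >= 1 - 1e-9) return(pnorm(-h))
  if (rho <= -1 + 1e-9) return(max(0, 1 - 2 * pnorm(h)))
  dens <- function(r) exp(-h^2 / (1 + r)) / (2 * pi * sqrt(1 - r^2))
  base + integrate(dens, 0, rho, rel.tol = 1e-10)$value
}

# binary (phi) correlation of two participation indicators with marginal q,
# given the latent Gaussian correlation
binary_corr_from_latent <- function(rho_latent, q) {
  h <- qnorm(1 - q)
  p11 <- bvn_upper_orthant(h, rho_latent)
  (p11 - q^2) / (q * (1 - q))
}

# inverse of the tetrachoric relation (monotone in rho_latent)
latent_from_binary_corr <- function(rho_bin, q) {
  if (rho_bin >= binary_corr_from_latent(0.9999, q)) return(0.9999)
  lo_val <- binary_corr_from_latent(-0.9999, q)
  if (rho_bin <= lo_val) return(-0.9999)
  uniroot(function(r) binary_corr_from_latent(r, q) - rho_bin,
          c(-0.9999, 0.9999), tol = 1e-9)$root
}

# project a symmetric matrix to the nearest (in eigenvalue clipping sense)
# positive-semidefinite correlation matrix
nearest_corr_psd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 / tcrossprod(d)
}

# shot-noise map: trace correlation as an affine function of the indicator
# correlation. q participation prob, w relative white-noise power.
#   rho_trace = (q^2 + q (1 - q) rho_bin) / (q + w)
trace_corr_affine <- function(q, w) {
  list(to_binary = function(rho_trace) (rho_trace * (q + w) - q^2) / (q * (1 - q)),
       to_trace = function(rho_bin) (q^2 + q * (1 - q) * rho_bin) / (q + w),
       max_trace = q / (q + w),
       min_trace = 0)  # attained at rho_bin = -q/(1-q) (latent -> -1)
}

# relative noise power w = sigma_n^2 / (a^2 p_e K2) for the exponential
# kernel, p_e the per-frame event probability
relative_noise_power <- function(noise_sd, amplitude, rate_hz, frame_rate_hz,
                                 decay_s) {
  if (noise_sd == 0) return(0)
  p_e <- rate_hz / frame_rate_hz
  k2 <- 1 / (1 - exp(-2 / (decay_s * frame_rate_hz)))
  noise_sd^2 / (amplitude^2 * p_e * k2)
}

#' Generate correlated event traces with prescribed correlation targets
#'
#' Low-level engine behind [generate_roi_population()], exposed so fixtures
#' with bespoke target structures (e.g. a coupling change confined to a cell
#' subgroup) can be built. Population events occur at Poisson times; per
#' event, participation indicators are drawn by thresholding a latent
#' multivariate normal whose correlation matrix is calibrated so the
#' resulting traces attain `c_target` per epoch.
#'
#' @param c_target_baseline,c_target_post target trace correlation matrices
#'   (unit diagonal). `c_target_post = NULL` reuses the baseline target.
#' @param n_frames_baseline,n_frames_post epoch lengths in frames.
#' @param frame_rate_hz imaging rate.
#' @param rate_hz population-event rate.
#' @param q per-cell participation probability.
#' @param amplitude transient amplitude (dF/F0).
#' @param decay_s transient decay constant.
#' @param noise_sd white-noise SD.
#' @return list with `traces` (N x T), `event_frames`, `participation`
#'   (events x N logical), `achieved_target` matrices after feasibility
#'   clipping and PSD projection.
#' @export
synth_correlated_event_traces <- function(c_target_baseline,
                                          c_target_post = NULL,
                                          n_frames_baseline, n_frames_post,
                                          frame_rate_hz, rate_hz, q,
                                          amplitude, decay_s, noise_sd) {
  n <- nrow(c_target_baseline)
  w <- relative_noise_power(noise_sd, amplitude, rate_hz, frame_rate_hz, decay_s)
  aff <- trace_corr_affine(q, w)

  calibrate <- function(c_target) {
    ct <- pmin(c_target, aff$max_trace - 1e-6)
    cb <- aff$to_binary(ct)
    cb <- pmin(pmax(cb, -q / (1 - q) + 1e-6), 1)
    lat <- matrix(1, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lat[i, j] <- lat[j, i] <- latent_from_binary_corr(cb[i, j], q)
    }
    nearest_corr_psd(lat)
  }
  lat_base <- calibrate(c_target_baseline)
  lat_post <- if (is.null(c_target_post)) lat_base else calibrate(c_target_post)

  h <- qnorm(1 - q)
  # Antithetic latent draws: events 2k-1 and 2k use eta_k and -eta_k. Each
  # event's latent vector is still standard normal marginally (symmetry), so
  # pairwise participation probabilities are untouched, but the global
  # event-size mode cancels between paired events, which keeps epoch-level
  # correlation estimates from drifting coherently. The same latent sequence
  # drives both epochs (common random numbers), pairing the conditions so
  # that post-minus-baseline contrasts are not dominated by event-sampling
  # noise. Both are variance-reduction choices, see the methods vignette.
  n_ev_base <- rpois(1, rate_hz / frame_rate_hz * n_frames_baseline)
  n_ev_post <- rpois(1, rate_hz / frame_rate_hz * n_frames_post)
  n_half <- ceiling(max(n_ev_base, n_ev_post, 1) / 2)
  eta <- matrix(rnorm(n_half * n), ncol = n)
  idx <- as.vector(rbind(seq_len(n_half), n_half + seq_len(n_half)))
  eta_seq <- rbind(eta, -eta)[idx, , drop = FALSE]

  sim_epoch <- function(lat, n_frames, n_ev) {
    frames <- sort(sample.int(n_frames, min(n_ev, n_frames)))
    ch <- chol(lat + diag(1e-10, n))
    # assign latent rows to frames in shuffled order: antithetic partners
    # must not sit at adjacent times, or their anticorrelated participations
    # overlap through the calcium kernel and attenuate trace covariances
    ord <- sample.int(length(frames))
    z <- eta_seq[seq_along(frames), , drop = FALSE][ord, , drop = FALSE] %*% ch
    part <- z > h
    spikes <- matrix(0, n_frames, n)
    for (k in seq_along(frames)) {
      spikes[frames[k], part[k, ]] <- spikes[frames[k], part[k, ]] + amplitude
    }
    decay <- exp(-1 / (decay_s * frame_rate_hz))
    traces <- apply(spikes, 2, function(s) {
      as.numeric(stats::filter(s, decay, method = "recursive", init = 0))
    })
    if (noise_sd > 0) traces <- traces + rnorm(length(traces), sd = noise_sd)
    list(traces = t(traces), frames = frames, part = part)
  }

  base <- sim_epoch(lat_base, n_frames_baseline, n_ev_base)
  post <- sim_epoch(lat_post, n_frames_post, n_ev_post)
  list(
    traces = cbind(base$traces, post$traces),
    event_frames = list(baseline = base$frames,
                        post = post$frames + n_frames_baseline),
    participation = list(baseline = base$part, post = post$part),
    achieved_target = list(
      baseline = aff$to_trace(pmin(pmax(
        vapply_mat(lat_base, function(r) binary_corr_from_latent(r, q)),
        -q / (1 - q)), 1)),
      post = aff$to_trace(pmin(pmax(
        vapply_mat(lat_post, function(r) binary_corr_from_latent(r, q)),
        -q / (1 - q)), 1))),
    relative_noise_power = w
  )
}

# apply a scalar function to the off-diagonal entries of a symmetric matrix
vapply_mat <- function(m, f) {
  out <- m
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- f(m[i, j])
  }
  diag(out) <- 1
  out
}

#' Generate a synthetic ROI population with known correlation structure
#'
#' Cells are placed uniformly in the field; the target baseline correlation of
#' a pair at distance `d` is
#' `distal_corr + (proximal_corr - distal_corr) * exp(-d^2 / (2 * scale^2))`,
#' and after the application time every pair's target is reduced by
#' `subtractive_shift` (floored at the generator's feasibility minimum).
#'
#' @param spec a [roi_synth_spec()].
#' @return list with `traces` (a `roi_trace_set`) and `ground_truth`
#'   (positions, per-epoch target correlation matrices, participation
#'   indicators, per-cell event counts, spec).
#' @export
generate_roi_population <- function(spec) {
  stopifnot(inherits(spec, "roi_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  pos <- cbind(x_um = runif(n, 0, spec$fov_um),
               y_um = runif(n, 0, spec$fov_um))
  d <- as.matrix(dist(pos))
  lam <- spec$participation_corr_scale_um
  c_base <- spec$distal_corr +
    (spec$proximal_corr - spec$distal_corr) * exp(-d^2 / (2 * lam^2))
  diag(c_base) <- 1
  c_post <- pmax(c_base - spec$subtractive_shift, 0)
  diag(c_post) <- 1

  nf_base <- round(spec$baseline_duration_s * spec$frame_rate_hz)
  nf_post <- round(spec$post_duration_s * spec$frame_rate_hz)
  sim <- synth_correlated_event_traces(
    c_base, c_post, nf_base, nf_post, spec$frame_rate_hz,
    spec$shared_event_rate_hz, spec$participation_prob,
    spec$event_amplitude_dff, spec$transient_decay_s, spec$noise_sd)

  traces <- roi_trace_set(
    cell_ids = seq_len(n), positions = pos, traces = sim$traces,
    frame_rate_hz = spec$frame_rate_hz,
    application_time_s = spec$baseline_duration_s,
    baseline_span_s = spec$baseline_duration_s)

  per_cell_events <- list(
    baseline = colSums(sim$participation$baseline),
    post = colSums(sim$participation$post))

  list(traces = traces,
       ground_truth = list(
         positions = pos, distances_um = d,
         target_corr_baseline = c_base, target_corr_post = c_post,
         achieved_target = sim$achieved_target,
         event_frames = sim$event_frames,
         participation = sim$participation,
         per_cell_event_counts = per_cell_events,
         relative_noise_power = sim$relative_noise_power,
         spec = spec))
}
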