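#' Specification for synthetic electrophysiology traces
#'
#' Fixture generator for the patch-clamp feature extractors: postsynaptic
#' currents (PSCs) as biexponential events at Poisson times, and parametric
#' action-potential (AP) waveforms with analytically known features.
#'
#' @param sample_rate_hz digitization rate (>= 20 kHz; default 50 kHz).
#' @param psc_rate_hz PSC rate (default 2 Hz).
#' @param psc_amplitude_pa PSC peak amplitude (default 30 pA).
#' @param psc_rise_ms,psc_decay_ms biexponential time constants (rise < decay;
#'   defaults 0.5 and 5 ms).
#' @param ap_overshoot_mv AP peak above 0 mV (default 15).
#' @param ap_halfwidth_ms AP width at half amplitude (default 1).
#' @param ap_threshold_mv AP threshold voltage (default -40).
#' @param noise_sd_pa,noise_sd_mv additive white-noise SDs (defaults 0).
#' @param seed integer RNG seed.
#' @return an `ephys_synth_spec` list.
#' @export
ephys_synth_spec <- function(sample_rate_hz = 50000, psc_rate_hz = 2,
                             psc_amplitude_pa = 30, psc_rise_ms = 0.5,
                             psc_decay_ms = 5, ap_overshoot_mv = 15,
                             ap_halfwidth_ms = 1, ap_threshold_mv = -40,
                             noise_sd_pa = 0, noise_sd_mv = 0, seed = 1L) {
  if (sample_rate_hz < 20000) {
    stop("ephys_synth_spec: sample_rate_hz must be >= 20 kHz")
  }
  if (psc_rise_ms >= psc_decay_ms) {
    stop("ephys_synth_spec: rise must be faster than decay")
  }
  stopifnot(psc_rate_hz >= 0, noise_sd_pa >= 0, noise_sd_mv >= 0)
  structure(as.list(environment()), class = "ephys_synth_spec")
}

#' Normalized biexponential PSC waveform
#'
#' `w(t) = (exp(-t/decay) - exp(-t/rise)) / peak`, scaled to unit peak at
#' `t_peak = rise*decay/(decay-rise) * log(decay/rise)`.
#'
#' @param t_ms time from onset (ms); values < 0 give 0.
#' @param rise_ms,decay_ms time constants (ms).
#' @return waveform values in \[0, 1\].
#' @export
psc_waveform <- function(t_ms, rise_ms, decay_ms) {
  tp <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  peak <- exp(-tp / decay_ms) - exp(-tp / rise_ms)
  out <- (exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)) / peak
  out[t_ms < 0] <- 0
  out
}

#' Analytic 20-80% rise time of a biexponential PSC
#'
#' Root-finding on the closed-form waveform: the time between the upward
#' crossings of 20% and 80% of peak.
#'
#' @param rise_ms,decay_ms time constants (ms).
#' @return rise time in ms.
#' @export
psc_rise_time_2080 <- function(rise_ms, decay_ms) {
  tp <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  crossing <- function(level) {
    uniroot(function(t) psc_waveform(t, rise_ms, decay_ms) - level,
            c(1e-9, tp), tol = 1e-12)$root
  }
  crossing(0.8) - crossing(0.2)
}

#' Generate a synthetic PSC current trace with ground truth
#'
#' Sums unit-peak biexponential events (scaled to `psc_amplitude_pa`) at
#' Poisson onset times over `duration_s`, plus white noise. Events are
#' positive-going (outward-current sign convention; detectors work on
#' magnitudes).
#'
#' @param spec an [ephys_synth_spec()].
#' @param duration_s trace length in seconds.
#' @return list with `trace` (pA), `sample_rate_hz` and `ground_truth`
#'   (data.frame of `onset_s`, `amplitude_pa`, plus the analytic
#'   `rise_time_2080_ms`).
#' @export
generate_psc_trace <- function(spec, duration_s = 60) {
  stopifnot(inherits(spec, "ephys_synth_spec"))
  assert_positive(duration_s, "duration_s")
  set.seed(spec$seed)
  fs <- spec$sample_rate_hz
  n <- round(duration_s * fs)
  trace <- numeric(n)
  n_ev <- rpois(1, spec$psc_rate_hz * duration_s)
  onsets <- sort(runif(n_ev, 0, duration_s - 0.05))
  kern_len <- round(fs * (spec$psc_decay_ms * 8) / 1000)
  t_ms <- (seq_len(kern_len) - 1) / fs * 1000
  kern <- psc_waveform(t_ms, spec$psc_rise_ms, spec$psc_decay_ms)
  for (o in onsets) {
    i0 <- round(o * fs) + 1L
    sl <- i0:min(n, i0 + kern_len - 1L)
    trace[sl] <- trace[sl] + spec$psc_amplitude_pa * kern[seq_along(sl)]
  }
  if (spec$noise_sd_pa > 0) trace <- trace + rnorm(n, sd = spec$noise_sd_pa)
  list(trace = trace, sample_rate_hz = fs,
       ground_truth = data.frame(
         onset_s = onsets,
         amplitude_pa = rep(spec$psc_amplitude_pa, n_ev),
         rise_time_2080_ms = rep(
           psc_rise_time_2080(spec$psc_rise_ms, spec$psc_decay_ms), n_ev)))
}

#' Generate a parametric AP voltage trace with analytic ground truth
#'
#' A square current pulse at `pulse_onset_s` drives a slow linear
#' depolarization from rest to threshold over `dtime_ms` (slope kept below
#' the 20 mV/ms threshold criterion), followed by a triangular spike: linear
#' rise at `rise_slope_mv_per_ms` to the peak, linear fall at
#' `fall_slope_mv_per_ms` back to rest. Triangle geometry gives the
#' half-width in closed form: `amp/2 * (1/rise_slope + 1/fall_slope)`.
#'
#' @param spec an [ephys_synth_spec()] (peak = `ap_overshoot_mv`, threshold =
#'   `ap_threshold_mv`).
#' @param v_rest_mv resting potential (default -70).
#' @param pulse_onset_s pulse onset (default 0.01 s).
#' @param dtime_ms time from pulse onset to threshold (default 3).
#' @param rise_slope_mv_per_ms,fall_slope_mv_per_ms spike slopes (defaults
#'   200 and 100).
#' @param duration_s trace length (default 0.05).
#' @return list with `trace` (mV), `sample_rate_hz` and `ground_truth`
#'   (overshoot, amplitude, halfwidth, dtime, threshold, max dV/dt).
#' @export
generate_ap_trace <- function(spec, v_rest_mv = -70, pulse_onset_s = 0.01,
                              dtime_ms = 3, rise_slope_mv_per_ms = 200,
                              fall_slope_mv_per_ms = 100, duration_s = 0.05) {
  stopifnot(inherits(spec, "ephys_synth_spec"))
  fs <- spec$sample_rate_hz
  n <- round(duration_s * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- rep(v_rest_mv, n)
  thr <- spec$ap_threshold_mv
  peak <- spec$ap_overshoot_mv
  amp <- peak - thr
  on_ms <- pulse_onset_s * 1000
  thr_ms <- on_ms + dtime_ms
  ramp_slope <- (thr - v_rest_mv) / dtime_ms   # mV/ms, well below 20
  if (ramp_slope >= 20) {
    stop("generate_ap_trace: pre-threshold ramp would exceed the dV/dt criterion")
  }
  peak_ms <- thr_ms + amp / rise_slope_mv_per_ms
  end_ms <- peak_ms + (peak - v_rest_mv) / fall_slope_mv_per_ms
  seg <- t_ms >= on_ms & t_ms < thr_ms
  v[seg] <- v_rest_mv + ramp_slope * (t_ms[seg] - on_ms)
  seg <- t_ms >= thr_ms & t_ms < peak_ms
  v[seg] <- thr + rise_slope_mv_per_ms * (t_ms[seg] - thr_ms)
  seg <- t_ms >= peak_ms & t_ms < end_ms
  v[seg] <- peak - fall_slope_mv_per_ms * (t_ms[seg] - peak_ms)
  # write the apex onto the nearest sample so the sampled peak equals the
  # nominal peak regardless of grid alignment
  v[which.min(abs(t_ms - peak_ms))] <- peak
  if (spec$noise_sd_mv > 0) {
    set.seed(spec$seed)
    v <- v + rnorm(n, sd = spec$noise_sd_mv)
  }
  list(trace = v, sample_rate_hz = fs,
       ground_truth = list(
         overshoot_mv = peak, amplitude_mv = amp,
         halfwidth_ms = amp / 2 * (1 / rise_slope_mv_per_ms +
                                     1 / fall_slope_mv_per_ms),
         dtime_ms = dtime_ms, threshold_mv = thr,
         pulse_onset_s = pulse_onset_s,
         max_dvdt_mv_per_ms = rise_slope_mv_per_ms))
}
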