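#' Detect postsynaptic-current events
#'
#' Template-free derivative-threshold detector: the trace is boxcar-smoothed,
#' its first derivative thresholded at `deriv_k` times the robust noise SD of
#' the derivative, and each suprathreshold run becomes a candidate onset.
#' Amplitude is measured from a local baseline (median over the
#' `baseline_window_ms` preceding onset) to the peak within `peak_window_ms`;
#' the 20-80% rise time is obtained by linear interpolation between
#' fractional crossings on the rising phase, and the rise rate is
#' amplitude / rise time (pA/ms).
#'
#' @param trace numeric current trace (pA, positive-going events).
#' @param sample_rate_hz digitization rate.
#' @param min_amplitude_pa discard events smaller than this (default 5).
#' @param deriv_k derivative threshold in robust-SD units (default 4).
#' @param smooth_ms boxcar width (default 0.2).
#' @param baseline_window_ms local-baseline span before onset (default 2).
#' @param peak_window_ms search span after onset (default 10).
#' @param refractory_ms minimum spacing between onsets (default 2).
#' @return data.frame with `onset_s`, `amplitude_pa`, `rise_time_2080_ms`,
#'   `rise_rate_pa_per_ms`; zero rows when nothing is detected.
#' @export
detect_psc_events <- function(trace, sample_rate_hz, min_amplitude_pa = 5,
                              deriv_k = 4, smooth_ms = 0.2,
                              baseline_window_ms = 2, peak_window_ms = 10,
                              refractory_ms = 2) {
  fs <- sample_rate_hz
  stopifnot(all(is.finite(trace)))
  box <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- as.numeric(stats::filter(trace, rep(1 / box, box), sides = 2))
  sm[is.na(sm)] <- trace[is.na(sm)]
  dv <- c(0, diff(sm))
  sd_dv <- stats::mad(dv, center = 0)
  thr_dv <- if (sd_dv > 0) deriv_k * sd_dv else
    max(1e-12, deriv_k * sd(dv) / 10)  # noiseless traces: any positive slope
  above <- dv > thr_dv
  onset_idx <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(onset_idx)) {
    return(data.frame(onset_s = numeric(0), amplitude_pa = numeric(0),
                      rise_time_2080_ms = numeric(0),
                      rise_rate_pa_per_ms = numeric(0)))
  }
  refr <- round(refractory_ms / 1000 * fs)
  keep <- c(TRUE, diff(onset_idx) > refr)
  onset_idx <- onset_idx[keep]

  bw <- max(1L, round(baseline_window_ms / 1000 * fs))
  pw <- max(2L, round(peak_window_ms / 1000 * fs))
  n <- length(trace)
  rows <- lapply(onset_idx, function(i0) {
    b0 <- max(1L, i0 - bw)
    base <- median(trace[b0:max(b0, i0 - 1L)])
    sl <- i0:min(n, i0 + pw)
    pk_rel <- which.max(trace[sl])
    pk_idx <- sl[pk_rel]
    amp <- trace[pk_idx] - base
    if (!is.finite(amp) || amp < min_amplitude_pa) return(NULL)
    seg <- trace[i0:pk_idx] - base
    cross <- function(level) {
      tgt <- level * amp
      k <- which(seg >= tgt)[1]
      if (is.na(k) || k == 1L) return(0)
      # linear interpolation between samples k-1 and k
      (k - 2 + (tgt - seg[k - 1]) / (seg[k] - seg[k - 1])) / fs * 1000
    }
    rt <- cross(0.8) - cross(0.2)
    if (rt <= 0) rt <- 1 / fs * 1000  # degenerate single-sample rise
    data.frame(onset_s = (i0 - 1) / fs, amplitude_pa = amp,
               rise_time_2080_ms = rt, rise_rate_pa_per_ms = amp / rt)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(onset_s = numeric(0), amplitude_pa = numeric(0),
                      rise_time_2080_ms = numeric(0),
                      rise_rate_pa_per_ms = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Event frequency in fixed bins
#'
#' Frequency timelines of postsynaptic currents: event counts in consecutive
#' bins of `bin_s` seconds (the conventional choices are 50 or 90 s),
#' divided by the bin length.
#'
#' @param onset_s event onset times in seconds.
#' @param duration_s segment length.
#' @param bin_s bin length (default 50).
#' @return data.frame with `bin_start_s`, `n_events`, `frequency_hz`.
#' @export
bin_frequency <- function(onset_s, duration_s, bin_s = 50) {
  if (bin_s > duration_s) stop("bin_frequency: bin longer than the segment")
  nbin <- floor(duration_s / bin_s)
  starts <- (seq_len(nbin) - 1) * bin_s
  counts <- if (length(onset_s)) {
    tabulate(findInterval(onset_s, c(starts, nbin * bin_s),
                          rightmost.closed = TRUE), nbins = nbin)
  } else rep(0L, nbin)
  data.frame(bin_start_s = starts, n_events = counts,
             frequency_hz = counts / bin_s)
}

#' Action-potential waveform features
#'
#' Threshold is the first sample (after `pulse_onset_s`) where dV/dt reaches
#' `dvdt_threshold` mV/ms. Features follow the standard definitions:
#' overshoot = peak above 0 mV; amplitude = peak minus threshold voltage;
#' width at half amplitude via linear interpolation of the crossings; dTime =
#' pulse onset to threshold crossing; max dV/dt of the first derivative.
#'
#' @param trace voltage trace (mV) containing exactly one AP after the pulse.
#' @param sample_rate_hz digitization rate.
#' @param pulse_onset_s current-pulse onset in seconds.
#' @param dvdt_threshold threshold criterion in mV/ms (default 20, the common
#'   convention).
#' @return list of class `ap_features`: `threshold_mv`, `peak_mv`,
#'   `overshoot_mv`, `amplitude_mv`, `halfwidth_ms`, `dtime_ms`,
#'   `max_dvdt_mv_per_ms`.
#' @export
ap_features <- function(trace, sample_rate_hz, pulse_onset_s,
                        dvdt_threshold = 20) {
  fs <- sample_rate_hz
  # forward difference: the threshold sample is the one from which the
  # suprathreshold rise departs, avoiding a one-sample bias on steep spikes
  dvdt <- c(diff(trace), 0) * fs / 1000   # mV per ms
  start <- max(1L, round(pulse_onset_s * fs) + 1L)
  cand <- which(dvdt[start:length(trace)] >= dvdt_threshold)
  if (!length(cand)) stop("ap_features: no AP detected (dV/dt criterion not reached)")
  thr_idx <- start + cand[1] - 1L
  v_thr <- trace[thr_idx]
  pk_idx <- thr_idx - 1L + which.max(trace[thr_idx:length(trace)])
  v_peak <- trace[pk_idx]
  amp <- v_peak - v_thr
  if (amp <= 0) stop("ap_features: non-positive amplitude")
  half <- v_thr + amp / 2

  interp_cross <- function(i, j) {
    # crossing of `half` between samples i and j (j = i +/- 1)
    (i - 1 + (half - trace[i]) / (trace[j] - trace[i]) * (j - i)) / fs * 1000
  }
  up <- which(trace[thr_idx:pk_idx] >= half)[1] + thr_idx - 1L
  t_up <- if (up == thr_idx) (up - 1) / fs * 1000 else interp_cross(up - 1L, up)
  after <- trace[pk_idx:length(trace)]
  dn_rel <- which(after < half)[1]
  if (is.na(dn_rel)) stop("ap_features: trace ends before repolarization")
  dn <- pk_idx + dn_rel - 1L
  t_dn <- interp_cross(dn - 1L, dn)

  list_out <- list(
    threshold_mv = v_thr, peak_mv = v_peak,
    overshoot_mv = v_peak,            # amplitude above 0 mV
    amplitude_mv = amp,
    halfwidth_ms = t_dn - t_up,
    dtime_ms = (thr_idx - 1) / fs * 1000 - pulse_onset_s * 1000,
    max_dvdt_mv_per_ms = max(dvdt))
  if (v_peak < 0) list_out$overshoot_mv <- NA_real_
  structure(list_out, class = "ap_features")
}

#' Ramp-protocol excitability (f-I by ISI bins)
#'
#' The ramp (default -100 to 140 pA at 96 pA/s, i.e. 2.5 s) is divided into
#' 175-ms bins. Spike times are upward crossings of `spike_threshold_mv`;
#' each inter-spike interval is assigned to the bin containing its first
#' spike, the mean ISI per bin inverted to an instantaneous frequency, and
#' paired with the mean injected current of the same bin. Bins with fewer
#' than 2 spikes are reported empty (`NA`).
#'
#' @param trace voltage trace (mV) covering the ramp.
#' @param sample_rate_hz digitization rate.
#' @param ramp list with `start_pa`, `end_pa`, `rate_pa_per_s`, `onset_s`.
#' @param bin_ms bin length (default 175).
#' @param spike_threshold_mv spike detection level (default 0).
#' @param include_partial include the trailing partial bin (default TRUE,
#'   flagged in the output).
#' @return a `ramp_response` data.frame: `bin_start_s`, `bin_end_s`,
#'   `mean_injected_pa`, `n_spikes`, `mean_isi_s`, `instantaneous_freq_hz`,
#'   `partial`.
#' @export
ramp_fi <- function(trace, sample_rate_hz,
                    ramp = list(start_pa = -100, end_pa = 140,
                                rate_pa_per_s = 96, onset_s = 0),
                    bin_ms = 175, spike_threshold_mv = 0,
                    include_partial = TRUE) {
  fs <- sample_rate_hz
  ramp_dur <- (ramp$end_pa - ramp$start_pa) / ramp$rate_pa_per_s
  n_full <- as.integer((ramp_dur * 1000) %/% bin_ms)
  edges <- ramp$onset_s + c(seq_len(n_full + 1) - 1) * bin_ms / 1000
  partial <- logical(n_full)
  if (include_partial && max(edges) < ramp$onset_s + ramp_dur - 1e-9) {
    edges <- c(edges, ramp$onset_s + ramp_dur)
    partial <- c(partial, TRUE)
  }
  nbin <- length(edges) - 1L

  x <- trace
  up <- which(x[-1] >= spike_threshold_mv & x[-length(x)] < spike_threshold_mv) + 1L
  spike_t <- (up - 1) / fs

  isi_first <- head(spike_t, -1L)
  isi <- diff(spike_t)
  bin_of <- findInterval(isi_first, edges, rightmost.closed = TRUE)
  spike_bin <- findInterval(spike_t, edges, rightmost.closed = TRUE)

  rows <- lapply(seq_len(nbin), function(b) {
    t0 <- edges[b]; t1 <- edges[b + 1]
    isis <- isi[bin_of == b]
    mean_isi <- if (length(isis) >= 1) mean(isis) else NA_real_
    n_sp <- sum(spike_bin == b)
    data.frame(
      bin_start_s = t0, bin_end_s = t1,
      mean_injected_pa = ramp$start_pa +
        ramp$rate_pa_per_s * ((t0 + t1) / 2 - ramp$onset_s),
      n_spikes = n_sp,
      mean_isi_s = if (n_sp >= 2 || length(isis) >= 1) mean_isi else NA_real_,
      instantaneous_freq_hz = if (!is.na(mean_isi)) 1 / mean_isi else NA_real_,
      partial = partial[b])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_full_bins") <- n_full
  attr(out, "ramp_duration_s") <- ramp_dur
  class(out) <- c("ramp_response", class(out))
  out
}

#' Baseline membrane-potential timeline
#'
#' Per-bin baseline Vm over consecutive `bin_s` bins (default 45 s), as the
#' median of the samples after removing windows around action potentials
#' (samples above `spike_threshold_mv` padded by `clip_pad_ms`). Bins fully
#' occupied by APs are flagged missing.
#'
#' @param trace voltage trace (mV).
#' @param sample_rate_hz digitization rate.
#' @param bin_s bin length (default 45).
#' @param spike_threshold_mv samples above this (default -20) start an AP
#'   window.
#' @param clip_pad_ms padding removed on each side of an AP window (default 5).
#' @return data.frame with `bin_start_s`, `vm_mv`, `n_samples`, `missing`.
#' @export
membrane_potential_timeline <- function(trace, sample_rate_hz, bin_s = 45,
                                        spike_threshold_mv = -20,
                                        clip_pad_ms = 5) {
  fs <- sample_rate_hz
  n <- length(trace)
  duration_s <- n / fs
  if (bin_s > duration_s) {
    stop("membrane_potential_timeline: bin longer than the recording")
  }
  bad <- trace > spike_threshold_mv
  if (any(bad)) {
    pad <- round(clip_pad_ms / 1000 * fs)
    idx <- which(bad)
    for (i in idx) bad[max(1L, i - pad):min(n, i + pad)] <- TRUE
  }
  nbin <- floor(duration_s / bin_s)
  rows <- lapply(seq_len(nbin), function(b) {
    sl <- (round((b - 1) * bin_s * fs) + 1L):round(b * bin_s * fs)
    ok <- sl[!bad[sl]]
    data.frame(bin_start_s = (b - 1) * bin_s,
               vm_mv = if (length(ok)) median(trace[ok]) else NA_real_,
               n_samples = length(ok), missing = length(ok) == 0L)
  })
  do.call(rbind, rows)
}

#' Depolarization between two epochs
#'
#' Voltage difference between the bin exhibiting the peak effect and the last
#' baseline bin.
#'
#' @param peak_epoch_vm_mv Vm of the peak-effect bin.
#' @param last_baseline_vm_mv Vm of the last baseline bin.
#' @return depolarization in mV (positive = depolarized).
#' @export
depolarization <- function(peak_epoch_vm_mv, last_baseline_vm_mv) {
  peak_epoch_vm_mv - last_baseline_vm_mv
}

#' Series-resistance quality control
#'
#' A recording fails when any series-resistance measurement exceeds
#' `abs_limit_mohm`, or when any measurement changes by more than
#' `rel_limit` relative to the first measurement.
#'
#' @param rs_mohm numeric vector of Rs measurements over time (>= 2).
#' @param abs_limit_mohm absolute cutoff (default 30).
#' @param rel_limit relative-change cutoff (default 0.30).
#' @return list with `pass`, `fail_absolute`, `fail_relative`,
#'   `max_rs_mohm`, `max_rel_change`.
#' @export
qc_series_resistance <- function(rs_mohm, abs_limit_mohm = 30,
                                 rel_limit = 0.30) {
  if (length(rs_mohm) < 2L) {
    stop("qc_series_resistance: need at least 2 measurements")
  }
  stopifnot(all(is.finite(rs_mohm)), all(rs_mohm > 0))
  rel <- abs(rs_mohm - rs_mohm[1]) / rs_mohm[1]
  fail_abs <- any(rs_mohm > abs_limit_mohm)
  fail_rel <- any(rel > rel_limit)
  list(pass = !(fail_abs || fail_rel),
       fail_absolute = fail_abs, fail_relative = fail_rel,
       max_rs_mohm = max(rs_mohm), max_rel_change = max(rel))
}
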