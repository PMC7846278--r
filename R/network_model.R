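#' Configuration of the recurrent E/I spiking network
#'
#' A single-sheet cortical network of current-based leaky integrate-and-fire
#' neurons on a 2D square with periodic boundaries. A quarter of the
#' inhibitory population is somatostatin-positive (SST); the neuropeptide
#' perturbation is a shift of the SST resting potential from -60.8 mV to
#' -56.3 mV (the 4.5 mV depolarization measured in current clamp). Excitatory
#' neurons receive a constant 50 pA external current plus a sinusoidal
#' background; SST interneurons receive 40 pA. Connection probability decays
#' with toroidal distance as `p0 * exp(-d^2 / (2 sigma_c^2))` per projection.
#'
#' Intrinsic parameters (capacitance, leak, thresholds) are free
#' configuration; the defaults place the baseline SST rheobase at
#' `g_l * (v_th - v_rest) = 2 * 20.8 = 41.6 pA`, just above the 40 pA drive,
#' so SST firing at baseline is driven by recurrent excitation and the
#' depolarized condition recruits tonic SST firing.
#'
#' @param n_excitatory,n_inhibitory population sizes (defaults 1600/400).
#' @param sst_fraction_of_inhibitory fraction of inhibitory neurons that are
#'   SST (default 0.25).
#' @param sheet_size_um edge of the periodic square sheet (default 400).
#' @param sigma_c_um named list of connectivity length scales per projection
#'   (`ee`, `ei`, `ie`, `ii`); inhibitory axons reach further laterally than
#'   excitatory ones, reflecting the lateral-inhibition geometry of SST
#'   interneurons.
#' @param p0 named list of peak connection probabilities per projection
#'   (`ee`, `ei`, `ie`, `ii`).
#' @param w_e,w_i synaptic weights in pA (excitatory positive, inhibitory
#'   negative).
#' @param tau_e_ms,tau_i_ms synaptic decay constants.
#' @param delay_ms conduction delay.
#' @param lif named list of per-population LIF parameters (`e`, `i`, `sst`),
#'   each with `v_rest`, `v_th`, `v_reset`, `g_l`, `c_m`, `t_ref_ms`.
#' @param i_ext_e_pa,i_ext_sst_pa,i_ext_i_pa external currents (defaults 50,
#'   40, 40 pA).
#' @param sin_amp_pa,sin_freq_hz sinusoidal background to the excitatory
#'   population (defaults 6 pA at 0.5 Hz).
#' @param noise_sd_pa per-step white-noise current SD in pA; a scalar or a
#'   named list per population (`e`, `i`, `sst`). The default drives
#'   excitatory cells with strong fluctuations (the event trigger) while
#'   interneurons are quieter, so SST firing is governed by its resting
#'   potential and recurrent drive.
#' @param duration_s simulated time per condition (default 60).
#' @param dt_ms integration step (default 0.1; must be <= 0.1).
#' @param n_record_e excitatory voltages recorded at `record_every_ms`
#'   (default 60 neurons at 1 ms, i.e. 1 kHz).
#' @param record_every_ms voltage sampling period.
#' @param sst_v_rest_mv baseline SST resting potential (-60.8).
#' @param sst_v_rest_oxt_mv SST resting potential under the neuropeptide
#'   (-56.3).
#' @param oxytocin logical; `TRUE` applies the SST shift.
#' @param seed integer seed for connectivity, positions and noise.
#' @return a `model_config` list.
#' @export
model_config <- function(n_excitatory = 1600, n_inhibitory = 400,
                         sst_fraction_of_inhibitory = 0.25,
                         sheet_size_um = 400,
                         sigma_c_um = list(ee = 100, ei = 100, ie = 140,
                                           ii = 100),
                         p0 = list(ee = 0.20, ei = 0.30, ie = 0.40, ii = 0.30),
                         w_e = 25, w_i = -60,
                         tau_e_ms = 5, tau_i_ms = 10, delay_ms = 1.5,
                         lif = list(
                           e   = list(v_rest = -65, v_th = -40, v_reset = -65,
                                      g_l = 2.5, c_m = 40, t_ref_ms = 2),
                           i   = list(v_rest = -62, v_th = -40, v_reset = -62,
                                      g_l = 2.5, c_m = 25, t_ref_ms = 1.5),
                           sst = list(v_rest = -60.8, v_th = -40, v_reset = -65,
                                      g_l = 2, c_m = 40, t_ref_ms = 2)),
                         i_ext_e_pa = 50, i_ext_sst_pa = 40, i_ext_i_pa = 40,
                         sin_amp_pa = 6, sin_freq_hz = 0.5,
                         noise_sd_pa = list(e = 120, i = 60, sst = 40),
                         duration_s = 60, dt_ms = 0.1,
                         n_record_e = 120, record_every_ms = 1,
                         sst_v_rest_mv = -60.8, sst_v_rest_oxt_mv = -56.3,
                         oxytocin = FALSE, seed = 1L) {
  stopifnot(sst_fraction_of_inhibitory > 0, sst_fraction_of_inhibitory <= 1,
            dt_ms <= 0.1, w_e >= 0, w_i <= 0)
  if (any(unlist(p0) < 0) || any(unlist(p0) > 1)) {
    stop("model_config: connection probabilities must lie in [0, 1]")
  }
  for (pp in lif) {
    if (pp$v_reset >= pp$v_th) stop("model_config: V_reset must be < V_th")
  }
  lif$sst$v_rest <- if (oxytocin) sst_v_rest_oxt_mv else sst_v_rest_mv
  structure(as.list(environment()), class = "model_config")
}

#' Apply the neuropeptide perturbation to a configuration
#'
#' Returns a configuration identical to the input except that the SST
#' resting potential is set to the depolarized value (-56.3 mV; a +4.5 mV
#' shift from the -60.8 mV baseline). Idempotent; no other field changes.
#'
#' @param config a [model_config()].
#' @return the perturbed `model_config`.
#' @export
apply_oxytocin <- function(config) {
  stopifnot(inherits(config, "model_config"))
  config$oxytocin <- TRUE
  config$lif$sst$v_rest <- config$sst_v_rest_oxt_mv
  config
}

# population label per neuron index (E first, then non-SST I, then SST)
population_labels <- function(config) {
  n_sst <- round(config$n_inhibitory * config$sst_fraction_of_inhibitory)
  c(rep("e", config$n_excitatory),
    rep("i", config$n_inhibitory - n_sst),
    rep("sst", n_sst))
}

# toroidal Euclidean distance matrix between rows of two position matrices
torus_distance <- function(a, b, size) {
  dx <- abs(outer(a[, 1], b[, 1], "-"))
  dy <- abs(outer(a[, 2], b[, 2], "-"))
  dx <- pmin(dx, size - dx)
  dy <- pmin(dy, size - dy)
  sqrt(dx^2 + dy^2)
}

#' Build the distance-dependent connectivity of a network
#'
#' Positions are uniform on the periodic sheet; each directed pair (i -> j,
#' i != j) is connected with probability `p0[projection] *
#' exp(-d_ij^2 / (2 sigma_c^2))` under the toroidal metric. E -> * synapses
#' carry `w_e > 0`, I -> * synapses `w_i < 0`.
#'
#' @param config a [model_config()].
#' @return list with `positions` (N x 2, um), `population` (labels),
#'   `syn_ptr`, `syn_tgt`, `syn_w` (CSR adjacency by source, 0-based) and
#'   `n_connections`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  pop <- population_labels(config)
  n <- length(pop)
  pos <- cbind(runif(n, 0, config$sheet_size_um),
               runif(n, 0, config$sheet_size_um))
  d <- torus_distance(pos, pos, config$sheet_size_um)
  is_e_src <- pop == "e"
  sig <- config$sigma_c_um
  if (!is.list(sig)) sig <- list(ee = sig, ei = sig, ie = sig, ii = sig)
  p0_mat <- matrix(0, n, n)
  sg_mat <- matrix(0, n, n)
  p0_mat[is_e_src, is_e_src] <- config$p0$ee
  p0_mat[is_e_src, !is_e_src] <- config$p0$ei
  p0_mat[!is_e_src, is_e_src] <- config$p0$ie
  p0_mat[!is_e_src, !is_e_src] <- config$p0$ii
  sg_mat[is_e_src, is_e_src] <- sig$ee
  sg_mat[is_e_src, !is_e_src] <- sig$ei
  sg_mat[!is_e_src, is_e_src] <- sig$ie
  sg_mat[!is_e_src, !is_e_src] <- sig$ii
  p <- p0_mat * exp(-d^2 / (2 * sg_mat^2))
  if (any(p > 1)) stop("build_network: connection probability exceeds 1")
  diag(p) <- 0
  conn <- matrix(runif(n * n), n, n) < p   # conn[i, j]: i -> j

  syn_ptr <- integer(n + 1L)
  tgt_list <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- which(conn[i, ])
    tgt_list[[i]] <- tg - 1L
    syn_ptr[i + 1L] <- syn_ptr[i] + length(tg)
  }
  syn_tgt <- unlist(tgt_list, use.names = FALSE)
  if (is.null(syn_tgt)) syn_tgt <- integer(0)
  w_src <- ifelse(is_e_src, config$w_e, config$w_i)
  syn_w <- rep(w_src, times = diff(syn_ptr))
  list(positions = pos, population = pop,
       syn_ptr = syn_ptr, syn_tgt = as.integer(syn_tgt),
       syn_w = as.numeric(syn_w), n_connections = length(syn_tgt))
}

# per-neuron LIF parameter vectors in network order
lif_param_vectors <- function(config, pop) {
  take <- function(field) {
    vapply(pop, function(p) config$lif[[p]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  list(v_rest = take("v_rest"), v_th = take("v_th"), v_reset = take("v_reset"),
       g_l = take("g_l"), c_m = take("c_m"), t_ref_ms = take("t_ref_ms"))
}

# per-neuron noise SD vector from a scalar or per-population list
noise_vector <- function(config, pop) {
  ns <- config$noise_sd_pa
  if (!is.list(ns)) ns <- list(e = ns, i = ns, sst = ns)
  vapply(pop, function(p) ns[[p]], numeric(1), USE.NAMES = FALSE)
}

# run one condition on a prebuilt network
run_condition <- function(config, net, condition) {
  pop <- net$population
  pars <- lif_param_vectors(config, pop)
  i_ext <- ifelse(pop == "e", config$i_ext_e_pa,
                  ifelse(pop == "sst", config$i_ext_sst_pa, config$i_ext_i_pa))
  sin_amp <- ifelse(pop == "e", config$sin_amp_pa, 0)
  rec_idx <- seq_len(min(config$n_record_e, config$n_excitatory)) - 1L
  res <- lif_simulate_cpp(
    pars$v_rest, pars$v_th, pars$v_reset, pars$g_l, pars$c_m, pars$t_ref_ms,
    i_ext, sin_amp, config$sin_freq_hz,
    net$syn_ptr, net$syn_tgt, net$syn_w,
    config$tau_e_ms, config$tau_i_ms, config$delay_ms,
    config$dt_ms, config$duration_s,
    rec_idx, config$record_every_ms,
    numeric(0), noise_vector(config, pop), config$seed)
  spikes <- data.frame(neuron = res$spike_id0 + 1L,
                       t_s = res$spike_t_ms / 1000,
                       population = pop[res$spike_id0 + 1L])
  rates <- vapply(c("e", "i", "sst"), function(p) {
    sum(spikes$population == p) / sum(pop == p) / config$duration_s
  }, numeric(1))
  structure(
    list(spikes = spikes, rates_hz = rates,
         v_rec = res$v_rec, recorded_neurons = rec_idx + 1L,
         positions = net$positions, population = pop,
         condition = condition, duration_s = config$duration_s,
         record_every_ms = config$record_every_ms,
         sheet_size_um = config$sheet_size_um),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: %.0f s, rates (Hz) E %.2f | I %.2f | SST %.2f\n",
              x$condition, x$duration_s, x$rates_hz["e"], x$rates_hz["i"],
              x$rates_hz["sst"]))
  invisible(x)
}

#' Simulate the network in baseline and neuropeptide conditions
#'
#' One connectivity draw (seeded) is shared by both conditions; between them
#' only the SST resting potential changes, and the same noise seed is used,
#' so any difference is attributable to the perturbation. Each condition runs
#' for `config$duration_s`.
#'
#' @param config a baseline [model_config()].
#' @return list with elements `baseline` and `oxytocin`, each a `sim_result`
#'   (spike trains, per-population rates, recorded excitatory voltages), plus
#'   `network` (the shared connectivity).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  net <- build_network(config)
  base <- run_condition(config, net, "baseline")
  oxt <- run_condition(apply_oxytocin(config), net, "oxytocin")
  list(baseline = base, oxytocin = oxt, network = net)
}

#' Closed-form firing rate of an isolated LIF neuron
#'
#' For a constant current I, the deterministic LIF fires at
#' `1000 / (t_ref + tau_m * log((V_inf - V_reset) / (V_inf - V_th)))` Hz with
#' `V_inf = V_rest + I / g_l`, and is silent when `V_inf <= V_th`.
#'
#' @param i_pa injected current (pA).
#' @param v_rest,v_th,v_reset membrane parameters (mV).
#' @param g_l leak conductance (nS).
#' @param c_m capacitance (pF).
#' @param t_ref_ms refractory period (ms).
#' @return firing rate in Hz.
#' @export
lif_rate_closed_form <- function(i_pa, v_rest, v_th, v_reset, g_l, c_m,
                                 t_ref_ms) {
  v_inf <- v_rest + i_pa / g_l
  tau_m <- c_m / g_l
  ifelse(v_inf <= v_th, 0,
         1000 / (t_ref_ms + tau_m * log((v_inf - v_reset) / (v_inf - v_th))))
}

#' Simulated f-I curve of an isolated model neuron
#'
#' Rates from constant-current simulations of a synaptically isolated neuron
#' (weights zeroed), per condition.
#'
#' @param config a baseline [model_config()].
#' @param population `"sst"` (default), `"e"` or `"i"`.
#' @param currents_pa current levels (pA).
#' @param duration_s simulated time per level (default 5).
#' @return data.frame with `current_pa`, `rate_baseline_hz`,
#'   `rate_oxytocin_hz`.
#' @export
model_fi_curve <- function(config, population = "sst",
                           currents_pa = seq(0, 140, by = 20),
                           duration_s = 5) {
  stopifnot(inherits(config, "model_config"))
  one <- function(cfg, i_pa) {
    p <- cfg$lif[[population]]
    res <- lif_simulate_cpp(
      p$v_rest, p$v_th, p$v_reset, p$g_l, p$c_m, p$t_ref_ms,
      i_pa, 0, 0,
      c(0L, 0L), integer(0), numeric(0),
      cfg$tau_e_ms, cfg$tau_i_ms, cfg$delay_ms,
      cfg$dt_ms, duration_s,
      integer(0), 1, numeric(0), 0, cfg$seed)  # noise off: deterministic f-I
    length(res$spike_t_ms) / duration_s
  }
  oxt <- apply_oxytocin(config)
  data.frame(
    current_pa = currents_pa,
    rate_baseline_hz = vapply(currents_pa, function(i) one(config, i), numeric(1)),
    rate_oxytocin_hz = vapply(currents_pa, function(i) one(oxt, i), numeric(1)))
}

#' Simulate an isolated model neuron under the ramp protocol
#'
#' Drives a synaptically isolated neuron with the standard one-step ramp
#' (default -100 to 140 pA at 96 pA/s) and returns its voltage trace with
#' spikes marked, ready for [ramp_fi()]. Spike/reset samples are replaced by
#' `spike_mark_mv` so threshold-crossing spike detection sees them.
#'
#' @param config a [model_config()].
#' @param population `"sst"` (default), `"e"` or `"i"`.
#' @param ramp list with `start_pa`, `end_pa`, `rate_pa_per_s`.
#' @param dt_ms integration step (default 0.05).
#' @param spike_mark_mv value written at spike samples (default +10).
#' @return list with `trace` (mV), `sample_rate_hz`, `ramp` (annotated with
#'   `onset_s = 0`).
#' @export
simulate_ramp <- function(config, population = "sst",
                          ramp = list(start_pa = -100, end_pa = 140,
                                      rate_pa_per_s = 96),
                          dt_ms = 0.05, spike_mark_mv = 10) {
  stopifnot(inherits(config, "model_config"))
  p <- config$lif[[population]]
  duration_s <- (ramp$end_pa - ramp$start_pa) / ramp$rate_pa_per_s
  n_steps <- round(duration_s * 1000 / dt_ms)
  res <- lif_simulate_cpp(p$v_rest, p$v_th, p$v_reset, p$g_l, p$c_m,
                          p$t_ref_ms, 0, 0, 0,
                          c(0L, 0L), integer(0), numeric(0),
                          config$tau_e_ms, config$tau_i_ms, config$delay_ms,
                          dt_ms, duration_s, 0L, dt_ms,
                          seq(ramp$start_pa, ramp$end_pa,
                              length.out = n_steps),
                          0, config$seed)
  v <- as.numeric(res$v_rec)
  spike_steps <- round(res$spike_t_ms / dt_ms) + 1L
  v[spike_steps[spike_steps <= length(v)]] <- spike_mark_mv
  list(trace = v, sample_rate_hz = 1000 / dt_ms,
       ramp = c(ramp, list(onset_s = 0)))
}

#' Voltage correlations of excitatory units by distance
#'
#' Pearson correlations between the recorded excitatory voltage traces
#' (sampled at 1 kHz by default), averaged within toroidal-distance bins, per
#' condition, with the per-bin difference. Constant traces are excluded and
#' counted.
#'
#' @param sim result of [simulate_network()].
#' @param breaks_um distance bin edges (default 6 bins spanning the sheet's
#'   maximal toroidal distance).
#' @param clip_spikes replace samples at the reset potential by `NA`-free
#'   linear interpolation before correlating (default FALSE: raw voltages).
#' @param settle_s initial burn-in discarded before correlating (default 1 s;
#'   all cells share the deterministic relaxation from rest to their
#'   operating point, which would otherwise inflate every correlation).
#' @return a `correlation_by_distance` data.frame: `bin_lo_um`, `bin_hi_um`,
#'   `n_pairs`, `corr_baseline`, `corr_oxytocin`, `delta`.
#' @export
voltage_correlations <- function(sim, breaks_um = NULL, clip_spikes = FALSE,
                                 settle_s = 1) {
  base <- sim$baseline; oxt <- sim$oxytocin
  stopifnot(inherits(base, "sim_result"), inherits(oxt, "sim_result"))
  rec <- base$recorded_neurons
  if (length(rec) < 2) stop("voltage_correlations: need >= 2 recorded units")
  pos <- base$positions[rec, , drop = FALSE]
  size <- base$sheet_size_um
  d <- torus_distance(pos, pos, size)
  if (is.null(breaks_um)) {
    breaks_um <- seq(0, size / sqrt(2), length.out = 7)
  }
  prep <- function(v) {
    drop_n <- min(round(settle_s * 1000 / base$record_every_ms), ncol(v) - 2L)
    if (drop_n > 0) v <- v[, -seq_len(drop_n), drop = FALSE]
    if (clip_spikes) {
      v <- apply(v, 1, function(x) {
        bad <- c(FALSE, diff(x) < -20)  # reset transitions
        if (any(bad)) x[bad] <- NA
        x <- stats::approx(seq_along(x), x, xout = seq_along(x), rule = 2)$y
        x
      })
      t(v)
    } else v
  }
  cor_ok <- function(v) {
    keep <- apply(v, 1, sd) > 0
    cm <- matrix(NA_real_, nrow(v), nrow(v))
    if (sum(keep) >= 2) cm[keep, keep] <- cor(t(v[keep, , drop = FALSE]))
    attr(cm, "n_constant") <- sum(!keep)
    cm
  }
  cb <- cor_ok(prep(base$v_rec))
  co <- cor_ok(prep(oxt$v_rec))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  bin <- cut(d[ut], breaks_um, include.lowest = TRUE)
  agg <- function(cm) tapply(cm[ut], bin, mean, na.rm = TRUE)
  mb <- agg(cb); mo <- agg(co)
  out <- data.frame(
    bin_lo_um = head(breaks_um, -1), bin_hi_um = breaks_um[-1],
    n_pairs = as.integer(table(bin)),
    corr_baseline = as.numeric(mb), corr_oxytocin = as.numeric(mo),
    delta = as.numeric(mo - mb))
  attr(out, "n_constant_traces") <- c(baseline = attr(cb, "n_constant"),
                                      oxytocin = attr(co, "n_constant"))
  class(out) <- c("correlation_by_distance", class(out))
  out
}
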