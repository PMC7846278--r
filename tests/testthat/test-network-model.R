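# small fast configuration used across these tests (overridable defaults)
small_config <- function(...) {
  args <- list(n_excitatory = 80, n_inhibitory = 20, duration_s = 2,
               n_record_e = 20, seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}

test_that("the neuropeptide perturbation changes only the SST resting potential", {
  cfg <- model_config(seed = 1)
  oxt <- apply_oxytocin(cfg)
  expect_equal(cfg$lif$sst$v_rest, -60.8)
  expect_equal(oxt$lif$sst$v_rest, -56.3)
  expect_equal(oxt$lif$sst$v_rest - cfg$lif$sst$v_rest, 4.5)
  expect_identical(apply_oxytocin(oxt), oxt)  # idempotent
  # every other field identical
  o2 <- oxt; o2$lif$sst$v_rest <- cfg$lif$sst$v_rest; o2$oxytocin <- FALSE
  expect_identical(o2, cfg)
})

test_that("connectivity respects the distance-dependent profile", {
  cfg0 <- small_config(p0 = list(ee = 0, ei = 0, ie = 0, ii = 0))
  expect_equal(build_network(cfg0)$n_connections, 0L)

  cfg1 <- small_config(p0 = list(ee = 1, ei = 1, ie = 1, ii = 1),
                       sigma_c_um = list(ee = 1e9, ei = 1e9, ie = 1e9, ii = 1e9))
  n <- 100
  expect_equal(build_network(cfg1)$n_connections, n * (n - 1))

  # realized connection fraction tracks p(d) within binomial error
  cfg <- model_config(n_excitatory = 500, n_inhibitory = 125,
                      sigma_c_um = list(ee = 100, ei = 100, ie = 100, ii = 100),
                      p0 = list(ee = 0.2, ei = 0.2, ie = 0.2, ii = 0.2),
                      seed = 3)
  net <- build_network(cfg)
  d <- spontnet:::torus_distance(net$positions, net$positions,
                                 cfg$sheet_size_um)
  conn <- matrix(FALSE, 625, 625)
  for (i in 1:625) {
    tg <- net$syn_tgt[(net$syn_ptr[i] + 1):net$syn_ptr[i + 1]] + 1L
    if (net$syn_ptr[i + 1] > net$syn_ptr[i]) conn[i, tg] <- TRUE
  }
  off <- row(d) != col(d)
  bins <- cut(d[off], seq(0, 250, by = 50))
  emp <- tapply(conn[off], bins, mean)
  expected <- tapply(0.2 * exp(-d[off]^2 / (2 * 100^2)), bins, mean)
  n_bin <- tapply(conn[off], bins, length)
  for (b in seq_along(emp)) {
    se <- sqrt(expected[b] * (1 - expected[b]) / n_bin[b])
    expect_lt(abs(emp[b] - expected[b]), 4 * se + 1e-6)
  }
  expect_error(build_network(small_config(p0 = list(ee = 1.5, ei = 0, ie = 0, ii = 0))),
               "probabilities")
})

test_that("uncoupled subthreshold neurons settle at the predicted fixed point", {
  cfg <- small_config(p0 = list(ee = 0, ei = 0, ie = 0, ii = 0),
                      sin_amp_pa = 0, noise_sd_pa = 0,
                      i_ext_e_pa = 20, i_ext_i_pa = 10, i_ext_sst_pa = 10)
  sim <- simulate_network(cfg)
  expect_equal(nrow(sim$baseline$spikes), 0L)
  v_end <- sim$baseline$v_rec[, ncol(sim$baseline$v_rec)]
  # E fixed point: v_rest + I/g_l = -65 + 20/2.5
  expect_equal(unname(v_end), rep(-65 + 20 / 2.5, length(v_end)),
               tolerance = 0.01)
})

test_that("isolated-neuron rates match the closed-form LIF solution", {
  cfg <- model_config(seed = 2)
  fi <- model_fi_curve(cfg, "sst", currents_pa = seq(10, 140, length.out = 10),
                       duration_s = 5)
  p <- cfg$lif$sst
  for (k in seq_len(nrow(fi))) {
    f_b <- lif_rate_closed_form(fi$current_pa[k], -60.8, p$v_th, p$v_reset,
                                p$g_l, p$c_m, p$t_ref_ms)
    f_o <- lif_rate_closed_form(fi$current_pa[k], -56.3, p$v_th, p$v_reset,
                                p$g_l, p$c_m, p$t_ref_ms)
    # 5-s simulation quantizes rate at 0.2 Hz
    expect_equal(fi$rate_baseline_hz[k], f_b,
                 tolerance = max(0.01 * max(f_b, 1), 0.2 / max(f_b, 1)))
    expect_equal(fi$rate_oxytocin_hz[k], f_o,
                 tolerance = max(0.01 * max(f_o, 1), 0.2 / max(f_o, 1)))
    expect_gte(fi$rate_oxytocin_hz[k], fi$rate_baseline_hz[k])
  }
  # subthreshold in both conditions
  fi0 <- model_fi_curve(cfg, "sst", currents_pa = 10, duration_s = 2)
  expect_equal(fi0$rate_baseline_hz, 0)
  expect_equal(fi0$rate_oxytocin_hz, 0)
})

test_that("simulations are deterministic and respect refractoriness", {
  cfg <- small_config()
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$baseline$spikes, s2$baseline$spikes)
  expect_identical(s1$oxytocin$spikes, s2$oxytocin$spikes)

  sp <- s1$baseline$spikes
  if (nrow(sp) > 1) {
    for (id in unique(sp$neuron)) {
      st <- sort(sp$t_s[sp$neuron == id])
      if (length(st) > 1) {
        t_ref <- cfg$lif[[s1$baseline$population[id]]]$t_ref_ms / 1000
        expect_true(all(diff(st) >= t_ref - 1e-9))
      }
    }
  }
})

test_that("removing inhibition cannot lower excitatory rates", {
  cfg <- small_config(duration_s = 4)
  full <- simulate_network(cfg)
  noinh <- simulate_network(small_config(duration_s = 4, w_i = 0))
  expect_gte(noinh$baseline$rates_hz[["e"]], full$baseline$rates_hz[["e"]])
})

test_that("voltage correlations behave for degenerate inputs", {
  cfg <- small_config(p0 = list(ee = 0, ei = 0, ie = 0, ii = 0),
                      sin_amp_pa = 0, duration_s = 8,
                      noise_sd_pa = list(e = 50, i = 0, sst = 0))
  sim <- simulate_network(cfg)
  vc <- voltage_correlations(sim, breaks_um = c(0, 150, 300))
  # independent noise drives, no coupling: bin-mean correlations near zero
  # (per-pair SE ~ 1/sqrt(duration / (2 tau_m)) ~ 0.06, averaged over pairs)
  expect_true(all(abs(vc$corr_baseline) < 0.1, na.rm = TRUE))

  # duplicated trace at distance zero correlates at 1
  simdup <- sim
  simdup$baseline$v_rec[2, ] <- simdup$baseline$v_rec[1, ]
  simdup$oxytocin$v_rec[2, ] <- simdup$oxytocin$v_rec[1, ]
  pos <- simdup$baseline$positions
  pos[simdup$baseline$recorded_neurons[2], ] <-
    pos[simdup$baseline$recorded_neurons[1], ]
  simdup$baseline$positions <- simdup$oxytocin$positions <- pos
  vc2 <- voltage_correlations(simdup, breaks_um = c(0, 1, 300))
  expect_equal(vc2$corr_baseline[1], 1, tolerance = 1e-9)
})

test_that("the depolarized-SST condition suppresses excitatory firing and synchrony", {
  ok_rate <- 0; ok_corr <- 0; delta_mat <- NULL
  for (s in 1:3) {
    cfg <- model_config(n_excitatory = 240, n_inhibitory = 60, duration_s = 8,
                        n_record_e = 60, seed = s)
    sim <- simulate_network(cfg)
    vc <- voltage_correlations(sim)
    ok_rate <- ok_rate + (sim$oxytocin$rates_hz[["e"]] < sim$baseline$rates_hz[["e"]])
    ok_corr <- ok_corr + (weighted.mean(vc$corr_oxytocin, vc$n_pairs) <
                          weighted.mean(vc$corr_baseline, vc$n_pairs))
    delta_mat <- rbind(delta_mat, vc$delta)
    expect_gt(sim$oxytocin$rates_hz[["sst"]], sim$baseline$rates_hz[["sst"]])
  }
  expect_gte(ok_rate, 2)
  expect_gte(ok_corr, 2)
  expect_lt(mean(delta_mat, na.rm = TRUE), 0)
})
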