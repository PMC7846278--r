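make_traceset <- function(traces, fs = 5, app_s = NULL, positions = NULL) {
  n <- nrow(traces)
  if (is.null(app_s)) app_s <- ncol(traces) / fs / 2
  if (is.null(positions)) positions <- cbind(seq_len(n) * 10, rep(0, n))
  roi_trace_set(seq_len(n), positions, traces, fs, app_s,
                baseline_span_s = app_s)
}

test_that("ROI event detection counts threshold crossings per cell", {
  fs <- 5
  x <- rep(0, 3000)
  for (o in c(300, 900, 1500, 2100)) {
    idx <- o:(o + 100)
    x[idx] <- x[idx] + 0.8 * exp(-(0:100) / (2 * fs))
  }
  noise <- rnorm(3000, sd = 0.02)
  set.seed(1)
  traces <- rbind(x + noise, rnorm(3000, sd = 0.02))
  ts <- make_traceset(traces, fs)
  ev <- detect_roi_events(ts, k_sd = 2)
  expect_length(ev$cells[[1]]$onsets, 4L)
  expect_equal(ev$detection_threshold_sd, 2)

  expect_error(detect_roi_events(make_traceset(rbind(rep(1, 100), rep(0, 100)))),
               "zero noise SD")
})

test_that("false positives on pure noise match the Gaussian tail bound", {
  # k_sd = 5 on 1000 iid Gaussian samples: expected upward crossings of the
  # 5-sigma level ~ 1000 * P(X_t >= 5s, X_{t-1} < 5s) < 1000 * Phi(-5) = 0.0003
  set.seed(42)
  n_fp <- vapply(1:50, function(i) {
    tr <- matrix(rnorm(2000, sd = 0.05), nrow = 2)
    ts <- make_traceset(tr)
    ev <- detect_roi_events(ts, k_sd = 5)
    length(ev$cells[[1]]$onsets) + length(ev$cells[[2]]$onsets)
  }, numeric(1))
  expect_lt(mean(n_fp), 1)
})

test_that("event counts recover the resolvable generator ground truth", {
  g <- generate_roi_population(roi_synth_spec(
    n_cells = 15, baseline_duration_s = 1200, post_duration_s = 300,
    noise_sd = 0.03, seed = 7))
  ev <- detect_roi_events(g$traces, k_sd = 2)
  # two transients closer than the decay-to-rearm time (tau * log(amp /
  # (thr/2)) ~ 5 s = 25 frames) merge into one detectable event; collapse
  # ground-truth onsets accordingly before comparing. Gaps right at the
  # rearm boundary resolve stochastically under noise, so single-event
  # discrepancies remain on a few cells.
  gt <- g$ground_truth
  frames <- c(gt$event_frames$baseline, gt$event_frames$post)
  part <- rbind(gt$participation$baseline, gt$participation$post)
  resolvable <- function(cell) {
    on <- sort(frames[part[, cell]])
    if (!length(on)) return(0L)
    sum(c(TRUE, diff(on) > 25))
  }
  truth <- vapply(seq_len(15), resolvable, numeric(1))
  found <- vapply(ev$cells, function(ce) length(ce$onsets), numeric(1))
  expect_true(all(abs(found - truth) <= 3))
  expect_lte(mean(abs(found - truth)), 1.5)
  expect_lt(abs(sum(found) - sum(truth)) / sum(truth), 0.05)
})

test_that("windowed correlations have the documented pair geometry", {
  set.seed(2)
  x <- rnorm(6000)
  traces <- rbind(x, x, matrix(rnorm(3 * 6000), nrow = 3))
  ts <- make_traceset(traces)
  ser <- windowed_correlations(ts, window_s = 420, step_s = 120)
  expect_equal(ser$n_pairs, 5 * 4 / 2)
  for (cm in ser$matrices) {
    expect_equal(cm, t(cm))
    expect_equal(diag(cm), rep(1, 5))
    expect_true(all(abs(cm[is.finite(cm)]) <= 1 + 1e-12))
    expect_equal(cm[1, 2], 1)   # identical traces
  }
  expect_error(windowed_correlations(make_traceset(matrix(rnorm(200), 2)),
                                     window_s = 400), "shorter")
})

test_that("zero-variance cells are excluded from window means with a count", {
  traces <- rbind(rnorm(6000), rnorm(6000), rep(0, 6000))
  ts <- make_traceset(traces)
  ser <- windowed_correlations(ts, window_s = 420, step_s = 300)
  expect_true(all(ser$n_zero_variance == 1L))
  expect_true(all(is.finite(ser$mean_pairwise)))
  for (cm in ser$matrices) expect_true(all(is.na(cm[3, -3])))
})

test_that("mean pairwise correlation of independent noise shrinks with window length", {
  set.seed(3)
  ts <- make_traceset(matrix(rnorm(20 * 21000), nrow = 20))
  ser_short <- windowed_correlations(ts, window_s = 120, step_s = 300)
  ser_long <- windowed_correlations(ts, window_s = 1200, step_s = 300)
  rms <- function(s) sqrt(mean(s$mean_pairwise^2))
  expect_lt(rms(ser_long), rms(ser_short))
  # at 420-s windows the pairwise SD is ~ 1/sqrt(window samples)
  ser <- windowed_correlations(ts, window_s = 420, step_s = 300)
  offdiag <- unlist(lapply(ser$matrices, function(m) m[upper.tri(m)]))
  expect_equal(sd(offdiag), 1 / sqrt(420 * 5), tolerance = 0.3)
  expect_lt(abs(mean(offdiag)), 0.005)
})

test_that("distance dependence of a subtractive shift has the expected geometry", {
  g <- generate_roi_population(roi_synth_spec(n_cells = 40,
                                              subtractive_shift = 0.1,
                                              seed = 21))
  ser <- windowed_correlations(g$traces)
  dd <- distance_dependence(ser, g$traces$positions)
  expect_equal(nrow(dd$pairs), 40 * 39 / 2)
  # delta roughly flat in distance, pct change more negative at distance
  expect_lt(abs(dd$fit_delta$slope), 5e-4)
  expect_lt(dd$fit_pct$slope, 0)
  expect_lt(dd$pearson_r_distance_vs_pct_change, 0)
})

test_that("identical epochs give zero deltas and a flagged undefined r", {
  set.seed(4)
  half <- matrix(rnorm(10 * 3000), nrow = 10)
  ts <- make_traceset(cbind(half, half))
  ser <- windowed_correlations(ts, window_s = 300, step_s = 150)
  dd <- distance_dependence(ser, ts$positions)
  # post windows replay baseline windows at matching offsets
  expect_equal(mean(abs(dd$pairs$delta_corr)), 0, tolerance = 0.02)
  ddz <- distance_dependence(ser, ts$positions, eps = 2)  # all pairs excluded
  expect_false(ddz$r_defined)
  expect_equal(ddz$pearson_r_distance_vs_pct_change, 0)
})

test_that("shuffling positions destroys the distance-percent-change relation", {
  g <- generate_roi_population(roi_synth_spec(n_cells = 40,
                                              subtractive_shift = 0.1,
                                              seed = 22))
  ser <- windowed_correlations(g$traces)
  r_true <- distance_dependence(ser,
                                g$traces$positions)$pearson_r_distance_vs_pct_change
  set.seed(99)
  r_null <- vapply(1:200, function(i) {
    distance_dependence(ser, g$traces$positions[sample(40), ],
                        )$pearson_r_distance_vs_pct_change
  }, numeric(1))
  expect_lt(quantile(abs(r_null), 0.95), abs(r_true))
  expect_lt(mean(abs(r_null)), 0.1)
})

test_that("matrix squared distance follows its conventions", {
  c1 <- diag(4)
  c1[1, 2] <- c1[2, 1] <- 0.5
  expect_equal(msd_between(c1, c1), 0)
  c2 <- c1
  c2[1, 2] <- c2[2, 1] <- 0.7
  expect_equal(msd_between(c1, c2, "all"), 2 * 0.2^2)
  expect_equal(msd_between(c1, c2, "upper"), 0.2^2)
  # monotone in perturbation size
  c3 <- c1; c3[1, 2] <- c3[2, 1] <- 0.9
  expect_gt(msd_between(c1, c3), msd_between(c1, c2))
  # invariance under simultaneous label permutation
  p <- c(3, 1, 4, 2)
  expect_equal(msd_between(c1[p, p], c2[p, p]), msd_between(c1, c2))
})

test_that("MSD of an unperturbed recording stays at baseline level", {
  g <- generate_roi_population(roi_synth_spec(n_cells = 30,
                                              subtractive_shift = 0, seed = 1))
  m <- correlation_msd(g$traces)
  expect_true(m$detrended)
  expect_true(all(is.finite(m$msd_normalized)))
  late <- m$epoch == "post" & m$times_s > 3600
  # no coupling change: no sustained elevation beyond baseline fluctuations
  expect_lt(abs(mean(m$msd_normalized[late])), 3)

  expect_warning(
    correlation_msd(make_traceset(matrix(rnorm(8 * 3500), nrow = 8), app_s = 350),
                    window_s = 300, step_s = 300, baseline_span_s = 330),
    "fewer than 3")
})

test_that("a sustained coupling change keeps normalized MSD elevated", {
  # a 15-cell subgroup changes its couplings after application while event
  # frequency is unchanged; the late normalized MSD must stay > 3 baseline
  # SDs (the sustained-structural-difference signature), with every late
  # window clearly elevated
  set.seed(6)
  n <- 30
  pos <- cbind(runif(n, 0, 300), runif(n, 0, 300))
  d <- as.matrix(dist(pos))
  c_base <- 0.25 + 0.45 * exp(-d^2 / (2 * 100^2)); diag(c_base) <- 1
  c_post <- c_base
  sub <- 1:15
  c_post[sub, sub] <- pmax(c_base[sub, sub] - 0.35, 0.05)
  diag(c_post) <- 1
  sim <- synth_correlated_event_traces(c_base, c_post, 13500, 13500,
                                       frame_rate_hz = 5, rate_hz = 0.18,
                                       q = 0.175, amplitude = 0.5,
                                       decay_s = 2, noise_sd = 0.05)
  ts <- roi_trace_set(seq_len(n), pos, sim$traces, 5, 2700)
  m <- correlation_msd(ts)
  late <- m$epoch == "post" & m$times_s > 3600
  expect_gt(mean(m$msd_normalized[late]), 3)
  expect_true(all(m$msd_normalized[late] > 2))
  expect_lt(mean(abs(m$msd_normalized[m$baseline_windows])), 2)
})

test_that("modulation classifier labels exact and noisy constructions correctly", {
  set.seed(7)
  base <- runif(100, 0.2, 0.8)
  sub <- classify_modulation(base, base - 0.1)
  expect_equal(sub$label, "subtractive")
  expect_equal(sub$shift, 0.1, tolerance = 1e-12)
  div <- classify_modulation(base, 0.5 * base)
  expect_equal(div$label, "divisive")
  expect_equal(div$scale, 0.5, tolerance = 1e-12)
  ind <- classify_modulation(rep(0.5, 20), rep(0.4, 20))
  expect_equal(ind$label, "indeterminate")
  expect_error(classify_modulation(base[1:5], base[1:5]), "at least 10")
})

test_that("both SEM conventions are available", {
  x <- c(1, 2, 3, 4)
  expect_equal(sem(x), sd(x) / 2)
  expect_equal(sem(x, "n"), sd(x) / 4)
})
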