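test_that("dF/F0 of a constant movie is zero and matches a brute-force moving average", {
  mov <- fluorescence_movie(array(1000, dim = c(30, 4, 4)))
  d <- compute_dff(mov, window = 10)
  expect_equal(max(abs(d$dff)), 0)

  # single-pixel transient: compare to a direct moving-average computation
  arr <- array(1000, dim = c(60, 3, 3))
  arr[20, 2, 2] <- 1120
  mov2 <- fluorescence_movie(arr)
  d2 <- compute_dff(mov2, window = 20)
  x <- arr[, 2, 2]
  f0 <- vapply(seq_along(x), function(t) {
    lo <- max(1, t - 9); hi <- min(length(x), t + 10)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(d2$dff[, 2, 2], x / f0 - 1, tolerance = 1e-12)
  expect_lt(abs(d2$dff[20, 2, 2] - 0.12), 0.01)
})

test_that("dF/F0 conversion rejects short movies and non-positive baselines", {
  mov <- fluorescence_movie(array(1000, dim = c(30, 2, 2)))
  expect_error(compute_dff(mov, window = 31), "shorter")
  arr <- array(1000, dim = c(30, 2, 2)); arr[, 2, 1] <- 0
  expect_error(compute_dff(fluorescence_movie(arr), window = 10), "y=2, x=1")
})

test_that("component labeling matches the exhaustive flood-fill oracle", {
  set.seed(42)
  for (k in 1:12) {
    mask <- random_stack(c(10, 9, 8), p = runif(1, 0.05, 0.35))
    for (conn in c("26", "6")) {
      dff <- as_dff(array(as.numeric(mask), dim = dim(mask)))
      cat_pkg <- detect_network_events(dff, threshold = 0.5,
                                       min_event_size = 1, connectivity = conn)
      oracle <- flood_fill_labels(mask, as.integer(conn))
      expect_true(same_voxel_sets(catalog_voxel_sets(cat_pkg),
                                  label_voxel_sets(oracle)),
                  info = paste("case", k, "conn", conn))
    }
  }
})

test_that("event count respects the minimum-size criterion", {
  arr <- array(0, dim = c(20, 20, 20))
  arr[3:6, 2:11, 2:11] <- 0.5          # 400 voxels
  dff <- as_dff(arr)
  expect_length(detect_network_events(dff, 0.12, 400)$events, 1L)
  expect_length(detect_network_events(dff, 0.12, 401)$events, 0L)

  # two blobs separated by > 1 frame and > 1 pixel in every direction
  arr[12:15, 2:11, 2:11] <- 0.5
  cat2 <- detect_network_events(as_dff(arr), 0.12, 10)
  expect_length(cat2$events, 2L)
})

test_that("detected events are monotone in threshold and size, and conserve voxels", {
  set.seed(7)
  arr <- array(pmax(0, rnorm(14 * 14 * 14, 0.05, 0.08)), dim = c(14, 14, 14))
  arr[2:5, 2:6, 2:6] <- 0.5
  dff <- as_dff(arr)
  n_ev <- function(th, ms) length(detect_network_events(dff, th, ms)$events)
  # monotone non-increasing in the minimum size for any input
  sizes <- c(1, 5, 20, 100)
  expect_true(all(diff(vapply(sizes, n_ev, numeric(1), th = 0.12)) <= 0))

  cat1 <- detect_network_events(dff, 0.12, 1)
  expect_equal(sum(vapply(cat1$events, `[[`, numeric(1), "n_voxels")),
               sum(arr >= 0.12))

  # monotone non-increasing in the threshold on unimodal (generator) events,
  # where raising the threshold cannot split a component
  g <- generate_widefield_movie(widefield_synth_spec(
    height_px = 32, width_px = 32, duration_s = 120, n_events = 3,
    noise_sd_dff = 0, seed = 13))
  dffg <- compute_dff(g$movie)
  ths <- c(0.05, 0.12, 0.2, 0.29, 0.5)
  expect_true(all(diff(vapply(ths, function(th) {
    length(detect_network_events(dffg, th, 5)$events)
  }, numeric(1))) <= 0))
})

test_that("area restriction keeps the pixels reaching 67% of the event peak", {
  # uniform event: all pixels pass, printed per-pixel area applies
  arr <- array(0, dim = c(10, 12, 12))
  arr[4:5, 2:11, 2:11] <- 0.3
  dff <- as_dff(arr)
  ev <- detect_network_events(dff, 0.12, 10)$events[[1]]
  r <- restrict_event_area(ev, dff)
  expect_equal(r$restricted_area_um2, 100 * 59)
  expect_equal(restrict_event_area(ev, dff, area_mode = "exact")$restricted_area_um2,
               100 * 7.68^2)

  # one peak pixel, rest at half peak: only the peak survives
  arr2 <- array(0, dim = c(10, 8, 8))
  arr2[5, 2:6, 2:6] <- 0.2
  arr2[5, 4, 4] <- 0.4
  dff2 <- as_dff(arr2)
  ev2 <- detect_network_events(dff2, 0.12, 5)$events[[1]]
  expect_equal(restrict_event_area(ev2, dff2)$n_restricted_px, 1L)
  expect_error(restrict_event_area(ev2, dff2, fraction = 1.5), "fraction")

  # radial Gaussian blob: restricted count equals the analytic-radius count
  h <- 31; sig_px <- 6
  g <- outer(exp(-((1:h) - 16)^2 / (2 * sig_px^2)),
             exp(-((1:h) - 16)^2 / (2 * sig_px^2)))
  arr3 <- array(0, dim = c(3, h, h))
  arr3[2, , ] <- 0.4 * g
  dff3 <- as_dff(arr3)
  ev3 <- detect_network_events(dff3, 0.12, 5)$events[[1]]
  r3 <- restrict_event_area(ev3, dff3)
  r67 <- sig_px * sqrt(-2 * log(0.67))
  analytic <- sum(outer(((1:h) - 16)^2, ((1:h) - 16)^2, "+") <= r67^2)
  expect_equal(r3$n_restricted_px, analytic)
})

test_that("restricted footprint is a subset of the full footprint", {
  set.seed(11)
  spec <- widefield_synth_spec(height_px = 32, width_px = 32, duration_s = 60,
                               n_events = 2, noise_sd_dff = 0, seed = 11)
  g <- generate_widefield_movie(spec)
  dff <- compute_dff(g$movie)
  catal <- annotate_catalog(detect_network_events(dff), dff)
  for (ev in catal$events) {
    full <- paste(ev$footprint_px[, 1], ev$footprint_px[, 2])
    res <- paste(ev$restricted_footprint_px[, 1], ev$restricted_footprint_px[, 2])
    expect_true(all(res %in% full))
    expect_lte(ev$restricted_area_um2, ev$n_voxels * 59)
  }
})

test_that("event frequency timecourse bins counts correctly", {
  # 12 events uniform over 600 s -> two 300-s bins of 0.02 Hz
  events <- lapply(seq(1, 600, length.out = 12), function(t0) {
    structure(list(onset_frame = round(t0 * 20), offset_frame = round(t0 * 20),
                   duration_s = 0.05, n_voxels = 1,
                   voxels = cbind(t = 1L, y = 1L, x = 1L),
                   peak_dff = 0.2, region = NA_character_),
              class = "network_event")
  })
  catal <- structure(list(events = events,
                          detection_params = list(), dims = c(12000L, 4L, 4L),
                          frame_rate_hz = 20, pixel_size_um = 7.68),
                     class = "event_catalog")
  tc <- event_frequency_timecourse(catal, bin_s = 300)
  expect_equal(tc$frequency_hz, c(0.02, 0.02))
  expect_error(event_frequency_timecourse(catal, bin_s = 700), "longer")

  catal$events <- list()
  expect_equal(event_frequency_timecourse(catal, bin_s = 300)$frequency_hz,
               c(0, 0))
})

test_that("percent change follows its definition and rejects zero baselines", {
  expect_equal(percent_change(0.042, 0.042), 0)
  expect_equal(percent_change(0.040, 0.020), -50)
  expect_error(percent_change(0, 0.01), "zero baseline")
})

test_that("trace peak detection survives high-frequency artifacts", {
  fs <- 20
  t <- seq(0, 60, by = 1 / fs)
  trace <- numeric(length(t))
  onsets <- c(5, 15, 25, 35, 45)
  for (o in onsets) {
    idx <- t >= o
    trace[idx] <- trace[idx] + 0.5 * exp(-(t[idx] - o) / 1.5)
  }
  params <- trace_peak_params(lowpass_cutoff_hz = 2, prominence = 0.2,
                              min_peak_height = 0.2)
  pk <- detect_trace_peaks(trace, fs, params)
  expect_equal(nrow(pk), 5L)
  expect_equal(pk$time_s, onsets, tolerance = 0.5)

  # additive 8 Hz artifact above the cutoff: same five peaks. A 4th-order
  # Butterworth at 2 Hz attenuates 8 Hz by (8/2)^-8 ~ 1.5e-5 in power, so the
  # filtered artifact amplitude is far below the prominence criterion.
  noisy <- trace + 0.15 * sin(2 * pi * 8 * t)
  pk2 <- detect_trace_peaks(noisy, fs, params)
  expect_equal(nrow(pk2), 5L)

  expect_equal(nrow(detect_trace_peaks(rep(0, 1000), fs, params)), 0L)
  expect_error(detect_trace_peaks(trace, fs,
                                  trace_peak_params(11, 0.1, 0.1)), "Nyquist")
})
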