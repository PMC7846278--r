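#' ROI trace set container
#'
#' Per-cell dF/F0 traces with positions, aligned by cell id, plus the epoch
#' geometry of the experiment (application time separating baseline from
#' post, and the span used for the full-baseline correlation matrix).
#'
#' @param cell_ids integer or character ids, one per cell.
#' @param positions `N x 2` matrix of (x, y) positions in micrometers.
#' @param traces `N x T` matrix of dF/F0 fractions.
#' @param frame_rate_hz imaging rate in Hz (typically 4-7).
#' @param application_time_s epoch boundary in seconds.
#' @param baseline_span_s span of the full-baseline correlation matrix
#'   (default 2700 s = 45 min).
#' @return a `roi_trace_set`.
#' @export
roi_trace_set <- function(cell_ids, positions, traces, frame_rate_hz,
                          application_time_s, baseline_span_s = 2700) {
  positions <- as.matrix(positions)
  traces <- as.matrix(traces)
  n <- length(cell_ids)
  if (n < 2L) stop("roi_trace_set: need at least 2 cells")
  stopifnot(nrow(positions) == n, ncol(positions) == 2L, nrow(traces) == n,
            all(is.finite(traces)))
  assert_positive(frame_rate_hz, "frame_rate_hz")
  duration_s <- ncol(traces) / frame_rate_hz
  if (application_time_s <= 0 || application_time_s >= duration_s) {
    stop("roi_trace_set: application_time_s must fall inside the recording")
  }
  structure(
    list(cell_ids = cell_ids, positions = positions, traces = traces,
         frame_rate_hz = frame_rate_hz,
         application_time_s = application_time_s,
         baseline_span_s = min(baseline_span_s, application_time_s)),
    class = "roi_trace_set"
  )
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d cells x %d frames @ %.3g Hz (application at %.0f s)\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate_hz,
              x$application_time_s))
  invisible(x)
}

#' Robust noise SD of a dF/F0 trace
#'
#' Estimates the SD of the signal in the absence of events as
#' `1.4826 * MAD(diff(x)) / sqrt(2)`: the first difference suppresses the
#' slow calcium transients and the median absolute deviation is insensitive
#' to the sparse large excursions the transients leave behind.
#'
#' @param x numeric trace.
#' @return scalar noise SD estimate.
#' @export
trace_noise_sd <- function(x) {
  dx <- diff(x)
  stats::mad(dx, center = 0, constant = 1.4826) / sqrt(2)
}

#' Detect calcium events per ROI by threshold crossing
#'
#' The per-cell threshold is `k_sd` times the robust noise SD
#' ([trace_noise_sd()]); defaults to 2x, held fixed across the epochs of one
#' experiment. Onsets are upward crossings that stay suprathreshold for at
#' least `min_above_frames` consecutive frames (a 2-sigma threshold alone
#' would fire constantly on Gaussian noise; calcium transients decay over
#' seconds, so requiring a brief sustained crossing costs no sensitivity).
#' Hysteresis is applied: after an onset the trace must fall back below half
#' the threshold before a new onset can be registered, preventing double
#' counts while a transient decays through the threshold.
#'
#' Crossings are evaluated on a lightly smoothed copy of the trace (boxcar of
#' `smooth_frames`); the threshold itself is estimated from the raw trace.
#'
#' @param traces a [roi_trace_set()].
#' @param k_sd threshold multiplier (default 2).
#' @param min_above_frames consecutive suprathreshold frames required
#'   (default 3).
#' @param smooth_frames boxcar width for the detection copy (default 3).
#' @return an `event_raster`: list with per-cell `onsets` (frame indices),
#'   `amplitudes` (trace value at the following local maximum), `threshold`
#'   per cell and `detection_threshold_sd = k_sd`.
#' @export
detect_roi_events <- function(traces, k_sd = 2, min_above_frames = 3L,
                              smooth_frames = 3L) {
  stopifnot(inherits(traces, "roi_trace_set"))
  m <- traces$traces
  nt <- ncol(m)
  out <- lapply(seq_len(nrow(m)), function(i) {
    raw <- m[i, ]
    sdn <- trace_noise_sd(raw)
    if (sdn == 0) stop("detect_roi_events: cell ", traces$cell_ids[i],
                       " has zero noise SD (constant trace)")
    thr <- k_sd * sdn
    x <- raw
    if (smooth_frames > 1L) {
      x <- as.numeric(stats::filter(raw, rep(1 / smooth_frames, smooth_frames),
                                    sides = 2))
      x[is.na(x)] <- raw[is.na(x)]
    }
    onsets <- integer(0)
    armed <- TRUE
    for (t in seq_along(x)) {
      if (armed && x[t] >= thr && (t == 1L || x[t - 1L] < thr)) {
        run_end <- min(nt, t + min_above_frames - 1L)
        if (all(x[t:run_end] >= thr)) {
          onsets <- c(onsets, t)
          armed <- FALSE
        }
      } else if (!armed && x[t] < thr / 2) {
        armed <- TRUE
      }
    }
    amp <- vapply(onsets, function(o) {
      seg <- x[o:min(length(x), o + 50L)]
      max(seg)
    }, numeric(1))
    list(onsets = onsets, amplitudes = amp, threshold = thr)
  })
  structure(
    list(cells = out, cell_ids = traces$cell_ids,
         frame_rate_hz = traces$frame_rate_hz,
         detection_threshold_sd = k_sd),
    class = "event_raster"
  )
}

#' Sliding-window pairwise Pearson correlations
#'
#' Pearson correlations of the raw dF/F0 traces between all unordered pairs
#' (`N(N-1)/2` of them), in a window of `window_s` seconds slid in steps of
#' `step_s`. Cells with zero variance inside a window have their pairs set to
#' `NA` and excluded from the window mean; the number of such exclusions is
#' recorded.
#'
#' @param traces a [roi_trace_set()].
#' @param window_s window length in seconds (default 420 = 7 min).
#' @param step_s step between window starts (default 60).
#' @return a `correlation_window_series`: list with `window_centers_s`,
#'   `window_length_s`, `matrices` (list of N x N matrices), `mean_pairwise`,
#'   `n_pairs`, `n_zero_variance`, `epoch` per window (`"baseline"`, `"post"`
#'   or `"boundary"` for windows straddling the application time).
#' @export
windowed_correlations <- function(traces, window_s = 420, step_s = 60) {
  stopifnot(inherits(traces, "roi_trace_set"))
  fs <- traces$frame_rate_hz
  nt <- ncol(traces$traces)
  wf <- round(window_s * fs)
  if (wf > nt) stop("windowed_correlations: recording shorter than the window")
  sf <- max(1L, round(step_s * fs))
  starts <- seq(1L, nt - wf + 1L, by = sf)
  n <- nrow(traces$traces)
  ut <- upper.tri(matrix(0, n, n))
  app_f <- traces$application_time_s * fs

  mats <- vector("list", length(starts))
  meanpw <- numeric(length(starts))
  nzv <- integer(length(starts))
  epoch <- character(length(starts))
  for (k in seq_along(starts)) {
    sl <- starts[k]:(starts[k] + wf - 1L)
    x <- t(traces$traces[, sl, drop = FALSE])
    sds <- apply(x, 2, sd)
    bad <- sds == 0
    cm <- suppressWarnings(cor(x))
    dimnames(cm) <- NULL
    cm[bad, ] <- NA_real_; cm[, bad] <- NA_real_
    diag(cm) <- 1
    mats[[k]] <- cm
    meanpw[k] <- mean(cm[ut], na.rm = TRUE)
    nzv[k] <- sum(bad)
    epoch[k] <- if (sl[length(sl)] <= app_f) "baseline"
                else if (sl[1L] > app_f) "post" else "boundary"
  }
  structure(
    list(window_centers_s = (starts - 1 + wf / 2) / fs,
         window_starts_s = (starts - 1) / fs,
         window_length_s = window_s,
         matrices = mats, mean_pairwise = meanpw,
         n_pairs = n * (n - 1) / 2,
         n_zero_variance = nzv, epoch = epoch,
         frame_rate_hz = fs, application_time_s = traces$application_time_s),
    class = "correlation_window_series"
  )
}

#' Distance dependence of the correlation change
#'
#' Per-pair epoch-average correlations before and after application, their
#' difference, the percent change for pairs whose baseline magnitude exceeds
#' `eps`, ordinary least-squares lines of delta and percent change against
#' interneuronal distance, and the per-dataset Pearson correlation between
#' distance and percent change.
#'
#' @param series a `correlation_window_series`.
#' @param positions `N x 2` matrix of cell positions in micrometers.
#' @param eps minimum `|baseline|` for a defined percent change (default 0.01).
#' @return a `distance_correlation_result`: list with the per-pair table
#'   (`pairs`), `fit_delta`, `fit_pct` (slope, intercept, p), scalar
#'   `pearson_r_distance_vs_pct_change` (+ `r_defined` flag),
#'   `n_pairs_excluded`.
#' @export
distance_dependence <- function(series, positions, eps = 0.01) {
  stopifnot(inherits(series, "correlation_window_series"))
  bl <- which(series$epoch == "baseline")
  po <- which(series$epoch == "post")
  if (!length(bl)) stop("distance_dependence: baseline epoch has no windows")
  if (!length(po)) stop("distance_dependence: post epoch has no windows")
  epoch_mean <- function(idx) {
    arr <- simplify2array(series$matrices[idx])
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  }
  cb <- epoch_mean(bl)
  cp <- epoch_mean(po)
  n <- nrow(cb)
  ut <- which(upper.tri(cb), arr.ind = TRUE)
  d <- as.matrix(dist(positions))[ut]
  base <- cb[ut]; post <- cp[ut]
  delta <- post - base
  defined <- abs(base) >= eps
  pct <- ifelse(defined, 100 * delta / base, NA_real_)
  pairs <- data.frame(i = ut[, 1], j = ut[, 2], distance_um = d,
                      baseline_corr = base, post_corr = post,
                      delta_corr = delta, pct_change = pct)
  ols <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(list(slope = 0, intercept = mean(y[ok]), p_value = NA_real_))
    }
    f <- lm(y ~ x, data = data.frame(y = y[ok], x = x[ok]))
    s <- summary(f)$coefficients
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         p_value = unname(s[2, 4]))
  }
  r_defined <- sum(defined, na.rm = TRUE) >= 3 &&
    sd(pct[defined]) > 0 && sd(d[defined]) > 0
  r <- if (r_defined) cor(d[defined], pct[defined]) else 0
  structure(
    list(pairs = pairs,
         fit_delta = ols(delta, d),
         fit_pct = ols(pct, d),
         pearson_r_distance_vs_pct_change = r,
         r_defined = r_defined,
         n_pairs_excluded = sum(!defined),
         eps = eps),
    class = "distance_correlation_result"
  )
}

#' Squared distance between two correlation matrices
#'
#' Sum of squared element-wise differences. The default convention sums over
#' all `N^2` entries (the diagonal contributes zero for correlation
#' matrices), so a perturbation of one unordered pair is counted twice;
#' `mode = "upper"` sums unordered pairs once. The two differ by an exact
#' factor of 2, which is immaterial after baseline z-scoring.
#'
#' @param c1,c2 square matrices of equal size.
#' @param mode `"all"` (default) or `"upper"`.
#' @return scalar squared distance.
#' @export
msd_between <- function(c1, c2, mode = c("all", "upper")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(c1), dim(c2)))
  d2 <- (c1 - c2)^2
  if (mode == "all") sum(d2, na.rm = TRUE)
  else sum(d2[upper.tri(d2)], na.rm = TRUE)
}

#' Correlation-matrix distance (MSD) time series
#'
#' For each sliding window, the squared distance between its correlation
#' matrix and the matrix computed over the entire baseline span. The raw
#' series is detrended by an OLS line fitted on the baseline windows
#' (extrapolated to all time points, removing slow drift present before
#' application), then z-scored by the mean and SD of the detrended baseline
#' values.
#'
#' @param traces a [roi_trace_set()].
#' @param series optional precomputed [windowed_correlations()] result; when
#'   `NULL` it is computed with `window_s`/`step_s`.
#' @param window_s,step_s window geometry when `series` is `NULL`.
#' @param baseline_span_s span of the full-baseline matrix (default
#'   `traces$baseline_span_s`).
#' @param mode summation convention, see [msd_between()].
#' @return an `msd_series`: list with `times_s`, `msd_raw`, `msd_detrended`,
#'   `msd_normalized`, `baseline_matrix`, flags `detrended` and `normalized`.
#' @export
correlation_msd <- function(traces, series = NULL, window_s = 420, step_s = 60,
                            baseline_span_s = NULL, mode = c("all", "upper")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traces, "roi_trace_set"))
  if (is.null(series)) series <- windowed_correlations(traces, window_s, step_s)
  if (is.null(baseline_span_s)) baseline_span_s <- traces$baseline_span_s
  fs <- traces$frame_rate_hz
  span_f <- round(baseline_span_s * fs)
  if (span_f < round(series$window_length_s * fs)) {
    stop("correlation_msd: baseline span shorter than the window length")
  }
  c_bl <- suppressWarnings(cor(t(traces$traces[, seq_len(span_f), drop = FALSE])))
  diag(c_bl) <- 1

  msd_raw <- vapply(series$matrices, msd_between, numeric(1), c2 = c_bl,
                    mode = mode)
  t_s <- series$window_centers_s
  bl <- which(series$epoch == "baseline")

  detrended_flag <- length(bl) >= 3
  if (detrended_flag) {
    fit <- lm(y ~ x, data = data.frame(y = msd_raw[bl], x = t_s[bl]))
    trend <- coef(fit)[1] + coef(fit)[2] * t_s
    msd_det <- msd_raw - trend
  } else {
    warning("correlation_msd: fewer than 3 baseline windows; detrending skipped")
    msd_det <- msd_raw
  }
  mu <- mean(msd_det[bl])
  sg <- sd(msd_det[bl])
  normalized_flag <- is.finite(sg) && sg > 0
  msd_norm <- if (normalized_flag) (msd_det - mu) / sg else rep(0, length(msd_det))

  structure(
    list(times_s = t_s, msd_raw = msd_raw, msd_detrended = msd_det,
         msd_normalized = msd_norm, baseline_matrix = c_bl,
         baseline_windows = bl, epoch = series$epoch, mode = mode,
         detrended = detrended_flag, normalized = normalized_flag),
    class = "msd_series"
  )
}

#' Classify a correlation change as subtractive or divisive
#'
#' Fits the one-parameter shift model `post = base - c` and the one-parameter
#' scaling model `post = a * base` by least squares and labels the pairing by
#' the better model under AIC. Equal-variance Gaussian AIC with one parameter
#' each, so this reduces to comparing residual sums of squares; `"mixed"` is
#' returned when they are indistinguishable (|dAIC| < 2).
#'
#' @param baseline_corr,post_corr numeric vectors of per-pair correlations
#'   (>= 10 pairs).
#' @return list with `label` (`"subtractive"`, `"divisive"`, `"mixed"` or
#'   `"indeterminate"`), `shift` (c), `scale` (a), `rss_subtractive`,
#'   `rss_divisive`, `aic_subtractive`, `aic_divisive`.
#' @export
classify_modulation <- function(baseline_corr, post_corr) {
  ok <- is.finite(baseline_corr) & is.finite(post_corr)
  base <- baseline_corr[ok]; post <- post_corr[ok]
  n <- length(base)
  if (n < 10) stop("classify_modulation: need at least 10 pairs")
  if (sd(base) == 0) {
    return(list(label = "indeterminate", shift = mean(base - post),
                scale = NA_real_, rss_subtractive = NA_real_,
                rss_divisive = NA_real_, aic_subtractive = NA_real_,
                aic_divisive = NA_real_))
  }
  c_hat <- mean(base - post)
  rss_sub <- sum((post - (base - c_hat))^2)
  a_hat <- sum(base * post) / sum(base^2)
  rss_div <- sum((post - a_hat * base)^2)
  aic <- function(rss) n * log(rss / n + 1e-300) + 2
  aic_sub <- aic(rss_sub); aic_div <- aic(rss_div)
  label <- if (abs(aic_sub - aic_div) < 2) "mixed"
           else if (aic_sub < aic_div) "subtractive" else "divisive"
  list(label = label, shift = c_hat, scale = a_hat,
       rss_subtractive = rss_sub, rss_divisive = rss_div,
       aic_subtractive = aic_sub, aic_divisive = aic_div)
}
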