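#' Standard error of the mean
#'
#' Across-animal dispersion of a summary statistic. The default is the
#' standard convention \eqn{\hat\sigma/\sqrt{N}}; `convention = "n"`
#' (\eqn{\hat\sigma/N}) is selectable for comparison with reports that use
#' the sample size itself as the divisor.
#'
#' @param x numeric vector (one value per animal/experiment).
#' @param convention `"sqrt-n"` (default) or `"n"`.
#' @return scalar standard error.
#' @export
sem <- function(x, convention = c("sqrt-n", "n")) {
  convention <- match.arg(convention)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- stats::sd(x)
  if (convention == "sqrt-n") s / sqrt(n) else s / n
}

#' Percent change relative to baseline
#'
#' @param baseline_mean,post_mean scalar summaries (e.g. event frequency in
#'   Hz) for the baseline and post-application epochs.
#' @return `100 * (post - baseline) / baseline`.
#' @export
percent_change <- function(baseline_mean, post_mean) {
  stopifnot(is.numeric(baseline_mean), is.numeric(post_mean))
  if (any(baseline_mean == 0)) stop("percent_change: zero baseline mean")
  100 * (post_mean - baseline_mean) / baseline_mean
}

#' Provenance record for an analysis output
#'
#' Every driver script serializes one of these next to its outputs so a run
#' can be reproduced from parameters + seed alone.
#'
#' @param params named list of parameters that determined the run.
#' @param seed integer seed used for the run (or `NA`).
#' @return a list with timestamp, package version, seed and parameters.
#' @export
provenance_record <- function(params = list(), seed = NA_integer_) {
  list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "spontnet",
    version = as.character(utils::packageVersion("spontnet")),
    seed = seed,
    params = params
  )
}

#' Write a provenance record as JSON
#'
#' @param record list from [provenance_record()].
#' @param path output path (`.json`).
#' @param force overwrite an existing file. Defaults to `FALSE`: no output is
#'   silently clobbered.
#' @export
write_provenance <- function(record, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("write_provenance: ", path, " exists (use force = TRUE)")
  }
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# internal: check a scalar is a positive finite number
assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite scalar")
  }
  invisible(TRUE)
}
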