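#' Analysis configuration
#'
#' Bundles the tunable parameters of the sliding-window classification and
#' permutation analyses. Times are milliseconds relative to first-object
#' onset; windows are half-open \code{[t, t + window_len_ms)} labeled by
#' their start time \code{t}.
#'
#' @param window_len_ms Sliding-window length in ms (default 150).
#' @param step_ms Step between consecutive window starts in ms (default 1).
#' @param run_len Number of consecutive same-label windows required for a
#'   signal segment. Defaults to \code{max(1, round(40 / step_ms))} so that
#'   the run *duration* (about 40 ms at the reference 1-ms step) is preserved
#'   when the step is coarsened; pass it explicitly to override.
#' @param n_shuffle Monte Carlo shuffles for the model comparison (default
#'   1000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param baseline_window_ms Half-open baseline interval in ms, default
#'   \code{c(-200, 0)} (the 200 ms before object onset).
#' @param sigma_ms Gaussian kernel SD for spike density functions (default 30).
#' @param ridge_lambda Ridge penalty on standardized predictors (default 1).
#' @param analysis_window_ms Half-open interval over which sliding windows are
#'   placed; window starts run from \code{analysis_window_ms[1]} to
#'   \code{analysis_window_ms[2] - window_len_ms}. Default \code{c(0, 1000)},
#'   the object-presentation period.
#' @param min_trials Minimum trials required for a window fit (default 10).
#' @param seed Integer master seed governing all stochastic stages; each stage
#'   derives an independent substream keyed by (stage name, unit id).
#' @return A list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(window_len_ms = 150L, step_ms = 1L,
                            run_len = NULL, n_shuffle = 1000L, alpha = 0.05,
                            baseline_window_ms = c(-200, 0), sigma_ms = 30,
                            ridge_lambda = 1, analysis_window_ms = c(0, 1000),
                            min_trials = 10L, seed = 1L) {
  if (window_len_ms <= 0) stop("window_len_ms must be > 0")
  if (step_ms <= 0) stop("step_ms must be > 0")
  if (is.null(run_len)) run_len <- max(1L, as.integer(round(40 / step_ms)))
  if (run_len < 1) stop("run_len must be >= 1")
  if (n_shuffle < 100) stop("n_shuffle must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (sigma_ms <= 0) stop("sigma_ms must be > 0")
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0")
  if (length(baseline_window_ms) != 2 ||
      baseline_window_ms[1] >= baseline_window_ms[2])
    stop("baseline_window_ms must be an increasing interval")
  if (length(analysis_window_ms) != 2 ||
      analysis_window_ms[1] >= analysis_window_ms[2])
    stop("analysis_window_ms must be an increasing interval")
  structure(list(
    window_len_ms = as.integer(window_len_ms),
    step_ms = as.integer(step_ms),
    run_len = as.integer(run_len),
    n_shuffle = as.integer(n_shuffle),
    alpha = alpha,
    baseline_window_ms = as.numeric(baseline_window_ms),
    sigma_ms = sigma_ms,
    ridge_lambda = ridge_lambda,
    analysis_window_ms = as.numeric(analysis_window_ms),
    min_trials = as.integer(min_trials),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  window %d ms, step %d ms, run_len %d windows\n",
              x$window_len_ms, x$step_ms, x$run_len))
  cat(sprintf("  n_shuffle %d, alpha %g, ridge lambda %g\n",
              x$n_shuffle, x$alpha, x$ridge_lambda))
  cat(sprintf("  baseline [%g, %g) ms, analysis [%g, %g) ms, sigma %g ms\n",
              x$baseline_window_ms[1], x$baseline_window_ms[2],
              x$analysis_window_ms[1], x$analysis_window_ms[2], x$sigma_ms))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Deterministic substream seed from (master seed, stage name, unit id).
# Polynomial string hash folded with the master seed, modulo 2^31 - 1,
# so every stochastic stage gets an independent reproducible stream.
substream_seed <- function(seed, stage, unit = 0L) {
  key <- paste(stage, unit, sep = ":")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded by a substream.
with_substream <- function(seed, stage, unit, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stage, unit))
  expr
}
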