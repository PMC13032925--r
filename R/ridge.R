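#' Ridge regression with unpenalized intercept
#'
#' Closed-form ridge fit of per-trial firing rate on a small set of
#' trial predictors. Predictors are standardized (zero mean, unit variance)
#' before penalization so the penalty \code{lambda * sum(beta^2)} treats
#' value-like and binary predictors on a common scale; the intercept is not
#' penalized. Ridge is used where the predictors are correlated by task
#' design (value and choice, value and reaction time): the penalty trades a
#' little bias for the variance explosion OLS suffers under collinearity.
#'
#' @param F_rate Response vector (per-trial rate, Hz).
#' @param X Predictor matrix (n x p), raw scale.
#' @param lambda Penalty weight on the standardized scale, >= 0.
#' @return List of class \code{"ridge_fit"}: \code{beta} (intercept followed
#'   by standardized-scale coefficients), \code{beta_raw} (original predictor
#'   scale), \code{lambda}, \code{x_center}, \code{x_scale}.
#' @export
fit_ridge <- function(F_rate, X, lambda = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(F_rate) != n) stop("F_rate and X dimensions differ")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- scl == 0
  if (any(const)) {
    warning("constant predictor(s) get coefficient 0: ",
            paste(colnames(X)[const], collapse = ", "))
    scl[const] <- 1
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[, const] <- 0
  Fc <- F_rate - mean(F_rate)
  A <- crossprod(Z) + diag(lambda, p)
  beta <- as.numeric(solve(A, crossprod(Z, Fc)))
  beta[const] <- 0
  beta_raw <- beta / scl
  b0 <- mean(F_rate)
  structure(list(
    beta = stats::setNames(c(b0, beta), c("(Intercept)", colnames(X))),
    beta_raw = stats::setNames(beta_raw, colnames(X)),
    lambda = lambda, x_center = ctr, x_scale = scl),
    class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("Ridge fit (lambda =", x$lambda, ", standardized predictors)\n")
  print(round(x$beta, 5))
  invisible(x)
}

# Precompute the linear map from centered response to penalized coefficients:
# beta = M %*% Fc, with M = (Z'Z + lambda I)^-1 Z'. Enables one matrix
# multiply for thousands of response permutations.
ridge_projector <- function(X, lambda) {
  X <- as.matrix(X)
  p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- scl == 0
  scl[const] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[, const] <- 0
  M <- solve(crossprod(Z) + diag(lambda, p), t(Z))
  list(M = M, const = const)
}

#' Permutation significance of ridge coefficients
#'
#' For each penalized coefficient, the two-sided permutation p value
#' \code{p = (1 + #\{|beta_perm| >= |beta_obs|\}) / (1 + n_perm)}, where each
#' permutation refits the ridge model after shuffling the response across
#' trials (the design is fixed, so the null preserves the predictor
#' correlation structure).
#'
#' @param F_rate Response vector.
#' @param X Predictor matrix.
#' @param lambda Ridge penalty.
#' @param n_perm Number of response permutations (>= 100).
#' @param seed Master seed; \code{unit} keys the substream.
#' @param unit Substream identifier.
#' @return Named numeric vector of p values (one per predictor).
#' @export
ridge_coef_significance <- function(F_rate, X, lambda = 1, n_perm = 1000L,
                                    seed = 1L, unit = "r") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  X <- as.matrix(X)
  n <- nrow(X)
  fit <- fit_ridge(F_rate, X, lambda)
  obs <- abs(fit$beta[-1])
  pr <- ridge_projector(X, lambda)
  Fc <- F_rate - mean(F_rate)
  perm_abs <- with_substream(seed, "ridge_perm", unit, {
    P <- vapply(seq_len(n_perm), function(j) Fc[sample.int(n)], numeric(n))
    abs(pr$M %*% P)            # p x n_perm coefficient magnitudes
  })
  p <- (1 + rowSums(perm_abs >= obs)) / (1 + n_perm)
  stats::setNames(pmin(p, 1), names(obs))
}

#' Max-statistic FWER control for population proportions
#'
#' Across time windows, the observed statistic is the proportion of neurons
#' whose coefficient p value is below \code{alpha}. The family-wise null is
#' built from exchangeable per-permutation replicates: for each permutation,
#' the proportion is computed on the shuffled-data p values in every window
#' and the *maximum* across windows is recorded. A window's observed
#' proportion is significant iff it strictly exceeds the \code{1 - alpha}
#' quantile of this null max distribution, which controls the family-wise
#' error rate over all windows.
#'
#' @param p_obs Matrix (neurons x windows) of observed per-neuron p values.
#' @param p_null Array (neurons x windows x n_perm) of exchangeable null p
#'   values (one replicate per permutation).
#' @param alpha Level used both for per-neuron significance and the max
#'   quantile (default 0.05).
#' @param window_start_ms Optional window-start grid for labeling.
#' @return List of class \code{"proportion_series"}: \code{window_start_ms},
#'   \code{prop_significant}, \code{null_max_quantile}, \code{significant},
#'   \code{null_max} (the permutation max distribution).
#' @export
population_proportion_fwer <- function(p_obs, p_null, alpha = 0.05,
                                       window_start_ms = NULL) {
  p_obs <- as.matrix(p_obs)
  n_win <- ncol(p_obs)
  if (n_win < 2)
    warning("fewer than 2 windows: degenerates to a single-window permutation test")
  stopifnot(length(dim(p_null)) == 3, dim(p_null)[1] == nrow(p_obs),
            dim(p_null)[2] == n_win)
  n_perm <- dim(p_null)[3]
  prop_obs <- colMeans(p_obs < alpha)
  null_max <- vapply(seq_len(n_perm), function(k)
    max(colMeans(p_null[, , k, drop = FALSE] < alpha)), 0)
  srt <- sort(null_max)
  thr <- srt[min(n_perm, ceiling((1 - alpha) * n_perm))]
  if (is.null(window_start_ms)) window_start_ms <- seq_len(n_win)
  structure(list(window_start_ms = window_start_ms,
                 prop_significant = prop_obs,
                 null_max_quantile = thr,
                 significant = prop_obs > thr,
                 null_max = null_max),
            class = "proportion_series")
}

#' @export
print.proportion_series <- function(x, ...) {
  cat(sprintf("Proportion series over %d windows; FWER threshold %.3f; %d significant\n",
              length(x$prop_significant), x$null_max_quantile,
              sum(x$significant)))
  invisible(x)
}

#' Windowed ridge analysis of a population
#'
#' Fits a ridge model to each neuron's rate in each analysis window and
#' applies [population_proportion_fwer()] per predictor. Models:
#' \describe{
#'   \item{value_choice}{rate ~ value1 + chosen, all decision trials.}
#'   \item{value_rt}{rate ~ value1 + latency_ms, chosen trials only (the
#'     release latency exists only when the button was released).}
#'   \item{prev_value}{rate ~ value2_{t-1} + value1_t + chosen_t; each
#'     session's first trial is dropped (no predecessor).}
#' }
#' Per-neuron coefficient significance uses one set of \code{n_perm} shared
#' response permutations per neuron/window: the observed p is the rank of
#' \code{|beta_obs|} among the permuted magnitudes, and the same permutation
#' set supplies the exchangeable null p replicates that feed the max-statistic
#' procedure.
#'
#' @param trains_by_neuron Named list (per neuron) of per-trial spike-train
#'   lists aligned with \code{trials} rows.
#' @param trials Decision-task trial data.frame.
#' @param model One of \code{"value_choice"}, \code{"value_rt"},
#'   \code{"prev_value"}.
#' @param cfg [analysis_config()]; \code{ridge_lambda}, \code{alpha},
#'   \code{window_len_ms} and \code{seed} are used.
#' @param n_perm Permutations per neuron/window (default 200).
#' @param stride_ms Spacing of window starts; defaults to the window length
#'   (non-overlapping windows tiling the object-presentation period).
#' @return List: \code{model}, \code{window_start_ms}, \code{coef_names},
#'   \code{beta_obs} (neurons x windows x coefs), \code{p_obs} (same shape),
#'   \code{fwer} (named list of [population_proportion_fwer()] results per
#'   predictor).
#' @export
run_ridge_analysis <- function(trains_by_neuron, trials,
                               model = c("value_choice", "value_rt",
                                         "prev_value"),
                               cfg = analysis_config(), n_perm = 200L,
                               stride_ms = NULL) {
  model <- match.arg(model)
  trials <- trials[trials$task == "decision", , drop = FALSE]
  if (is.null(stride_ms)) stride_ms <- cfg$window_len_ms
  len <- cfg$window_len_ms
  ws <- seq(cfg$analysis_window_ms[1], cfg$analysis_window_ms[2] - len,
            by = stride_ms)

  keep <- switch(model,
    value_choice = rep(TRUE, nrow(trials)),
    value_rt = trials$chosen == 1 & !is.na(trials$latency_ms),
    prev_value = {
      ord <- order(trials$session_id, trials$trial_index)
      stopifnot(identical(ord, seq_len(nrow(trials))))
      !duplicated(trials$session_id)  # first trial per session flagged ...
    })
  if (model == "prev_value") keep <- !keep
  if (model == "value_rt" && !any(keep))
    stop("insufficient data: no chosen trials with a release latency")

  X <- switch(model,
    value_choice = cbind(value = trials$value1, choice = trials$chosen),
    value_rt = cbind(value = trials$value1, rt = trials$latency_ms),
    prev_value = {
      prev <- c(NA_integer_, trials$value2[-nrow(trials)])
      prev[!keep] <- NA
      cbind(prev_value = prev, value = trials$value1,
            choice = trials$chosen)
    })
  X <- X[keep, , drop = FALSE]
  cf <- colnames(X)
  n <- sum(keep)
  neurons <- names(trains_by_neuron)
  pr <- ridge_projector(X, cfg$ridge_lambda)

  beta_obs <- array(NA_real_, c(length(neurons), length(ws), length(cf)),
                    dimnames = list(neurons, NULL, cf))
  p_obs <- beta_obs
  p_null <- array(NA_real_,
                  c(length(neurons), length(ws), length(cf), n_perm))

  for (i in seq_along(neurons)) {
    trains <- trains_by_neuron[[i]][keep]
    counts <- vapply(trains, function(sp) {
      findInterval(ws + len, sp, left.open = TRUE) -
        findInterval(ws, sp, left.open = TRUE)
    }, numeric(length(ws)))
    counts <- matrix(counts, nrow = length(ws))
    for (w in seq_along(ws)) {
      F_rate <- counts[w, ] / (len / 1000)
      Fc <- F_rate - mean(F_rate)
      b <- as.numeric(pr$M %*% Fc)
      ab <- with_substream(cfg$seed, "ridge_fwer",
                           paste(neurons[i], ws[w], model, sep = ":"), {
        P <- vapply(seq_len(n_perm), function(j) Fc[sample.int(n)],
                    numeric(n))
        abs(pr$M %*% P)
      })
      allabs <- cbind(abs(b), ab)          # coef x (1 + n_perm)
      # rank-based exchangeable p's: p_i = #\{|b_j| >= |b_i|\} / (B + 1)
      pm <- t(apply(allabs, 1, function(a)
        (length(a) + 1 - rank(a, ties.method = "min")) / length(a)))
      beta_obs[i, w, ] <- b
      p_obs[i, w, ] <- pm[, 1]
      p_null[i, w, , ] <- pm[, -1]
    }
  }

  fwer <- lapply(stats::setNames(seq_along(cf), cf), function(j) {
    po <- matrix(p_obs[, , j], nrow = length(neurons))
    pn <- array(p_null[, , j, ], c(length(neurons), length(ws), n_perm))
    population_proportion_fwer(po, pn, alpha = cfg$alpha,
                               window_start_ms = ws)
  })
  list(model = model, window_start_ms = ws, coef_names = cf,
       beta_obs = beta_obs, p_obs = p_obs, fwer = fwer)
}
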