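#' Psychometric choice model
#'
#' Maximum-likelihood logistic regression of the choice flag on first-object
#' value: \code{P(chosen) = plogis(b0 + b1 * value1)}. Fitting is by
#' iteratively reweighted least squares capped at 25 iterations; complete or
#' quasi-complete separation (expected in overtrained behavior) is reported
#' through \code{converged = FALSE} and \code{diagnostic}, never raised.
#'
#' @param trials Trial data.frame (decision task).
#' @return List of class \code{"logistic_fit"}: \code{beta} (named vector),
#'   \code{se}, \code{converged}, \code{diagnostic}, \code{n}.
#' @export
fit_choice_logistic <- function(trials) {
  trials <- trials[trials$task == "decision", , drop = FALSE]
  if (length(unique(trials$value1)) < 2)
    stop("need >= 2 distinct value1 levels")
  if (length(unique(trials$chosen)) < 2) {
    fit <- suppressWarnings(
      stats::glm(chosen ~ value1, data = trials, family = stats::binomial(),
                 control = stats::glm.control(maxit = 25)))
    return(logistic_result(fit, nrow(trials), force_diag = "separation"))
  }
  fit <- suppressWarnings(
    stats::glm(chosen ~ value1, data = trials, family = stats::binomial(),
               control = stats::glm.control(maxit = 25)))
  logistic_result(fit, nrow(trials))
}

#' Previous-trial value model
#'
#' Logistic regression of the current choice on the previous trial's
#' second-object value and the current first-object value:
#' \code{P(chosen_t) = plogis(b0 + b1 * value2_{t-1} + b2 * value1_t)}.
#' Each session's first trial has no predecessor and is dropped, so
#' \code{n} equals total trials minus the number of sessions. Histories never
#' cross session boundaries.
#'
#' @param trials Trial data.frame (decision task), grouped by session and
#'   ordered by trial index (as returned by the readers/generators).
#' @return \code{"logistic_fit"} with coefficients
#'   \code{(b0, prev_value2, value1)}.
#' @export
fit_previous_value_logistic <- function(trials) {
  trials <- trials[trials$task == "decision", , drop = FALSE]
  trials <- trials[order(trials$session_id, trials$trial_index), ,
                   drop = FALSE]
  parts <- split(trials, trials$session_id)
  rows <- lapply(parts, function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(chosen = d$chosen[-1], v2_prev = d$value2[-nrow(d)],
               v1 = d$value1[-1])
  })
  dat <- do.call(rbind, rows)
  if (is.null(dat) || nrow(dat) < 3)
    stop("need >= 2 trials per session to form previous-trial predictors")
  dat <- dat[!is.na(dat$v2_prev), , drop = FALSE]
  if (length(unique(dat$v2_prev)) < 2) {
    return(structure(list(beta = c(NA, NA, NA), se = c(NA, NA, NA),
                          converged = FALSE,
                          diagnostic = "rank-deficient: previous value constant",
                          n = nrow(dat)), class = "logistic_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(chosen ~ v2_prev + v1, data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 25)))
  logistic_result(fit, nrow(dat))
}

logistic_result <- function(fit, n, force_diag = NULL) {
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- !fit$converged || any(abs(beta[-1]) > 15) ||
    all(fit$fitted.values > 1 - 1e-8) || all(fit$fitted.values < 1e-8)
  diag_msg <- if (!is.null(force_diag)) force_diag
  else if (sep) "possible separation or non-convergence (IRLS cap 25)"
  else ""
  structure(list(beta = beta, se = se,
                 converged = fit$converged && !sep && is.null(force_diag),
                 diagnostic = diag_msg, n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, ")\n")
  print(round(rbind(beta = x$beta, se = x$se), 4))
  if (!x$converged) cat("NOT converged:", x$diagnostic, "\n")
  invisible(x)
}

#' Indifference point (risk attitude)
#'
#' The first-object value chosen with 50\% probability under a fitted
#' psychometric curve, \code{-b0/b1}. Higher values indicate a stronger
#' tendency to hold out for the second option.
#'
#' @param fit A converged [fit_choice_logistic()] result.
#' @return Indifference value, in value units.
#' @export
risk_attitude <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge; indifference undefined")
  b0 <- fit$beta[[1]]; b1 <- fit$beta[[2]]
  if (b1 == 0) stop("slope is zero; indifference value undefined")
  unname(-b0 / b1)
}

#' Latency-vs-value regression
#'
#' OLS of button-release latency on object value. \code{which = "first"} uses
#' chosen trials (latency of the release that selects the first object,
#' regressed on \code{value1}); \code{which = "second"} uses unchosen trials
#' that carry a second-object release latency (\code{latency2_ms}, regressed
#' on \code{value2}).
#'
#' @param trials Trial data.frame.
#' @param which \code{"first"} or \code{"second"}.
#' @return List of class \code{"linear_fit"}: \code{slope}, \code{intercept},
#'   \code{se_slope}, \code{r2}, \code{n}.
#' @export
fit_latency_regression <- function(trials, which = c("first", "second")) {
  which <- match.arg(which)
  trials <- trials[trials$task == "decision", , drop = FALSE]
  if (which == "first") {
    d <- trials[trials$chosen == 1 & !is.na(trials$latency_ms), , drop = FALSE]
    x <- d$value1; y <- d$latency_ms
  } else {
    d <- trials[trials$chosen == 0 & !is.na(trials$latency2_ms), ,
                drop = FALSE]
    x <- d$value2; y <- d$latency2_ms
  }
  if (length(y) < 3) stop("insufficient data: need >= 3 usable trials")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (all(y == y[1])) 0 else sm$r.squared
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = unname(sm$coefficients[2, 2]),
                 r2 = r2, n = length(y)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: slope %.4g (SE %.3g), intercept %.4g, r2 %.3f, n %d\n",
              x$slope, x$se_slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Per-session behavioral summary
#'
#' Fits the psychometric choice model and the first-object latency regression
#' separately per session and tests the session slopes against zero with a
#' two-sided Wilcoxon signed-rank test, the session-level inference used for
#' population statements about behavior.
#'
#' @param trials Trial data.frame spanning one or more sessions.
#' @return List with \code{per_session} (data.frame of slopes) and
#'   \code{tests} (named list of \code{wilcox.test} results).
#' @export
behavior_session_summary <- function(trials) {
  parts <- split(trials, trials$session_id)
  rows <- lapply(names(parts), function(s) {
    d <- parts[[s]]
    cf <- tryCatch(fit_choice_logistic(d), error = function(e) NULL)
    lf <- tryCatch(fit_latency_regression(d, "first"),
                   error = function(e) NULL)
    data.frame(session_id = s,
               choice_slope = if (!is.null(cf)) cf$beta[[2]] else NA,
               choice_converged = if (!is.null(cf)) cf$converged else FALSE,
               latency_slope = if (!is.null(lf)) lf$slope else NA,
               indifference = if (!is.null(cf) && cf$converged)
                 risk_attitude(cf) else NA)
  })
  per <- do.call(rbind, rows)
  tests <- list()
  cs <- per$choice_slope[per$choice_converged & !is.na(per$choice_slope)]
  if (length(cs) >= 3)
    tests$choice_slope <- stats::wilcox.test(cs, mu = 0, exact = FALSE)
  ls <- per$latency_slope[!is.na(per$latency_slope)]
  if (length(ls) >= 3)
    tests$latency_slope <- stats::wilcox.test(ls, mu = 0, exact = FALSE)
  list(per_session = per, tests = tests)
}
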