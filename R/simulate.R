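#' Behavioral generator parameters
#'
#' Parameters of the synthetic decision task. On each trial two of six
#' reward-predicting objects (values 1..6, drawn i.i.d. uniform) are shown in
#' sequence; the subject releases a button to choose the first object with
#' probability \code{plogis(beta0 + beta1 * V1_t + beta_prev * V2_{t-1})}
#' (the previous-trial second-object term is omitted on each session's first
#' trial). The defaults place the indifference point at value 4
#' (\code{-beta0/beta1 = 4}), where choices actually fluctuate, with a weak
#' negative carry-over from the previous second object's value. Release
#' latency on chosen trials is Gaussian around a linearly decreasing law
#' (higher value, faster release), truncated positive; unchosen trials carry
#' a faster, flatter second-object release latency in \code{latency2_ms}.
#'
#' @param beta0,beta1 Choice-logit intercept and slope on first-object value.
#' @param beta_prev Previous-trial second-object value coefficient (small,
#'   negative by default).
#' @param lat_intercept_ms,lat_slope_ms,lat_sd_ms First-object release latency
#'   law: intercept, slope per value unit (ms), Gaussian SD (ms).
#' @param lat2_intercept_ms,lat2_slope_ms Second-object (reflexive) release
#'   latency law on unchosen trials.
#' @param n_trials Trials per session.
#' @return List of class \code{"behavior_params"}.
#' @export
behavior_params <- function(beta0 = -4.8, beta1 = 1.2, beta_prev = -0.1,
                            lat_intercept_ms = 600, lat_slope_ms = -25,
                            lat_sd_ms = 60, lat2_intercept_ms = 400,
                            lat2_slope_ms = -12, n_trials = 300L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (lat_sd_ms <= 0) stop("lat_sd_ms must be > 0")
  structure(list(beta0 = beta0, beta1 = beta1, beta_prev = beta_prev,
                 lat_intercept_ms = lat_intercept_ms,
                 lat_slope_ms = lat_slope_ms, lat_sd_ms = lat_sd_ms,
                 lat2_intercept_ms = lat2_intercept_ms,
                 lat2_slope_ms = lat2_slope_ms,
                 n_trials = as.integer(n_trials)),
            class = "behavior_params")
}

#' Neuron generator parameters
#'
#' An inhomogeneous-Poisson neuron over \code{[-400, 1000]} ms around
#' first-object onset. Its rate is \code{baseline_hz} plus
#' \code{value_gain_hz * (V1 - 3.5)} during the value epoch
#' \code{[t_value_on_ms, t_switch_ms)} and \code{choice_gain_hz * C} during
#' the choice epoch \code{[t_switch_ms, 1000)}, clipped at zero. Value coding
#' is centered at the mean value 3.5 so the baseline equals the grand-mean
#' rate and gain recovery is decoupled from baseline recovery. The hard
#' epoch switch gives an unambiguous ground-truth latency for classifier
#' recovery tests. The neuron conditions on the realized choice produced by
#' the behavioral generator, matching the conditioning structure of the
#' analyses; spike-count noise is Poisson only.
#'
#' @param baseline_hz Baseline rate (Hz), >= 0.
#' @param value_gain_hz Rate change per value unit during the value epoch.
#' @param choice_gain_hz Rate change on chosen trials during the choice epoch.
#' @param t_value_on_ms,t_switch_ms Epoch boundaries, ms;
#'   \code{0 <= t_value_on_ms < t_switch_ms <= 1000}.
#' @return List of class \code{"neuron_params"}.
#' @export
neuron_params <- function(baseline_hz = 10, value_gain_hz = 2,
                          choice_gain_hz = 5, t_value_on_ms = 100,
                          t_switch_ms = 500) {
  if (baseline_hz < 0) stop("baseline_hz must be >= 0")
  if (!(t_value_on_ms >= 0 && t_value_on_ms < t_switch_ms &&
        t_switch_ms <= 1000))
    stop("epochs must satisfy 0 <= t_value_on_ms < t_switch_ms <= 1000")
  structure(list(baseline_hz = baseline_hz, value_gain_hz = value_gain_hz,
                 choice_gain_hz = choice_gain_hz,
                 t_value_on_ms = t_value_on_ms, t_switch_ms = t_switch_ms),
            class = "neuron_params")
}

#' Stimulation-session generator parameters
#'
#' A stimulation session behaves like a behavioral session except that a
#' random half of the trials receive an additive shift \code{delta_logit} to
#' the choice logit (the other half are non-stimulation controls). Because
#' the shift acts on the logit, its effect on the choice *rate* is largest
#' where the psychometric curve is steepest, i.e. at the indifference value —
#' the structure the stimulation analyses are designed to detect. The default
#' behavior is a steep psychometric (logit \code{3 * (V - 4)}): overtrained
#' subjects choose near-deterministically away from the indifference value,
#' so a logit shift visibly moves choices only where the decision actually
#' fluctuates (value 4).
#'
#' @param delta_logit Per-site additive logit shift on stimulation trials.
#' @param n_trials Total trials (must be even; half stimulated).
#' @param behavior [behavior_params()] for the underlying task behavior.
#' @return List of class \code{"stim_params"}.
#' @export
stim_params <- function(delta_logit = 1.5, n_trials = 600L,
                        behavior = behavior_params(beta0 = -12, beta1 = 3,
                                                   beta_prev = 0)) {
  if (n_trials %% 2 != 0) stop("n_trials must be even (half stimulated)")
  structure(list(delta_logit = delta_logit, n_trials = as.integer(n_trials),
                 behavior = behavior),
            class = "stim_params")
}

# Internal: shared trial generator. delta_logit applies to rows with stim = 1.
generate_trials <- function(p, n_trials, session_id, stim, delta_logit = 0) {
  v1 <- sample.int(6L, n_trials, replace = TRUE)
  v2 <- sample.int(6L, n_trials, replace = TRUE)
  v2_prev <- c(NA_integer_, v2[-n_trials])
  logit <- p$beta0 + p$beta1 * v1 + delta_logit * stim
  logit[-1] <- logit[-1] + p$beta_prev * v2_prev[-1]
  chosen <- as.integer(stats::runif(n_trials) < stats::plogis(logit))
  rtrunc_pos <- function(mu) {
    x <- stats::rnorm(length(mu), mu, p$lat_sd_ms)
    while (any(bad <- x <= 0))
      x[bad] <- stats::rnorm(sum(bad), mu[bad], p$lat_sd_ms)
    x
  }
  latency <- rep(NA_real_, n_trials)
  i1 <- chosen == 1
  latency[i1] <- rtrunc_pos(p$lat_intercept_ms + p$lat_slope_ms * v1[i1])
  latency2 <- rep(NA_real_, n_trials)
  i0 <- chosen == 0
  latency2[i0] <- rtrunc_pos(p$lat2_intercept_ms + p$lat2_slope_ms * v2[i0])
  data.frame(session_id = session_id, trial_index = seq_len(n_trials),
             value1 = v1, value2 = v2, chosen = chosen,
             latency_ms = latency, stim = as.integer(stim),
             task = "decision", latency2_ms = latency2,
             stringsAsFactors = FALSE)
}

#' Simulate one behavioral session
#'
#' @param params [behavior_params()].
#' @param seed Integer seed.
#' @param session_id Session identifier (default \code{"s1"}).
#' @return Validated trial data.frame (see [read_trials()] for the contract).
#' @export
simulate_behavior <- function(params, seed, session_id = "s1") {
  stopifnot(inherits(params, "behavior_params"))
  df <- with_substream(seed, "behavior", session_id,
                       generate_trials(params, params$n_trials, session_id,
                                       stim = 0L))
  validate_trials(df)
}

#' Simulate one stimulation session
#'
#' Trials are generated as in [simulate_behavior()]; a random half receive
#' the \code{delta_logit} shift and are flagged \code{stim = 1}.
#'
#' @param params [stim_params()].
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @return Validated trial data.frame with the \code{stim} flag set.
#' @export
simulate_stim_session <- function(params, seed, session_id = "stim1") {
  stopifnot(inherits(params, "stim_params"))
  n <- params$n_trials
  df <- with_substream(seed, "stim_session", session_id, {
    stim <- integer(n)
    stim[sample.int(n, n %/% 2)] <- 1L
    generate_trials(params$behavior, n, session_id, stim,
                    delta_logit = params$delta_logit)
  })
  validate_trials(df)
}

#' Simulate spike trains for one neuron
#'
#' Draws, for every trial in \code{trials}, an inhomogeneous Poisson spike
#' train over \code{[-400, 1000]} ms with the piecewise-constant rate profile
#' of [neuron_params()] (rate clipped at zero). The neuron conditions on the
#' realized value and choice of each trial.
#'
#' @param params [neuron_params()].
#' @param trials Trial data.frame from [simulate_behavior()].
#' @param seed Integer seed.
#' @param neuron_id Identifier used for the RNG substream.
#' @return List of sorted spike-time vectors, one per trial, named
#'   \code{session_id:trial_index}.
#' @export
simulate_neuron <- function(params, trials, seed, neuron_id = "n1") {
  stopifnot(inherits(params, "neuron_params"))
  breaks <- c(-400, params$t_value_on_ms, params$t_switch_ms, 1000)
  with_substream(seed, "neuron", neuron_id, {
    out <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      add_val <- params$value_gain_hz * (trials$value1[i] - 3.5)
      add_cho <- params$choice_gain_hz * trials$chosen[i]
      rates <- pmax(0, params$baseline_hz + c(0, add_val, add_cho))
      sp <- numeric(0)
      for (k in 1:3) {
        dur <- breaks[k + 1] - breaks[k]
        n <- stats::rpois(1, rates[k] * dur / 1000)
        if (n > 0) sp <- c(sp, stats::runif(n, breaks[k], breaks[k + 1]))
      }
      out[[i]] <- sort(sp)
    }
    names(out) <- paste(trials$session_id, trials$trial_index, sep = ":")
    out
  })
}

#' Simulate a population of neurons
#'
#' Convenience wrapper drawing one spike-train list per parameter set, each
#' with its own RNG substream.
#'
#' @param params_list List of [neuron_params()].
#' @param trials Trial data.frame.
#' @param seed Integer seed.
#' @return Named list of spike-train lists (\code{"n1"}, \code{"n2"}, ...).
#' @export
simulate_population <- function(params_list, trials, seed) {
  out <- lapply(seq_along(params_list), function(i)
    simulate_neuron(params_list[[i]], trials, seed,
                    neuron_id = paste0("n", i)))
  names(out) <- paste0("n", seq_along(params_list))
  out
}
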