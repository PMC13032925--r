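#' Spike density function
#'
#' Trial-averaged firing-rate estimate: each spike is replaced by a Gaussian
#' kernel (SD \code{sigma_ms}), kernel sums are averaged over trials. The
#' kernel is normalized so each spike contributes unit area on the seconds
#' scale, i.e. a single spike peaks at \code{1000 / (sigma_ms * sqrt(2*pi))}
#' spikes/s.
#'
#' @param trains List of spike-time vectors (one per trial); a single numeric
#'   vector is treated as one trial.
#' @param grid Uniform evaluation grid in ms.
#' @param sigma_ms Kernel SD in ms (default 30).
#' @return List of class \code{"sdf"}: \code{times_ms}, \code{rate_hz},
#'   \code{sigma_ms}, \code{n_trials}.
#' @export
compute_sdf <- function(trains, grid, sigma_ms = 30) {
  if (is.numeric(trains)) trains <- list(trains)
  if (length(trains) < 1) stop("need >= 1 spike train")
  if (length(grid) == 0) stop("empty evaluation grid")
  if (sigma_ms <= 0) stop("sigma_ms must be > 0")
  all_sp <- unlist(trains, use.names = FALSE)
  rate <- numeric(length(grid))
  if (length(all_sp)) {
    # sum over spikes of a unit-area (in s) Gaussian: 1000 * dnorm(ms scale)
    for (s in all_sp) rate <- rate + stats::dnorm(grid, s, sigma_ms)
    rate <- rate * 1000 / length(trains)
  }
  structure(list(times_ms = grid, rate_hz = rate, sigma_ms = sigma_ms,
                 n_trials = length(trains)), class = "sdf")
}

#' @export
print.sdf <- function(x, ...) {
  cat(sprintf("SDF: %d grid points [%g, %g] ms, sigma %g ms, %d trials, peak %.2f Hz\n",
              length(x$times_ms), min(x$times_ms), max(x$times_ms),
              x$sigma_ms, x$n_trials, max(x$rate_hz)))
  invisible(x)
}

#' Firing rate in a half-open window
#'
#' Counts spikes with \code{a <= t < b} and divides by the window duration in
#' seconds. Half-open windows mean boundary spikes are never double-counted
#' across adjacent windows.
#'
#' @param train Numeric spike-time vector (ms).
#' @param a,b Window start and end (ms), \code{a < b}.
#' @return Rate in Hz.
#' @export
window_rate <- function(train, a, b) {
  if (a >= b) stop("window must satisfy a < b")
  sum(train >= a & train < b) / ((b - a) / 1000)
}

# Per-trial rates for a list of trains in [a, b); vectorized workhorse.
window_rates <- function(trains, a, b) {
  vapply(trains, function(t) sum(t >= a & t < b), 0) / ((b - a) / 1000)
}

#' Compare movement-locked modulation across tasks
#'
#' Tests whether neurons modulated around the choice action in the decision
#' task show the same modulation when the identical movement is produced in a
#' simple button-release task with no decision. Per neuron and task,
#' modulation is the mean rate in a peri-release window (aligned at button
#' release) minus the mean baseline rate (aligned at object/go onset); the
#' per-neuron test is a two-sided Wilcoxon signed-rank over trials of the
#' peri-minus-baseline differences. The population comparison is a paired
#' two-sided Wilcoxon signed-rank of decision-task vs motor-task modulation
#' across neurons, run separately for positively and negatively modulated
#' neurons (sign taken from the decision task). For unchosen decision trials
#' (no release), surrogate release times are resampled with replacement from
#' that session's chosen-trial release times (seeded).
#'
#' @param decision_trains,motor_trains Named lists (by neuron) of per-trial
#'   spike-train lists, aligned at object/go onset.
#' @param decision_trials,motor_trials Matching trial tables;
#'   \code{latency_ms} supplies release times.
#' @param peri_window Window around release, ms (default \code{c(-200, 200)}).
#' @param baseline_window Window around onset, ms (default \code{c(-200, 0)}).
#' @param seed Seed for surrogate release-time resampling.
#' @return List: \code{per_neuron} data.frame (modulations, p values, sign)
#'   and \code{population} (list of paired tests by sign group).
#' @export
motor_modulation_compare <- function(decision_trains, motor_trains,
                                     decision_trials, motor_trials,
                                     peri_window = c(-200, 200),
                                     baseline_window = c(-200, 0),
                                     seed = 1L) {
  neurons <- names(decision_trains)
  skipped <- setdiff(neurons, names(motor_trains))
  if (length(skipped))
    warning("neuron(s) missing the motor task, excluded: ",
            paste(skipped, collapse = ", "))
  neurons <- intersect(neurons, names(motor_trains))

  task_mod <- function(trains, trials, unit) {
    # substream keyed by neuron only, so identical inputs in the two tasks
    # receive identical surrogate release assignments
    release <- trials$latency_ms
    has <- !is.na(release)
    if (any(!has)) {
      if (!any(has)) stop("no release times available for surrogate sampling")
      release[!has] <- with_substream(seed, "surrogate_release", unit,
        sample(release[has], sum(!has), replace = TRUE))
    }
    peri <- mapply(function(tr, r)
      window_rate(tr, r + peri_window[1], r + peri_window[2]),
      trains, release)
    base <- window_rates(trains, baseline_window[1], baseline_window[2])
    d <- peri - base
    p <- if (all(d == 0)) 1
    else stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value
    list(mod = mean(peri) - mean(base), p = p)
  }

  rows <- lapply(neurons, function(nid) {
    dd <- task_mod(decision_trains[[nid]], decision_trials, nid)
    mm <- task_mod(motor_trains[[nid]], motor_trials, nid)
    data.frame(neuron_id = nid, mod_decision_hz = dd$mod,
               mod_motor_hz = mm$mod, p_decision = dd$p, p_motor = mm$p,
               sign = if (dd$mod >= 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)

  population <- lapply(c(positive = "positive", negative = "negative"),
    function(sg) {
      sub <- per[per$sign == sg, , drop = FALSE]
      if (nrow(sub) < 3) return(NULL)
      d <- sub$mod_decision_hz - sub$mod_motor_hz
      if (all(d == 0))
        list(statistic = 0, p.value = 1, n = nrow(sub))
      else {
        wt <- stats::wilcox.test(sub$mod_decision_hz, sub$mod_motor_hz,
                                 paired = TRUE, exact = FALSE)
        list(statistic = unname(wt$statistic), p.value = wt$p.value,
             n = nrow(sub))
      }
    })
  list(per_neuron = per, population = population)
}
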