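#' Simple-regression fit of windowed activity
#'
#' OLS of per-trial firing rate on a single predictor (object value, or the
#' binary choice flag), with the coefficient of determination and the F-test
#' of the slope. These two nested one-predictor models are the units of the
#' model-comparison classifier; a multiple regression with both predictors is
#' deliberately avoided there because value and choice are strongly
#' correlated by construction of the task.
#'
#' @param F_rate Per-trial rates (Hz).
#' @param X Per-trial predictor; must not be constant.
#' @return List: \code{beta0}, \code{beta1}, \code{r2}, \code{p} (F-test).
#' @export
fit_single_predictor <- function(F_rate, X) {
  n <- length(F_rate)
  if (n < 3) stop("need >= 3 observations")
  if (length(X) != n) stop("F_rate and X lengths differ")
  if (stats::var(X) == 0) stop("degenerate design: predictor is constant")
  xc <- X - mean(X); yc <- F_rate - mean(F_rate)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (syy == 0)
    return(list(beta0 = mean(F_rate), beta1 = 0, r2 = 0, p = 1))
  beta1 <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  r2 <- min(max(r2, 0), 1)
  p <- if (r2 >= 1) 0
  else stats::pf(r2 / (1 - r2) * (n - 2), 1, n - 2, lower.tail = FALSE)
  list(beta0 = mean(F_rate) - beta1 * mean(X), beta1 = beta1, r2 = r2, p = p)
}

# r2 of y against each column of (already centered) matrix Bc; zero-variance
# columns give 0 (with one warning from the caller).
r2_vs_matrix <- function(yc, Bc) {
  syy <- sum(yc^2)
  css <- colSums(Bc^2)
  num <- as.numeric(crossprod(yc, Bc))^2
  den <- syy * css
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

#' Monte Carlo value-vs-choice model comparison for one window
#'
#' The classifier's core test. The observed statistic is the difference in
#' R-square between the value model (\code{rate ~ value}) and the choice
#' model (\code{rate ~ chosen}) fitted to the window's per-trial rates. The
#' null is built from the baseline period, which carries no task signal: the
#' per-trial baseline rates are randomly reassigned across trials, both
#' models are fitted to the shuffled baseline rates, and their R-square
#' difference is recorded; this is repeated \code{n_shuffle} times.
#' \code{exceed_count} is the number of shuffles whose null difference lies
#' strictly below the observed difference (ties count as non-exceeding, the
#' conservative choice). Labels, at two-sided level \code{alpha}:
#' \itemize{
#'   \item \code{value}: \code{exceed_count > (1 - alpha/2) * n_shuffle} and
#'     the value model's F-test p < alpha;
#'   \item \code{choice}: \code{exceed_count < (alpha/2) * n_shuffle} and the
#'     choice model's F-test p < alpha;
#'   \item \code{intermediate}: neither tail, but both models fit
#'     significantly (both F-test p < alpha);
#'   \item \code{none}: otherwise.
#' }
#'
#' @param F_rate Per-trial rates in the analysis window (Hz).
#' @param V Per-trial first-object values.
#' @param C Per-trial choice flags (0/1).
#' @param baseline_F Per-trial baseline rates (same trial set).
#' @param n_shuffle Number of shuffles (default 1000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Master seed; \code{unit} keys the RNG substream.
#' @param unit Substream identifier (e.g. "neuron:window").
#' @return List of class \code{"mc_comparison"}: \code{dr2_obs},
#'   \code{exceed_count}, \code{n_shuffle}, \code{fit_p_value},
#'   \code{fit_p_choice}, \code{label}.
#' @export
mc_model_comparison <- function(F_rate, V, C, baseline_F, n_shuffle = 1000L,
                                alpha = 0.05, seed = 1L, unit = "w") {
  n <- length(F_rate)
  stopifnot(length(V) == n, length(C) == n, length(baseline_F) == n)
  if (n < 3) stop("need >= 3 trials")

  one_fit <- function(y, x) {
    if (stats::var(x) == 0) list(r2 = 0, p = 1)
    else fit_single_predictor(y, x)
  }
  fv <- one_fit(F_rate, V)
  fc <- one_fit(F_rate, C)
  dr2_obs <- fv$r2 - fc$r2

  if (stats::var(baseline_F) == 0)
    warning("baseline rates are constant; null differences are all 0")
  Vc <- V - mean(V); Cc <- C - mean(C)
  dr2_null <- with_substream(seed, "mc_shuffle", unit, {
    perm <- vapply(seq_len(n_shuffle), function(j) sample.int(n), integer(n))
    B <- matrix(baseline_F[perm], nrow = n)
    Bc <- B - rep(colMeans(B), each = n)
    # same statistic as observed, on shuffled no-signal data
    r2_vs_matrix(Vc, Bc) - r2_vs_matrix(Cc, Bc)
  })
  exceed <- sum(dr2_obs > dr2_null)

  hi <- (1 - alpha / 2) * n_shuffle
  lo <- (alpha / 2) * n_shuffle
  label <- if (exceed > hi && fv$p < alpha) "value"
  else if (exceed < lo && fc$p < alpha) "choice"
  else if (exceed <= hi && exceed >= lo && fv$p < alpha && fc$p < alpha)
    "intermediate"
  else "none"

  structure(list(dr2_obs = dr2_obs, exceed_count = exceed,
                 n_shuffle = n_shuffle, fit_p_value = fv$p,
                 fit_p_choice = fc$p, label = label),
            class = "mc_comparison")
}

#' Sliding-window classification of one neuron
#'
#' Applies [mc_model_comparison()] at every window start in
#' \code{[analysis_window_ms[1], analysis_window_ms[2] - window_len_ms]} at
#' \code{step_ms} spacing (half-open windows labeled by start time). The
#' baseline rate of each trial is computed once from
#' \code{baseline_window_ms}. Each window draws fresh shuffles from its own
#' seeded substream.
#'
#' @param trains Per-trial spike-train list for one neuron, aligned with the
#'   rows of \code{trials}.
#' @param trials Decision-task trial data.frame.
#' @param cfg [analysis_config()].
#' @param neuron_id Identifier recorded in the output and used for RNG
#'   substreams.
#' @return data.frame of class \code{"window_label_series"}: one row per
#'   window with \code{window_start_ms}, \code{dr2_obs}, \code{exceed_count},
#'   \code{fit_p_value}, \code{fit_p_choice}, \code{label}.
#' @export
classify_neuron <- function(trains, trials, cfg = analysis_config(),
                            neuron_id = "n1") {
  trials <- trials[trials$task == "decision", , drop = FALSE]
  n <- nrow(trials)
  if (length(trains) != n)
    stop("trains and trials describe different trial sets")
  if (n < cfg$min_trials)
    stop(sprintf("insufficient data: %d trials < min_trials = %d",
                 n, cfg$min_trials))
  len <- cfg$window_len_ms
  ws <- seq(cfg$analysis_window_ms[1], cfg$analysis_window_ms[2] - len,
            by = cfg$step_ms)
  V <- trials$value1
  C <- trials$chosen
  baseline_F <- window_rates(trains, cfg$baseline_window_ms[1],
                             cfg$baseline_window_ms[2])

  # trial x window spike-count matrix via sorted-search, O(spikes + windows)
  counts <- vapply(trains, function(sp) {
    findInterval(ws + len, sp, left.open = TRUE) -
      findInterval(ws, sp, left.open = TRUE)
  }, numeric(length(ws)))
  counts <- matrix(counts, nrow = length(ws))

  rows <- lapply(seq_along(ws), function(w) {
    F_rate <- counts[w, ] / (len / 1000)
    mc <- mc_model_comparison(F_rate, V, C, baseline_F,
                              n_shuffle = cfg$n_shuffle, alpha = cfg$alpha,
                              seed = cfg$seed,
                              unit = paste(neuron_id, ws[w], sep = ":"))
    data.frame(neuron_id = neuron_id, window_start_ms = ws[w],
               dr2_obs = mc$dr2_obs, exceed_count = mc$exceed_count,
               fit_p_value = mc$fit_p_value, fit_p_choice = mc$fit_p_choice,
               label = mc$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_label_series", "data.frame")
  out
}

#' Extract signal segments from a labeled window series
#'
#' A signal segment is a maximal run of at least \code{run_len} consecutive
#' windows carrying the same non-\code{none} label. Its latency is the start
#' time of the run's first window; \code{end_ms} is the start time of its
#' last window.
#'
#' @param series Output of [classify_neuron()].
#' @param run_len Minimum run length in windows (at the configured step).
#' @return data.frame: \code{neuron_id}, \code{kind}, \code{latency_ms},
#'   \code{end_ms}, \code{n_windows} (possibly zero rows).
#' @export
extract_segments <- function(series, run_len = 40L) {
  lab <- as.character(series$label)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values %in% c("value", "intermediate", "choice") &
    r$lengths >= run_len
  nid <- if (nrow(series)) series$neuron_id[1] else NA_character_
  out <- data.frame(
    neuron_id = rep(nid, sum(keep)),
    kind = r$values[keep],
    latency_ms = series$window_start_ms[starts[keep]],
    end_ms = series$window_start_ms[ends[keep]],
    n_windows = r$lengths[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Signal latencies across a population
#'
#' For each neuron and signal kind, the latency of the first qualifying
#' segment. With \code{align = "button_release"}, each neuron's latencies are
#' re-expressed relative to its mean release time (supply
#' \code{release_times}, a named vector per neuron). Kinds are compared
#' pairwise with two-sided Wilcoxon rank-sum tests.
#'
#' @param segments Row-bound [extract_segments()] output across neurons.
#' @param align \code{"object_onset"} (default) or \code{"button_release"}.
#' @param release_times Named numeric vector (per neuron) of mean release
#'   times, required for release alignment.
#' @return List: \code{latencies} (named list of numeric vectors per kind)
#'   and \code{comparisons} (data.frame of pairwise rank-sum p values).
#' @export
signal_latencies <- function(segments, align = c("object_onset",
                                                 "button_release"),
                             release_times = NULL) {
  align <- match.arg(align)
  kinds <- c("value", "intermediate", "choice")
  lat <- stats::setNames(vector("list", 3), kinds)
  if (nrow(segments)) {
    firsts <- do.call(rbind, lapply(
      split(segments, list(segments$neuron_id, segments$kind), drop = TRUE),
      function(d) d[which.min(d$latency_ms), , drop = FALSE]))
    if (align == "button_release") {
      if (is.null(release_times))
        stop("release_times required for button_release alignment")
      firsts$latency_ms <- firsts$latency_ms -
        release_times[firsts$neuron_id]
    }
    for (k in kinds) lat[[k]] <- firsts$latency_ms[firsts$kind == k]
  } else {
    for (k in kinds) lat[[k]] <- numeric(0)
  }
  pairs <- utils::combn(kinds, 2)
  comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p <- if (length(lat[[a]]) >= 2 && length(lat[[b]]) >= 2)
      stats::wilcox.test(lat[[a]], lat[[b]], exact = FALSE)$p.value
    else NA_real_
    data.frame(kind_a = a, kind_b = b, p = p, stringsAsFactors = FALSE)
  }))
  list(latencies = lat, comparisons = comp)
}

#' Transition probabilities between signal kinds
#'
#' Among neurons exhibiting two signal kinds, the probability that one kind's
#' first segment precedes the other's. For each unordered pair (A, B),
#' \code{P(A -> B)} is the fraction of both-kind neurons whose first A
#' segment starts before their first B segment, so
#' \code{P(A -> B) + P(B -> A) = 1}. Latency ties are counted half to each
#' direction and flagged. The transition time is the later segment's latency.
#'
#' @param segments Row-bound [extract_segments()] output across neurons.
#' @return List: \code{prob} (3x3 matrix, \code{prob[A, B] = P(A -> B)}, NA
#'   where no neuron shows both kinds), \code{n_both} (neurons per pair),
#'   \code{transition_times} (named list of later-segment latencies per
#'   ordered transition), \code{ties} (count of tied pairs).
#' @export
transition_probabilities <- function(segments) {
  kinds <- c("value", "intermediate", "choice")
  prob <- matrix(NA_real_, 3, 3, dimnames = list(kinds, kinds))
  n_both <- matrix(0L, 3, 3, dimnames = list(kinds, kinds))
  times <- list()
  ties <- 0L
  if (nrow(segments) == 0)
    return(list(prob = prob, n_both = n_both,
                transition_times = times, ties = ties))
  per_neuron <- split(segments, segments$neuron_id)
  first_lat <- lapply(per_neuron, function(d)
    vapply(split(d$latency_ms, d$kind), min, 0))
  for (i in 1:2) for (j in (i + 1):3) {
    a <- kinds[i]; b <- kinds[j]
    wins_ab <- 0
    for (fl in first_lat) {
      if (!all(c(a, b) %in% names(fl))) next
      n_both[a, b] <- n_both[a, b] + 1L
      if (fl[a] < fl[b]) {
        wins_ab <- wins_ab + 1
        times[[paste(a, b, sep = "->")]] <-
          c(times[[paste(a, b, sep = "->")]], unname(fl[b]))
      } else if (fl[b] < fl[a]) {
        times[[paste(b, a, sep = "->")]] <-
          c(times[[paste(b, a, sep = "->")]], unname(fl[a]))
      } else {
        wins_ab <- wins_ab + 0.5
        ties <- ties + 1L
      }
    }
    n_both[b, a] <- n_both[a, b]
    if (n_both[a, b] > 0) {
      prob[a, b] <- wins_ab / n_both[a, b]
      prob[b, a] <- 1 - prob[a, b]
    }
  }
  if (ties > 0) warning(ties, " tied latency pair(s) counted half each way")
  list(prob = prob, n_both = n_both, transition_times = times, ties = ties)
}
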