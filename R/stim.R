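#' Per-value stimulation effect on choice rate
#'
#' For each first-object value present in a paired stimulation/control
#' session, the difference in choice rate between stimulation and
#' non-stimulation trials (delta = rate_stim - rate_nostim). Values missing
#' either condition get an absent (NA) delta with a warning.
#'
#' @param trials Trial data.frame for one stimulation session (stim flag set
#'   on stimulated trials).
#' @return data.frame: \code{value}, \code{n_stim}, \code{n_nostim},
#'   \code{rate_stim}, \code{rate_nostim}, \code{delta}.
#' @export
delta_choice_rate <- function(trials) {
  vals <- sort(unique(trials$value1))
  rows <- lapply(vals, function(v) {
    d <- trials[trials$value1 == v, , drop = FALSE]
    ns <- sum(d$stim == 1); nn <- sum(d$stim == 0)
    rs <- if (ns > 0) mean(d$chosen[d$stim == 1]) else NA_real_
    rn <- if (nn > 0) mean(d$chosen[d$stim == 0]) else NA_real_
    data.frame(value = v, n_stim = ns, n_nostim = nn,
               rate_stim = rs, rate_nostim = rn, delta = rs - rn)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$delta)))
    warning("value(s) with a condition absent; delta set NA: ",
            paste(out$value[is.na(out$delta)], collapse = ", "))
  out
}

#' Chi-square test of the stimulation effect at one value
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on the
#' 2x2 table stimulation/non-stimulation x chosen/unchosen restricted to
#' trials with the given first-object value. A zero margin leaves the test
#' undefined (NA).
#'
#' @param trials Session trial data.frame.
#' @param value First-object value defining the stratum.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: \code{chi2}, \code{p}, \code{table}.
#' @export
site_chi_square <- function(trials, value, correct = FALSE) {
  d <- trials[trials$value1 == value, , drop = FALSE]
  tab <- table(factor(d$stim, levels = 0:1),
               factor(d$chosen, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, p = NA_real_, table = tab))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Value profile of absolute stimulation effects
#'
#' The absolute delta choice rate |delta| reflects the net stimulation effect
#' at a site even when positive and negative effects mix across sites. This
#' summarizes |delta| per value (mean, SEM) across sites, tests for a value
#' dependence with a one-way F test (site as unit), and contrasts the
#' indifference value 4 against the pooled other values.
#'
#' @param site_deltas data.frame with columns \code{site_id}, \code{value},
#'   \code{delta} (row-bound [delta_choice_rate()] outputs).
#' @param focus_value Value contrasted against the others (default 4).
#' @return List: \code{profile} (per-value mean/SEM of |delta|), \code{anova}
#'   (\code{f}, \code{p}, \code{df}), \code{contrast} (two-group Welch test
#'   of the focus value vs others), or descriptive-only when < 2 sites.
#' @export
abs_delta_profile <- function(site_deltas, focus_value = 4) {
  d <- site_deltas[!is.na(site_deltas$delta), , drop = FALSE]
  d$abs_delta <- abs(d$delta)
  prof <- do.call(rbind, lapply(sort(unique(d$value)), function(v) {
    x <- d$abs_delta[d$value == v]
    data.frame(value = v, mean_abs_delta = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), n_sites = length(x))
  }))
  n_sites <- length(unique(d$site_id))
  if (n_sites < 2)
    return(list(profile = prof, anova = NULL, contrast = NULL))
  res <- list(profile = prof)
  if (stats::var(d$abs_delta) == 0) {
    res$anova <- list(f = 0, p = 1, df = c(NA, NA))
    res$contrast <- list(statistic = 0, p = 1)
    return(res)
  }
  fit <- stats::aov(abs_delta ~ factor(value), data = d)
  sm <- summary(fit)[[1]]
  f <- sm[1, "F value"]; p <- sm[1, "Pr(>F)"]
  if (!is.finite(f)) { f <- 0; p <- 1 }
  res$anova <- list(f = f, p = p, df = sm[, "Df"])
  a <- d$abs_delta[d$value == focus_value]
  b <- d$abs_delta[d$value != focus_value]
  res$contrast <- if (length(a) >= 2 && length(b) >= 2) {
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         mean_focus = mean(a), mean_other = mean(b))
  } else NULL
  res
}

# Null deltas at one value under within-site label exchange. Only the labels
# that land on the value-v trials matter, so the permutation restricted to
# the stratum is two nested hypergeometric draws: the number of stimulation
# labels among the n_v stratum trials, then the chosen count among them.
shuffle_deltas <- function(trials, value, n_shuffle) {
  ns_tot <- sum(trials$stim == 1); nn_tot <- sum(trials$stim == 0)
  sel <- trials$value1 == value
  n_v <- sum(sel); c_v <- sum(trials$chosen[sel])
  m <- stats::rhyper(n_shuffle, ns_tot, nn_tot, n_v)
  x <- stats::rhyper(n_shuffle, c_v, n_v - c_v, m)
  d <- x / m - (c_v - x) / (n_v - m)
  d[m == 0 | m == n_v] <- NA
  d
}

#' Distribution-width shuffle test for net stimulation effects
#'
#' Tests whether the spread of site-level delta choice rates at a value
#' exceeds what trial-level condition exchange would produce. The width is
#' the sigma of a maximum-likelihood Gaussian fit to the deltas after
#' centering (i.e. the 1/n-denominator SD), matching a Gaussian fitted to
#' the delta distribution with its center normalized to zero. For each
#' shuffle, stimulation/no-stimulation labels are permuted within every site
#' (preserving per-site trial counts and value composition), deltas are
#' recomputed and the chance-level width recorded. The effect is significant
#' iff the observed width exceeds the chance width in more than
#' \code{(1 - alpha/2) * n_shuffle} shuffles (two-tailed Monte Carlo
#' convention).
#'
#' @param sessions Named list of per-site session trial data.frames.
#' @param value First-object value at which deltas are computed (default 4).
#' @param n_shuffle Number of shuffles (>= 100; default 1000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Master seed.
#' @return List of class \code{"width_test"}: \code{width_obs},
#'   \code{exceed_count}, \code{n_shuffle}, \code{p}, \code{significant},
#'   \code{deltas}, \code{null_widths}.
#' @export
width_shuffle_test <- function(sessions, value = 4, n_shuffle = 1000L,
                               alpha = 0.05, seed = 1L) {
  if (n_shuffle < 100) stop("n_shuffle must be >= 100")
  if (length(sessions) < 5)
    warning("fewer than 5 sites: width estimate is unstable")
  ml_sigma <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  deltas <- vapply(sessions, function(tr) {
    dd <- delta_choice_rate(tr)
    i <- match(value, dd$value)
    if (is.na(i)) NA_real_ else dd$delta[i]
  }, 0)
  width_obs <- ml_sigma(deltas)
  null_mat <- with_substream(seed, "width_shuffle", value,
    vapply(sessions, function(tr) shuffle_deltas(tr, value, n_shuffle),
           numeric(n_shuffle)))
  null_mat <- matrix(null_mat, nrow = n_shuffle)
  null_widths <- apply(null_mat, 1, ml_sigma)
  exceed <- sum(width_obs > null_widths, na.rm = TRUE)
  n_le <- sum(width_obs <= null_widths, na.rm = TRUE)
  p <- min(1, 2 * min(1 + n_le, 1 + exceed) / (1 + n_shuffle))
  structure(list(width_obs = width_obs, exceed_count = exceed,
                 n_shuffle = n_shuffle, p = p,
                 significant = exceed > (1 - alpha / 2) * n_shuffle,
                 deltas = deltas, null_widths = null_widths),
            class = "width_test")
}

#' @export
print.width_test <- function(x, ...) {
  cat(sprintf("Width test: observed %.4f, exceeds chance in %d/%d shuffles (p = %.3g)%s\n",
              x$width_obs, x$exceed_count, x$n_shuffle, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Stimulation effect on release latency (motor control)
#'
#' Control analysis separating decision effects from motor effects: per-site
#' mean release-latency difference (stimulation minus non-stimulation, chosen
#' trials), a population two-sided Wilcoxon signed-rank test of the
#' differences against zero, and the Pearson correlation between the latency
#' difference and the choice-rate difference at the focus value. Sites with
#' no released trials in either condition are excluded.
#'
#' @param sessions Named list of per-site session trial data.frames.
#' @param focus_value Value at which the choice-rate delta is taken
#'   (default 4).
#' @return List: \code{per_site} (data.frame of \code{delta_latency_ms} and
#'   \code{delta_choice}), \code{wilcoxon} (population test), \code{cor}
#'   (correlation test), both NULL when < 3 usable sites.
#' @export
latency_effect <- function(sessions, focus_value = 4) {
  rows <- lapply(names(sessions), function(sid) {
    tr <- sessions[[sid]]
    rel <- !is.na(tr$latency_ms)
    ls <- tr$latency_ms[rel & tr$stim == 1]
    ln <- tr$latency_ms[rel & tr$stim == 0]
    if (length(ls) == 0 || length(ln) == 0) return(NULL)
    dd <- delta_choice_rate(tr)
    i <- match(focus_value, dd$value)
    data.frame(site_id = sid, delta_latency_ms = mean(ls) - mean(ln),
               delta_choice = if (is.na(i)) NA_real_ else dd$delta[i],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  out <- list(per_site = per, wilcoxon = NULL, cor = NULL)
  if (is.null(per) || nrow(per) < 3) return(out)
  dl <- per$delta_latency_ms
  out$wilcoxon <- if (all(dl == 0)) list(statistic = 0, p.value = 1)
  else {
    wt <- stats::wilcox.test(dl, mu = 0, exact = FALSE)
    list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  ok <- !is.na(per$delta_choice)
  if (sum(ok) >= 3 && stats::sd(dl[ok]) > 0 &&
      stats::sd(per$delta_choice[ok]) > 0) {
    ct <- stats::cor.test(dl[ok], per$delta_choice[ok])
    out$cor <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  out
}

#' Early/late-half consistency of stimulation effects
#'
#' Descriptive check that per-site effects are not trial-order artifacts:
#' the sign of the delta choice rate at the focus value computed on the
#' first and second halves of each session's trials, and whether they agree.
#'
#' @param sessions Named list of per-site session trial data.frames.
#' @param focus_value Value at which deltas are computed (default 4).
#' @return data.frame: \code{site_id}, \code{delta_early}, \code{delta_late},
#'   \code{consistent}.
#' @export
half_consistency <- function(sessions, focus_value = 4) {
  rows <- lapply(names(sessions), function(sid) {
    tr <- sessions[[sid]]
    tr <- tr[order(tr$trial_index), , drop = FALSE]
    half <- nrow(tr) %/% 2
    dval <- function(d) {
      dd <- suppressWarnings(delta_choice_rate(d))
      i <- match(focus_value, dd$value)
      if (is.na(i)) NA_real_ else dd$delta[i]
    }
    de <- dval(tr[seq_len(half), , drop = FALSE])
    dl <- dval(tr[(half + 1):nrow(tr), , drop = FALSE])
    data.frame(site_id = sid, delta_early = de, delta_late = dl,
               consistent = !is.na(de) && !is.na(dl) &&
                 sign(de) == sign(dl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
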