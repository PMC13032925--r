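test_that("delta choice rate is plain per-value arithmetic", {
  p_stim <- c(.0, .1, .2, .6, .9, 1); p_no <- c(.0, .1, .2, .4, .9, 1)
  tr <- toy_stim_session(50, p_stim, p_no)
  d <- delta_choice_rate(tr)
  expect_equal(d$delta[d$value == 4], 0.20)
  expect_equal(d$n_stim, rep(50, 6))

  same <- toy_stim_session(50, p_no, p_no)
  expect_true(all(delta_choice_rate(same)$delta == 0))

  # antisymmetry under swapping condition labels; chi2 invariant
  sw <- tr; sw$stim <- 1L - sw$stim
  expect_equal(delta_choice_rate(sw)$delta, -d$delta)
  expect_equal(site_chi_square(sw, 4)$chi2, site_chi_square(tr, 4)$chi2)
})

test_that("chi-square matches the hand 2x2 formula", {
  tr <- toy_stim_session(50, p_stim = c(.5, .5, .5, .6, .5, .5),
                         p_nostim = c(.5, .5, .5, .4, .5, .5))
  # table 30/20 vs 20/30 of 50 each: N(ad-bc)^2 / (r1 r2 c1 c2) = 4
  res <- site_chi_square(tr, 4)
  expect_equal(res$chi2, 4.0, tolerance = 1e-12)
  expect_equal(res$p, pchisq(4, 1, lower.tail = FALSE))

  ident <- toy_stim_session(50, p_stim = rep(.5, 6), p_nostim = rep(.5, 6))
  res0 <- site_chi_square(ident, 3)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  degen <- toy_stim_session(20, p_stim = rep(0, 6), p_nostim = rep(0, 6))
  expect_true(is.na(site_chi_square(degen, 2)$chi2))
})

test_that("chi-square rejects at the nominal rate under the null", {
  sig <- vapply(1:500, function(i) {
    st <- simulate_stim_session(
      stim_params(delta_logit = 0, n_trials = 240,
                  behavior = behavior_params(beta0 = -4.8, beta1 = 1.2,
                                             beta_prev = 0)),
      seed = 5000 + i)
    p <- site_chi_square(st, 4)$p
    !is.na(p) && p < 0.05
  }, TRUE)
  expect_lt(abs(mean(sig) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("absolute-delta profile peaks at the indifference value", {
  set.seed(23)
  sites <- lapply(1:56, function(i)
    simulate_stim_session(
      stim_params(delta_logit = sample(c(-1.5, 1.5), 1), n_trials = 600),
      seed = 6000 + i, session_id = paste0("site", i)))
  names(sites) <- paste0("site", 1:56)
  deltas <- do.call(rbind, lapply(names(sites), function(s) {
    d <- delta_choice_rate(sites[[s]])
    data.frame(site_id = s, value = d$value, delta = d$delta)
  }))
  prof <- abs_delta_profile(deltas)
  expect_equal(prof$profile$value[which.max(prof$profile$mean_abs_delta)], 4)
  expect_lt(prof$anova$p, 0.05)
  expect_lt(prof$contrast$p, 0.05)
  expect_gt(prof$contrast$mean_focus, prof$contrast$mean_other)
})

test_that("degenerate delta profiles report no effect", {
  flat <- data.frame(site_id = rep(paste0("s", 1:4), each = 6),
                     value = rep(1:6, 4), delta = 0)
  res <- abs_delta_profile(flat)
  expect_equal(res$anova$f, 0)
  expect_equal(res$anova$p, 1)
  one <- abs_delta_profile(flat[flat$site_id == "s1", ])
  expect_null(one$anova)
})

test_that("zero deltas never exceed the chance width", {
  sess <- lapply(1:6, function(i)
    toy_stim_session(25, p_stim = rep(.5, 6), p_nostim = rep(.5, 6),
                     session_id = paste0("s", i)))
  names(sess) <- paste0("s", 1:6)
  wt <- width_shuffle_test(sess, value = 4, n_shuffle = 200, seed = 24)
  expect_equal(wt$width_obs, 0)
  expect_equal(wt$exceed_count, 0)
  expect_false(wt$significant)
})

test_that("width test flags mixed-sign effects at value 4 but not at extremes", {
  set.seed(25)
  sess <- lapply(1:50, function(i)
    simulate_stim_session(
      stim_params(delta_logit = sample(c(-1.5, 1.5), 1), n_trials = 600),
      seed = 7000 + i, session_id = paste0("site", i)))
  names(sess) <- paste0("site", 1:50)
  w4 <- width_shuffle_test(sess, value = 4, n_shuffle = 500, seed = 26)
  expect_true(w4$significant)
  expect_lt(w4$p, 0.05)
  w1 <- width_shuffle_test(sess, value = 1, n_shuffle = 500, seed = 27)
  w6 <- width_shuffle_test(sess, value = 6, n_shuffle = 500, seed = 28)
  expect_false(w1$significant)
  expect_false(w6$significant)
})

test_that("width-test p values are calibrated under a null population", {
  rej <- vapply(1:100, function(r) {
    sess <- lapply(1:12, function(i)
      simulate_stim_session(
        stim_params(delta_logit = 0, n_trials = 192),
        seed = 8000 + r * 40 + i, session_id = paste0("s", i)))
    names(sess) <- paste0("s", 1:12)
    width_shuffle_test(sess, value = 4, n_shuffle = 200,
                       seed = 9000 + r)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("latency effects are measured per site and tested at the population", {
  set.seed(29)
  sess <- lapply(1:20, function(i)
    simulate_stim_session(stim_params(delta_logit = 0, n_trials = 400),
                          seed = 10000 + i, session_id = paste0("s", i)))
  names(sess) <- paste0("s", 1:20)
  base <- latency_effect(sess)
  expect_equal(nrow(base$per_site), 20)

  # identical conditions -> exactly zero per-site differences
  same <- lapply(sess, function(tr) {
    h <- nrow(tr) %/% 2
    tr$stim <- rep(c(0L, 1L), length.out = nrow(tr))
    half <- tr[tr$stim == 0, ]
    dup <- half; dup$stim <- 1L
    dup$trial_index <- dup$trial_index + nrow(tr)
    rbind(half, dup)
  })
  z <- latency_effect(same)
  expect_true(all(z$per_site$delta_latency_ms == 0))
  expect_equal(z$wilcoxon$p.value, 1)

  # injected +30 ms shift on stimulation trials: detected, choices untouched
  shifted <- lapply(sess, function(tr) {
    tr$latency_ms <- tr$latency_ms + 30 * (tr$stim == 1)
    tr
  })
  sh <- latency_effect(shifted)
  expect_lt(sh$wilcoxon$p.value, 0.05)
  expect_equal(sh$per_site$delta_choice, base$per_site$delta_choice)
})

test_that("null latency effects are usually nonsignificant and uncorrelated", {
  hits <- vapply(1:30, function(r) {
    sess <- lapply(1:15, function(i)
      simulate_stim_session(stim_params(delta_logit = 0, n_trials = 240),
                            seed = 20000 + r * 40 + i,
                            session_id = paste0("s", i)))
    names(sess) <- paste0("s", 1:15)
    latency_effect(sess)$wilcoxon$p.value < 0.05
  }, TRUE)
  expect_lte(mean(hits), 0.10)
})

test_that("half-consistency is reported descriptively", {
  sess <- list(site1 = simulate_stim_session(
    stim_params(delta_logit = 2.5, n_trials = 1200), seed = 31))
  hc <- half_consistency(sess)
  expect_equal(nrow(hc), 1)
  expect_true(hc$consistent)
})
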