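test_that("single-predictor fit matches lm on exact and noisy data", {
  v <- 1:6
  f <- fit_single_predictor(as.numeric(v), v)
  expect_equal(f$r2, 1)
  expect_equal(f$beta1, 1)
  expect_equal(f$p, 0)

  fconst <- fit_single_predictor(rep(5, 6), v)
  expect_equal(fconst$r2, 0)
  expect_equal(fconst$p, 1)

  y <- c(2, 3, 5, 4, 6, 8)
  f2 <- fit_single_predictor(y, v)
  ref <- summary(lm(y ~ v))
  expect_equal(f2$r2, ref$r.squared, tolerance = 1e-12)
  expect_equal(f2$beta1, unname(coef(ref)[2, 1]), tolerance = 1e-12)
  expect_equal(f2$p, unname(coef(ref)[2, 4]), tolerance = 1e-12)

  expect_error(fit_single_predictor(y, rep(2, 6)), "constant")
})

test_that("noise-free value coding saturates the Monte Carlo comparison", {
  set.seed(123)
  n <- 60
  V <- rep(1:6, each = 10)
  C <- as.integer(V > 3.5)
  flip <- sample(n, n %/% 5)
  C[flip] <- 1L - C[flip]
  base <- rpois(n, 5)
  mc <- mc_model_comparison(as.numeric(V), V, C, base, n_shuffle = 1000,
                            seed = 17, unit = "t1")
  expect_equal(mc$exceed_count, 1000)
  expect_equal(mc$label, "value")

  # symmetric mirror: rate determined by choice, value independent
  set.seed(124)
  C2 <- rep(0:1, 30)
  V2 <- sample(rep(1:6, 10))
  mc2 <- mc_model_comparison(10 * C2, V2, C2, rpois(60, 5),
                             n_shuffle = 1000, seed = 18, unit = "t2")
  expect_equal(mc2$exceed_count, 0)
  expect_equal(mc2$label, "choice")

  # constant rate: nothing to explain
  mc3 <- mc_model_comparison(rep(7, 60), V, C, rpois(60, 5),
                             n_shuffle = 1000, seed = 19, unit = "t3")
  expect_equal(mc3$dr2_obs, 0)
  expect_equal(mc3$label, "none")
})

test_that("every window carries exactly one of the four labels", {
  tr <- simulate_behavior(behavior_params(n_trials = 80), seed = 25)
  trains <- simulate_neuron(neuron_params(value_gain_hz = 3), tr, seed = 25)
  cfg <- analysis_config(step_ms = 50, n_shuffle = 100, seed = 25)
  ser <- classify_neuron(trains, tr, cfg)
  expect_true(all(ser$label %in% c("value", "intermediate", "choice",
                                   "none")))
  expect_equal(nrow(ser), length(seq(0, 850, by = 50)))
})

test_that("exceed counts are uniform for an exchangeable null", {
  # rate and baseline both task-independent: exceed_count/n_shuffle ~ U(0,1)
  set.seed(42)
  u <- vapply(1:200, function(i) {
    n <- 40
    V <- sample(rep(1:6, length.out = n))
    C <- rbinom(n, 1, 0.5)
    mc <- mc_model_comparison(rnorm(n, 10), V, C, rnorm(n, 10),
                              n_shuffle = 100, seed = 600 + i, unit = "u")
    mc$exceed_count / 100
  }, 0)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("segment extraction honours the run-length rule", {
  mk_series <- function(labels, starts = seq_along(labels) - 1) {
    data.frame(neuron_id = "n1", window_start_ms = starts,
               dr2_obs = 0, exceed_count = 0, fit_p_value = 1,
               fit_p_choice = 1, label = labels, stringsAsFactors = FALSE)
  }
  lab <- rep("none", 200)
  lab[101:140] <- "value"                    # windows starting 100..139
  seg <- extract_segments(mk_series(lab), run_len = 40)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$latency_ms, 100)
  expect_equal(seg$kind, "value")

  lab39 <- rep("none", 200)
  lab39[101:139] <- "value"                  # only 39 consecutive
  expect_equal(nrow(extract_segments(mk_series(lab39), 40)), 0)

  lab2 <- rep("none", 500)
  lab2[51:100] <- "value"
  lab2[401:461] <- "choice"
  seg2 <- extract_segments(mk_series(lab2), 40)
  expect_equal(seg2$kind, c("value", "choice"))
  expect_equal(seg2$latency_ms, c(50, 400))
})

test_that("transition probabilities count first-latency order", {
  seg <- rbind(
    data.frame(neuron_id = "a", kind = c("value", "choice"),
               latency_ms = c(200, 500), end_ms = c(240, 540), n_windows = 41),
    data.frame(neuron_id = "b", kind = c("value", "choice"),
               latency_ms = c(200, 500), end_ms = c(240, 540), n_windows = 41),
    data.frame(neuron_id = "c", kind = c("choice", "value"),
               latency_ms = c(150, 400), end_ms = c(190, 440), n_windows = 41))
  tp <- transition_probabilities(seg)
  expect_equal(tp$prob["value", "choice"], 2 / 3)
  expect_equal(tp$prob["choice", "value"], 1 / 3)
  expect_equal(tp$n_both["value", "choice"], 3L)
  expect_equal(sort(tp$transition_times[["value->choice"]]), c(500, 500))
  expect_equal(tp$transition_times[["choice->value"]], 400)

  single <- seg[seg$kind == "value" & seg$neuron_id == "a", ]
  tp2 <- transition_probabilities(single)
  expect_true(all(is.na(tp2$prob)))
})

test_that("latency summaries pick each neuron's first segment per kind", {
  seg <- data.frame(neuron_id = "a", kind = c("value", "value"),
                    latency_ms = c(300, 120), end_ms = c(350, 170),
                    n_windows = 41)
  out <- signal_latencies(seg)
  expect_equal(out$latencies$value, 120)
  expect_equal(out$latencies$choice, numeric(0))

  empty <- signal_latencies(seg[0, ])
  expect_true(all(lengths(empty$latencies) == 0))

  # release alignment subtracts the per-neuron release time
  out2 <- signal_latencies(seg, align = "button_release",
                           release_times = c(a = 500))
  expect_equal(out2$latencies$value, -380)
})

test_that("insufficient trials are refused", {
  tr <- simulate_behavior(behavior_params(n_trials = 5), seed = 1)
  trains <- simulate_neuron(neuron_params(), tr, seed = 1)
  expect_error(classify_neuron(trains, tr, analysis_config(step_ms = 100)),
               "insufficient")
})
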