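test_that("lambda = 0 reproduces OLS on the standardized design", {
  set.seed(7)
  X <- cbind(v = rnorm(30), c = rbinom(30, 1, 0.5))
  F_rate <- 5 + X[, 1] - 2 * X[, 2] + rnorm(30)
  fit <- fit_ridge(F_rate, X, lambda = 0)
  ols <- coef(lm(F_rate ~ scale(X)))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-10)
})

test_that("a huge lambda shrinks penalized coefficients to zero", {
  set.seed(8)
  X <- cbind(rnorm(25), rnorm(25))
  F_rate <- rnorm(25, 10)
  fit <- fit_ridge(F_rate, X, lambda = 1e6)
  expect_true(all(abs(fit$beta[-1]) < 1e-3))
  expect_equal(fit$beta[[1]], mean(F_rate))
})

test_that("the 4-point toy matches the hand closed form", {
  F_rate <- c(1, 2, 3, 5)
  x <- c(0.1, 0.9, 0.4, 0.2)
  z <- (x - mean(x)) / sd(x)
  beta_hand <- sum(z * (F_rate - mean(F_rate))) / (sum(z^2) + 1)
  fit <- fit_ridge(F_rate, matrix(x), lambda = 1)
  expect_equal(fit$beta[[2]], beta_hand, tolerance = 1e-12)
})

test_that("closed form agrees with a numerical minimizer on random designs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(8:15, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    F_rate <- rnorm(n, 5, 2)
    lambda <- runif(1, 0, 5)
    fit <- fit_ridge(F_rate, X, lambda)
    ref <- ridge_loss_min(F_rate, X, lambda)
    expect_lt(max(abs(unname(fit$beta) - ref)), 1e-8)
  }
})

test_that("penalized coefficient norm is nonincreasing in lambda", {
  set.seed(12)
  X <- cbind(rnorm(40), rnorm(40), rnorm(40))
  F_rate <- 2 + X[, 1] + rnorm(40)
  norms <- vapply(c(0, 0.5, 1, 5, 20, 100), function(l)
    sqrt(sum(fit_ridge(F_rate, X, l)$beta[-1]^2)), 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("ridge stabilizes sign recovery under strong predictor correlation", {
  # value and choice correlated ~0.8 by construction; modest effects
  set.seed(13)
  ols_flips <- 0; ridge_flips <- 0
  for (i in 1:60) {
    n <- 40
    V <- sample(rep(1:6, length.out = n))
    C <- as.integer(V + rnorm(n, 0, 1.2) > 3.5)
    F_rate <- 10 + 0.8 * V + 1.2 * C + rnorm(n, 0, 4)
    Z <- scale(cbind(V, C))
    b_ols <- coef(lm(F_rate ~ Z))[-1]
    b_rdg <- fit_ridge(F_rate, cbind(V, C), lambda = 8)$beta[-1]
    ols_flips <- ols_flips + any(sign(b_ols) < 0)
    ridge_flips <- ridge_flips + any(sign(b_rdg) < 0)
  }
  expect_gt(ols_flips / 60, 0.10)
  expect_lt(ridge_flips, ols_flips)
})

test_that("permutation p values hit the floor for strong effects and 1 for flat data", {
  set.seed(14)
  n <- 50
  X <- cbind(v = rnorm(n), c = rnorm(n))
  F_strong <- 5 * X[, 1] + rnorm(n, 0, 1)
  p <- ridge_coef_significance(F_strong, X, lambda = 1, n_perm = 200,
                               seed = 15)
  expect_equal(unname(p["v"]), 1 / 201)

  expect_warning(
    p_flat <- ridge_coef_significance(rep(3, n), X, lambda = 1,
                                      n_perm = 200, seed = 16),
    NA)
  expect_equal(unname(p_flat), c(1, 1), ignore_attr = TRUE)

  expect_error(ridge_coef_significance(F_strong, X, n_perm = 50), "n_perm")
})

test_that("null permutation p values are close to uniform", {
  set.seed(17)
  n <- 30
  X <- cbind(v = rnorm(n))
  ps <- vapply(1:120, function(i)
    ridge_coef_significance(rnorm(n), X, lambda = 1, n_perm = 100,
                            seed = 700 + i)[[1]], 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("max-statistic thresholding uses a strict inequality", {
  # all neurons significant in window 1; null maxima strictly below 1
  n_neuron <- 20; n_win <- 5; n_perm <- 120
  p_obs <- matrix(0.5, n_neuron, n_win)
  p_obs[, 1] <- 0.001
  set.seed(18)
  p_null <- array(runif(n_neuron * n_win * n_perm, 0.2, 1),
                  c(n_neuron, n_win, n_perm))
  res <- population_proportion_fwer(p_obs, p_null, alpha = 0.05)
  expect_true(res$significant[1])
  expect_true(all(!res$significant[-1]))

  # observed proportion exactly at the null quantile: not significant
  p_null2 <- array(1, c(n_neuron, n_win, n_perm))
  p_null2[, 1, ] <- 0.001  # every null max equals 1.0
  p_obs2 <- matrix(0.001, n_neuron, n_win)
  res2 <- population_proportion_fwer(p_obs2, p_null2, alpha = 0.05)
  expect_equal(res2$null_max_quantile, 1)
  expect_true(all(!res2$significant))
})

test_that("windowed ridge recovers value coding and only value coding", {
  tr <- simulate_behavior(behavior_params(n_trials = 120), seed = 19)
  pop <- lapply(1:12, function(i)
    simulate_neuron(neuron_params(baseline_hz = 12, value_gain_hz = 4,
                                  choice_gain_hz = 0, t_value_on_ms = 0,
                                  t_switch_ms = 1000),
                    tr, seed = 20 + i, neuron_id = paste0("n", i)))
  names(pop) <- paste0("n", 1:12)
  cfg <- analysis_config(seed = 21)
  res <- run_ridge_analysis(pop, tr, "value_choice", cfg, n_perm = 150)
  expect_true(any(res$fwer$value$significant))
  expect_false(any(res$fwer$choice$significant))
})
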