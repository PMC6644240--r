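test_that("quantile binning reproduces hand-counted proportions", {
  # 100 correct, 0 errors: default cuts give 10/20/20/20/20/10
  obs <- observed_summary(rt_ms = 300 + 1:100, correct = rep(TRUE, 100),
                          congruency = rep("congruent", 100))
  b <- bin_observed(obs)
  expect_equal(b$congruent$props[1:6],
               c(0.10, 0.20, 0.20, 0.20, 0.20, 0.10), ignore_attr = TRUE)
  expect_equal(sum(b$congruent$props), 1)

  # 95 correct + 5 errors below the pooling threshold: one pooled error bin
  obs2 <- observed_summary(rt_ms = 300 + 1:100,
                           correct = c(rep(TRUE, 95), rep(FALSE, 5)),
                           congruency = rep("congruent", 100))
  b2 <- bin_observed(obs2)
  expect_length(b2$congruent$props, 7)
  expect_null(b2$congruent$error_edges)
  expect_equal(unname(b2$congruent$props[7]), 0.05)
  expect_equal(sum(b2$congruent$props), 1)

  # 50 correct + 50 errors: errors quantile-binned too
  obs3 <- observed_summary(rt_ms = c(300 + 1:50, 500 + 1:50),
                           correct = rep(c(TRUE, FALSE), each = 50),
                           congruency = rep("congruent", 100))
  b3 <- bin_observed(obs3)
  expect_length(b3$congruent$props, 12)
  expect_equal(unname(b3$congruent$props[7:12]),
               c(0.05, 0.10, 0.10, 0.10, 0.10, 0.05))
  expect_equal(sum(b3$congruent$props), 1)
})

test_that("binning requires at least one correct trial", {
  obs <- observed_summary(rt_ms = c(400, 500), correct = c(FALSE, FALSE),
                          congruency = c("congruent", "congruent"))
  expect_error(bin_observed(obs), "at least one correct")
})

test_that("G-squared matches the hand-computed example and identity case", {
  # one condition, n = 100, (0.5, 0.5) vs (0.25, 0.75)
  g2 <- g_squared(list(c(0.5, 0.5)), list(c(0.25, 0.75)), 100)
  expect_equal(g2, 2 * 100 * (0.5 * log(2) + 0.5 * log(2 / 3)))
  expect_equal(g2, 28.77, tolerance = 1e-3)
  expect_equal(g_squared(list(c(0.5, 0.5)), list(c(0.5, 0.5)), 100), 0)
  expect_error(g_squared(list(c(0.5, 0.5)), list(c(1, 0, 0)), 100),
               "mismatch")
})

test_that("G-squared is non-negative, zero only at identity, and convex-ish", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    n <- sample(50:500, 1)
    p_obs <- as.vector(stats::rmultinom(1, n, runif(k))) / n
    p_pred <- runif(k) + 1e-3
    p_pred <- p_pred / sum(p_pred)
    g <- g_squared(list(p_obs), list(p_pred), n)
    expect_gte(g, 0)
    expect_equal(g_squared(list(p_obs), list(p_obs), n), 0)
    # halving the deviation strictly decreases G-squared
    p_half <- (p_obs + p_pred) / 2
    if (g > 1e-10)
      expect_lt(g_squared(list(p_obs), list(p_half), n), g)
  }
})

test_that("zero observed proportions contribute nothing", {
  expect_equal(g_squared(list(c(0, 1)), list(c(0.5, 0.5)), 50),
               2 * 50 * log(1 / 0.5))
})

test_that("predicted proportions are normalized, floored, and CRN-stable", {
  p <- base_params()
  sim <- simulate_both(p, sim_config(n_trials = 400, seed = 2))
  obs <- observed_summary(sim$rt_ms, sim$correct, sim$congruency)
  b <- bin_observed(obs)
  fc <- fit_config(n_sim = 1000)
  pred <- predicted_proportions(p, b, fc, seed = 7)
  for (cond in names(pred)) {
    expect_equal(sum(pred[[cond]]), 1)
    expect_true(all(pred[[cond]] > 0))
    expect_true(all(pred[[cond]] <= 1))
  }
  expect_identical(pred, predicted_proportions(p, b, fc, seed = 7))
  # zeta = 0 with common random numbers: identical across congruency
  p0 <- base_params(zeta = 0)
  sim0 <- simulate_both(p0, sim_config(n_trials = 400, seed = 2))
  obs0 <- observed_summary(sim0$rt_ms, sim0$correct, sim0$congruency)
  b0 <- bin_observed(obs0)
  pred0 <- predicted_proportions(p0, b0, fc, seed = 7)
  expect_identical(pred0$congruent, pred0$incongruent)
})

test_that("true parameters beat a 30% boundary perturbation in G-squared", {
  p <- base_params()
  sim <- simulate_both(p, sim_config(n_trials = 2000, seed = 13))
  obs <- observed_summary(sim$rt_ms, sim$correct, sim$congruency)
  b <- bin_observed(obs)
  fc <- fit_config(n_sim = 5000)
  g_true <- g_squared(b, predicted_proportions(p, b, fc, seed = 31))
  p_bad <- base_params(a = 75 * 1.3)
  g_bad <- g_squared(b, predicted_proportions(p_bad, b, fc, seed = 31))
  expect_lt(g_true, g_bad)
})

test_that("fit_dataset is deterministic and never worse than its starts", {
  p <- base_params()
  sim <- simulate_both(p, sim_config(n_trials = 300, seed = 4))
  obs <- observed_summary(sim$rt_ms, sim$correct, sim$congruency)
  fc <- tiny_fit_config()
  f1 <- fit_dataset(obs, fc, seed = 11)
  f2 <- fit_dataset(obs, fc, seed = 11)
  expect_equal(f1$g2, f2$g2)
  expect_equal(unclass(f1$best_params), unclass(f2$best_params))
  expect_equal(f1$g2, min(f1$restarts$g2_final))
  expect_s3_class(f1$best_params, "dmc_params")
  expect_gte(f1$g2, 0)
  expect_equal(nrow(f1$restarts), fc$n_restarts)
})

test_that("fit configuration validates its inputs", {
  expect_error(fit_config(n_sim = 10), "n_sim")
  expect_error(fit_config(start_ranges = list(a = c(2, 1))), "start_ranges")
  pc <- fit_config(paper_scale = TRUE)
  expect_equal(pc$n_sim, 50000L)
  expect_equal(pc$max_iterations, 250L)
  expect_equal(pc$n_restarts, 30L)
})
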