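test_that("parameter validation rejects out-of-domain values", {
  expect_error(base_params(a = -1), "a > 0")
  expect_error(base_params(alpha = 1), "alpha > 1")
  expect_error(base_params(tau = 0), "tau > 0")
  expect_error(base_params(ter = 0), "ter > 0")
  expect_error(base_params(sr = -5), "sr >= 0")
  expect_error(base_params(zeta = -1), "zeta >= 0")
  expect_s3_class(base_params(), "dmc_params")
})

test_that("automatic activation starts at zero, peaks at zeta, decays", {
  cases <- expand.grid(alpha = c(1.5, 2, 3, 4.2), tau = c(30, 50, 120),
                       zeta = c(5, 20))
  for (i in seq_len(nrow(cases))) {
    p <- base_params(alpha = cases$alpha[i], tau = cases$tau[i],
                     zeta = cases$zeta[i])
    t_max <- (p$alpha - 1) * p$tau
    expect_identical(automatic_activation(0, p), 0)
    expect_equal(automatic_activation(t_max, p), p$zeta, tolerance = 1e-12)
    # peak identity on a fine grid
    grid <- seq(0.01, 1500, by = 0.01)
    act <- automatic_activation(grid, p)
    expect_equal(max(act), p$zeta, tolerance = 1e-6)
    expect_equal(grid[which.max(act)], t_max, tolerance = 0.02)
    # decay in the far tail
    expect_lt(automatic_activation(1500, p), automatic_activation(t_max, p))
  }
})

test_that("activation at alpha=2, tau=50, zeta=20, t=25 matches direct formula", {
  # independent evaluation: zeta * (t e / tau)^ (alpha-1) ... = 10*exp(0.5)
  p <- base_params(alpha = 2, tau = 50, zeta = 20)
  oracle <- 20 * (25 * exp(1) / 50)^1 * exp(-25 / 50)
  expect_equal(oracle, 10 * exp(0.5))
  expect_equal(automatic_activation(25, p), oracle, tolerance = 1e-12)
  expect_lt(automatic_activation(25, p), 20)
})

test_that("drift increments telescope and change sign at the peak", {
  p <- base_params(alpha = 2, tau = 50, zeta = 20)
  cfg <- sim_config(dt = 1)
  k <- 1:50 # t_max = 50 ms
  expect_equal(sum(automatic_drift_increment(k, p, cfg)),
               automatic_activation(50, p), tolerance = 1e-12)
  expect_lt(automatic_drift_increment(51, p, cfg), 0)
  expect_gt(automatic_drift_increment(10, p, cfg), 0)
  p0 <- base_params(zeta = 0)
  expect_equal(automatic_drift_increment(1:100, p0, cfg), rep(0, 100))
  expect_error(automatic_drift_increment(0, p, cfg), "k must be")
})

test_that("derived times match analytic t_max and a numeric gamma inverse", {
  expect_equal(unname(derived_times(base_params(alpha = 2, tau = 100))["t_max"]), 100)
  expect_equal(unname(derived_times(base_params(alpha = 1.5, tau = 80))["t_max"]), 40)
  # independent oracle: root-find P(alpha, t/tau) = 0.9
  t90_oracle <- uniroot(function(t) pgamma(t, shape = 2, scale = 50) - 0.9,
                        c(1, 5000), tol = 1e-10)$root
  expect_equal(unname(derived_times(base_params(alpha = 2, tau = 50))["t_90"]),
               t90_oracle, tolerance = 1e-7)
})

test_that("wiener_reference reproduces the closed form and its limits", {
  w <- wiener_reference(75, 0.5, 4)
  expect_equal(unname(w["mean_dt"]), (75 / 0.5) * tanh(75 * 0.5 / 16))
  expect_equal(unname(w["mean_dt"]), 147.26, tolerance = 1e-4)
  expect_equal(unname(w["p_correct"]), 0.9909, tolerance = 1e-4)
  expect_equal(unname(wiener_reference(75, 0, 4)["p_correct"]), 0.5)
  expect_gt(wiener_reference(150, 0.5, 4)["p_correct"],
            wiener_reference(75, 0.5, 4)["p_correct"])
})

test_that("simulation is deterministic given the seed", {
  p <- base_params()
  cfg <- sim_config(n_trials = 200, seed = 99)
  expect_identical(simulate_decisions(p, "incongruent", cfg),
                   simulate_decisions(p, "incongruent", cfg))
  cfg2 <- sim_config(n_trials = 200, seed = 100)
  expect_false(identical(simulate_decisions(p, "incongruent", cfg),
                         simulate_decisions(p, "incongruent", cfg2)))
})

test_that("with zeta = 0 congruency has no effect (bit-identical outcomes)", {
  p <- base_params(zeta = 0)
  cfg <- sim_config(n_trials = 500, seed = 5)
  a <- simulate_decisions(p, "congruent", cfg)
  b <- simulate_decisions(p, "incongruent", cfg)
  expect_identical(a[setdiff(names(a), "congruency")],
                   b[setdiff(names(b), "congruency")])
})

test_that("RT composition and residual positivity hold for every outcome", {
  p <- base_params(sr = 80) # stress the rejection sampler
  s <- suppressWarnings(
    simulate_decisions(p, "incongruent", sim_config(n_trials = 2000, seed = 3)))
  expect_equal(s$rt_ms, s$decision_ms + s$residual_ms)
  expect_true(all(s$residual_ms >= 0))
  expect_true(all(s$decision_ms <= 1500))
  expect_true(all(s$rt_ms > 0))
})

test_that("conflict slows incongruent trials and raises their error rate", {
  p <- base_params()
  cfg_c <- sim_config(n_trials = 50000, seed = 21)
  con <- simulate_decisions(p, "congruent", cfg_c)
  inc <- simulate_decisions(p, "incongruent", cfg_c)
  expect_gt(mean(inc$rt_ms) - mean(con$rt_ms), 0)
  expect_gt(mean(con$correct), mean(inc$correct))
})

test_that("unabsorbed trials are flagged, scored as errors, and warned about", {
  # near-zero drift and high boundary: many paths miss the horizon
  p <- base_params(mu_c = 0.01, zeta = 0, a = 200, sr = 0)
  expect_warning(
    s <- simulate_decisions(p, "congruent", sim_config(n_trials = 500, seed = 8)),
    "unabsorbed")
  stuck <- !s$absorbed
  expect_gt(sum(stuck), 0)
  expect_true(all(s$decision_ms[stuck] == 1500))
  expect_true(all(!s$correct[stuck]))
})
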