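test_that("session round trip: generated sessions load and validate", {
  cfg <- cohort_config(n_subjects = 1, n_per_congruency = 30)
  s <- simulate_session(base_params(), "sham", cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(s, path)
  loaded <- load_sessions(path)
  expect_equal(nrow(loaded), nrow(s))
  expect_equal(loaded$rt_ms, s$rt_ms)
  expect_setequal(unique(loaded$phase), c("practice", "main"))
})

test_that("load_sessions rejects inconsistent or out-of-range rows", {
  s <- manual_session(c("congruent", "incongruent"), c(TRUE, TRUE),
                      c(500, 600))
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- s
  bad$congruency[1] <- "incongruent" # word == font_color says congruent
  write_sessions(bad, path)
  expect_error(load_sessions(path), "inconsistent")
  bad2 <- s
  bad2$rt_ms[2] <- 1700
  write_sessions(bad2, path)
  expect_error(load_sessions(path), "rt_ms")
  incomplete <- s[, setdiff(names(s), "word")]
  write.csv(incomplete, path, row.names = FALSE)
  expect_error(load_sessions(path), "missing columns")
})

test_that("sequence annotation shifts congruency by one main trial", {
  s <- manual_session(c("congruent", "incongruent", "incongruent"),
                      rep(TRUE, 3), c(500, 600, 610))
  a <- annotate_sequence(s)
  expect_equal(a$prev_congruency, c("none", "congruent", "incongruent"))

  # practice trials neither receive nor feed CPT
  s2 <- manual_session(rep("congruent", 4), rep(TRUE, 4), rep(500, 4),
                       phase = c("practice", "practice", "main", "main"))
  a2 <- annotate_sequence(s2)
  expect_equal(a2$prev_congruency, c("none", "none", "none", "congruent"))

  # session boundary resets CPT
  s3 <- rbind(manual_session(c("congruent", "incongruent"), c(TRUE, TRUE),
                             c(500, 600), condition = "sham"),
              manual_session(c("incongruent", "congruent"), c(TRUE, TRUE),
                             c(500, 600), condition = "6hz"))
  a3 <- annotate_sequence(s3)
  expect_equal(a3$prev_congruency, c("none", "congruent", "none", "incongruent"))

  # alternating sequence of 10: enumerate CPT counts by hand
  alt <- manual_session(rep(c("congruent", "incongruent"), 5), rep(TRUE, 10),
                        rep(500, 10))
  a4 <- annotate_sequence(alt)
  expect_equal(sum(a4$prev_congruency == "congruent"), 5)
  expect_equal(sum(a4$prev_congruency == "incongruent"), 4)
  expect_equal(sum(a4$prev_congruency == "none"), 1)

  expect_error(annotate_sequence(s[c(2, 1), ]), "ordered")
})

test_that("exclusion rules drop error and posterror trials for RT analyses", {
  s <- annotate_sequence(manual_session(rep("congruent", 4),
                                        c(TRUE, FALSE, TRUE, TRUE),
                                        rep(500, 4)))
  rt <- apply_exclusions(s, for_rt = TRUE)
  expect_equal(rt$trial_idx, c(0L, 3L))
  acc <- apply_exclusions(s, for_rt = FALSE)
  expect_equal(nrow(acc), 4)
  # idempotence
  expect_equal(apply_exclusions(rt, for_rt = TRUE), rt)

  # practice always dropped
  s2 <- annotate_sequence(manual_session(rep("congruent", 3), rep(TRUE, 3),
                                         rep(500, 3),
                                         phase = c("practice", "main", "main")))
  expect_equal(nrow(apply_exclusions(s2, for_rt = TRUE)), 2)
})

test_that("exclusions on randomly placed errors match a brute-force count", {
  set.seed(77)
  correct <- runif(600) > 0.05
  s <- annotate_sequence(manual_session(
    sample(c("congruent", "incongruent"), 600, TRUE), correct,
    runif(600, 400, 900)))
  kept <- apply_exclusions(s, for_rt = TRUE)
  # independent rule application on the raw vectors
  posterror <- c(FALSE, !correct[-600])
  expect_equal(nrow(kept), sum(correct & !posterror))
  expect_equal(kept$trial_idx, (which(correct & !posterror) - 1L))
})

test_that("effect table reproduces cell means, Stroop, and Gratton", {
  # hand-built cells: RTs constant within each CCT x CPT cell
  cct <- rep(c("congruent", "incongruent"), each = 8)
  cpt <- rep(rep(c("congruent", "incongruent"), each = 4), 2)
  rt <- c(rep(600, 4), rep(590, 4), rep(650, 4), rep(620, 4))
  tr <- data.frame(participant = "s01", condition = "sham",
                   congruency = cct, prev_congruency = cpt, rt_ms = rt,
                   correct = TRUE, phase = "main")
  et <- effect_table(tr)
  e <- et$sham
  expect_equal(unname(e$cells_cct_cpt["congruent", "congruent"]), 600)
  expect_equal(e$stroop_effect, mean(c(650, 620)) - mean(c(600, 590)))
  expect_equal(unname(e$stroop_by_cpt["congruent"]), 50)
  expect_equal(unname(e$stroop_by_cpt["incongruent"]), 30)
  expect_equal(e$gratton, 20)
  # stroop reproduces from its cell means exactly
  expect_equal(e$stroop_effect,
               unname(e$cells_cct["incongruent"] - e$cells_cct["congruent"]),
               tolerance = 1e-9)

  # identical RTs in all cells: all effects zero
  tr0 <- tr; tr0$rt_ms <- 500
  e0 <- effect_table(tr0)$sham
  expect_equal(e0$stroop_effect, 0)
  expect_equal(e0$gratton, 0)
})

test_that("grand mean RT equals the count-weighted mean of CCT cell means", {
  set.seed(12)
  tr <- annotate_sequence(manual_session(
    sample(c("congruent", "incongruent"), 200, TRUE, prob = c(0.7, 0.3)),
    rep(TRUE, 200), runif(200, 400, 900)))
  e <- effect_table(tr)$sham
  n_c <- sum(tr$congruency == "congruent")
  n_i <- 200 - n_c
  expect_equal((n_c * e$cells_cct["congruent"] +
                  n_i * e$cells_cct["incongruent"]) / 200,
               mean(tr$rt_ms), ignore_attr = TRUE)
})

test_that("label-permuted data show no systematic Stroop effect", {
  set.seed(5)
  rt <- runif(400, 400, 900)
  effects <- replicate(200, {
    lab <- sample(rep(c("congruent", "incongruent"), each = 200))
    mean(rt[lab == "incongruent"]) - mean(rt[lab == "congruent"])
  })
  expect_lt(abs(mean(effects)), 2 * sd(effects) / sqrt(200))
})

test_that("delta_vs_sham computes sham-minus-active differences", {
  tab <- effect_table_from_summary(data.frame(
    condition = c("sham", "6hz"),
    stroop = c(40, 30),
    stroop_cpt_congruent = c(50, 35),
    stroop_cpt_incongruent = c(30, 25)))
  d <- delta_vs_sham(tab)
  expect_equal(d$delta[d$effect == "stroop"], 10)
  expect_equal(d$delta[d$effect == "stroop_cpt_congruent"], 15)
  expect_equal(d$delta[d$effect == "gratton"], 20 - 10)
  # identical tables: all deltas zero
  tab0 <- effect_table_from_summary(data.frame(
    condition = c("sham", "6hz"), stroop = c(40, 40)))
  expect_true(all(delta_vs_sham(tab0)$delta == 0, na.rm = TRUE))
  expect_error(delta_vs_sham(effect_table_from_summary(
    data.frame(condition = "6hz", stroop = 30))), "sham")
})
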