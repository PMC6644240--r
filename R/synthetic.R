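#' @name synthetic_data
#' @title Synthetic Stroop experiment generator
#' @description Generates complete synthetic two-choice Stroop sessions --
#'   balanced stimulus sequences, chi-squared interstimulus intervals,
#'   practice phase with the 18-of-last-20 termination rule, and
#'   DMC-generated responses with configurable conflict-adaptation and
#'   stimulation-condition effects -- standing in for the request-only
#'   study data.
NULL

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Stimulus-to-button mapping
#'
#' Four color words on two response buttons: green and red share one
#' button, yellow and blue the other (the two-alternative forced-choice
#' design).
#'
#' @return list with `colors` and a named `buttons` vector.
#' @export
stimulus_mapping <- function() {
  list(colors = c("green", "red", "yellow", "blue"),
       buttons = c(green = 1L, red = 1L, yellow = 2L, blue = 2L))
}

balanced_assign <- function(items, n) {
  # n slots spread as evenly as possible over items; remainder randomized
  k <- length(items)
  counts <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) {
    extra <- sample.int(k, rem)
    counts[extra] <- counts[extra] + 1
  }
  rep(items, times = counts)
}

#' Generate a randomized Stroop stimulus sequence
#'
#' Exactly `n_per_congruency` congruent (word equals font color) and
#' `n_per_congruency` incongruent trials in uniform random order.
#' Incongruent stimuli always pair a word and a font color that map to
#' *different* buttons, so the word's semantics genuinely conflicts with
#' the required response. Words and font colors are balanced across the
#' four colors up to integer remainders.
#'
#' @param n_per_congruency trials per congruency (default 300, i.e. a
#'   600-trial main phase).
#' @param mapping a [stimulus_mapping()].
#' @param seed RNG seed.
#' @return data.frame with columns `word`, `font_color`, `congruency`.
#' @export
generate_sequence <- function(n_per_congruency = 300,
                              mapping = stimulus_mapping(), seed = 1) {
  stopifnot(n_per_congruency >= 1)
  buttons <- mapping$buttons
  colors <- mapping$colors
  cross_pairs <- expand.grid(word = colors, font_color = colors,
                             stringsAsFactors = FALSE)
  cross_pairs <- cross_pairs[buttons[cross_pairs$word] !=
                               buttons[cross_pairs$font_color], ]
  with_seed(seed, {
    cong_color <- balanced_assign(colors, n_per_congruency)
    cong <- data.frame(word = cong_color, font_color = cong_color,
                       congruency = "congruent", stringsAsFactors = FALSE)
    idx <- balanced_assign(seq_len(nrow(cross_pairs)), n_per_congruency)
    incong <- data.frame(word = cross_pairs$word[idx],
                         font_color = cross_pairs$font_color[idx],
                         congruency = "incongruent", stringsAsFactors = FALSE)
    seq_df <- rbind(cong, incong)
    seq_df <- seq_df[sample.int(nrow(seq_df)), ]
    rownames(seq_df) <- NULL
    seq_df
  })
}

#' Sample interstimulus intervals
#'
#' Chi-squared ISIs on \[0.3, 0.7\] s with mean 0.5 s: draws are
#' `0.3 + 0.075 * chisq(df = 4)`, resampled until inside the range. The
#' scale 0.075 is calibrated analytically so the truncated mean is 0.500 s.
#'
#' @param n number of intervals.
#' @param seed RNG seed.
#' @return numeric vector of ISIs in seconds, all inside \[0.3, 0.7\].
#' @export
sample_isi <- function(n, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- 0.3 + 0.075 * rchisq(2 * (n - length(out)) + 10, df = 4)
      out <- c(out, draw[draw >= 0.3 & draw <= 0.7])
    }
    out[seq_len(n)]
  })
}

#' Simulate a practice phase
#'
#' Practice trials accumulate until at least 50 trials have been run and at
#' least 18 of the last 20 were correct; a cap of 500 trials guards against
#' non-terminating configurations (with a warning). Congruency is random
#' (50/50) per trial.
#'
#' @param params the subject's [dmc_params()].
#' @param seed RNG seed.
#' @param sim a [sim_config()] template (its `n_trials`/`seed` are ignored).
#' @return data.frame of practice trials: `word`, `font_color`,
#'   `congruency`, `rt_ms`, `correct`, `phase`.
#' @export
simulate_practice <- function(params, seed = 1, sim = sim_config()) {
  seeds <- derive_seeds(seed, 101)
  mapping <- stimulus_mapping()
  trials <- NULL
  block <- 0
  repeat {
    block <- block + 1
    stim <- generate_sequence(5, mapping, seed = seeds[block])
    out <- rbind(
      sim_block(params, stim[stim$congruency == "congruent", ], "congruent",
                sim, seeds[block] + 1),
      sim_block(params, stim[stim$congruency == "incongruent", ],
                "incongruent", sim, seeds[block] + 2))
    out <- out[with_seed(seeds[block] + 3, sample.int(nrow(out))), ]
    trials <- rbind(trials, out)
    n <- nrow(trials)
    if (n >= 50 && sum(trials$correct[(n - 19):n]) >= 18) break
    if (n >= 500) {
      warning("practice did not reach criterion within 500 trials",
              call. = FALSE)
      break
    }
  }
  trials$phase <- "practice"
  rownames(trials) <- NULL
  trials
}

# simulate DMC outcomes for a stimulus subset; deadline-censored at max_time
sim_block <- function(params, stim, congruency, sim, seed) {
  if (!nrow(stim)) return(NULL)
  cfg <- sim_config(dt = sim$dt, sigma = sim$sigma, n_trials = nrow(stim),
                    max_time = sim$max_time, seed = seed)
  out <- suppressWarnings(simulate_decisions(params, congruency, cfg))
  missed <- !out$absorbed | out$rt_ms > cfg$max_time
  data.frame(word = stim$word, font_color = stim$font_color,
             congruency = congruency,
             rt_ms = pmin(out$rt_ms, cfg$max_time),
             correct = out$correct & !missed,
             stringsAsFactors = FALSE)
}

#' Cohort configuration for synthetic experiments
#'
#' Group-level parameter distribution and effect sizes of the generative
#' model. Per-subject parameters are drawn around `means` with
#' between-subject `sds` (normal for `a`, `mu_c`, `ter`; moment-matched
#' log-normal for `zeta`, `alpha - 1`, `tau`, `sr` to respect their
#' domains; redrawn until valid). Conflict adaptation is generated by
#' shrinking the automatic amplitude by the factor `1 - kappa` on trials
#' preceded by an incongruent trial. Stimulation conditions act through
#' multipliers: `zeta_mult` scales the automatic amplitude on trials
#' preceded by a *congruent* trial (the stratum the reference finding
#' localises the reduction to), `kappa_mult` scales the adaptation
#' coefficient.
#'
#' @param n_subjects number of subjects.
#' @param conditions stimulation conditions; must include `"sham"`.
#' @param means,sds named numeric vectors over the seven DMC parameters.
#' @param kappa adaptation coefficient in \[0, 1).
#' @param stim_effects named list per condition of
#'   `list(zeta_mult =, kappa_mult =)`.
#' @param n_per_congruency main-phase trials per congruency.
#' @param seed master seed.
#' @return `dmc_cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 12,
                          conditions = c("sham", "6hz"),
                          means = c(a = 75, mu_c = 0.5, zeta = 20, alpha = 2,
                                    tau = 50, ter = 300, sr = 30),
                          sds = c(a = 8, mu_c = 0.06, zeta = 4, alpha = 0.3,
                                  tau = 10, ter = 25, sr = 6),
                          kappa = 0.25,
                          stim_effects = default_stim_effects(),
                          n_per_congruency = 300,
                          seed = 1) {
  stopifnot(n_subjects >= 1, "sham" %in% conditions,
            kappa >= 0, kappa < 1, n_per_congruency >= 1,
            all(dmc_param_names() %in% names(means)),
            all(dmc_param_names() %in% names(sds)))
  for (cond in conditions)
    if (is.null(stim_effects[[cond]]))
      stim_effects[[cond]] <- list(zeta_mult = 1, kappa_mult = 1)
  if (any(vapply(stim_effects, function(e)
    e$zeta_mult <= 0 || e$kappa_mult <= 0, logical(1))))
    stop("stimulation multipliers must be positive", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 means = means[dmc_param_names()], sds = sds[dmc_param_names()],
                 kappa = kappa, stim_effects = stim_effects,
                 n_per_congruency = as.integer(n_per_congruency), seed = seed),
            class = "dmc_cohort_config")
}

#' Default stimulation effects
#'
#' Theta (6 Hz) stimulation shrinks the automatic amplitude to 70% on
#' trials preceded by a congruent trial; the alpha control (9.7 Hz) and
#' sham are null.
#'
#' @return named list of per-condition multiplier lists.
#' @export
default_stim_effects <- function() {
  list(sham = list(zeta_mult = 1, kappa_mult = 1),
       `6hz` = list(zeta_mult = 0.7, kappa_mult = 1),
       `9.7hz` = list(zeta_mult = 1, kappa_mult = 1))
}

draw_subject_params <- function(means, sds, seed) {
  lnorm_draw <- function(m, s) {
    if (s == 0) return(m)
    sig2 <- log(1 + s^2 / m^2)
    rlnorm(1, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
  }
  with_seed(seed, {
    for (attempt in seq_len(100)) {
      p <- list(a = rnorm(1, means["a"], sds["a"]),
                mu_c = rnorm(1, means["mu_c"], sds["mu_c"]),
                zeta = lnorm_draw(means["zeta"], sds["zeta"]),
                alpha = 1 + lnorm_draw(means["alpha"] - 1, sds["alpha"]),
                tau = lnorm_draw(means["tau"], sds["tau"]),
                ter = rnorm(1, means["ter"], sds["ter"]),
                sr = lnorm_draw(means["sr"], sds["sr"]))
      p <- lapply(p, unname)
      ok <- tryCatch({ validate_dmc_params(p); TRUE },
                     error = function(e) FALSE)
      if (ok) return(do.call(dmc_params, p))
    }
    stop("failed to draw valid subject parameters in 100 attempts",
         call. = FALSE)
  })
}

#' Simulate one complete Stroop session
#'
#' Composes [generate_sequence()], [sample_isi()], [simulate_practice()]
#' and the DMC simulator into one session of trial records. Each main
#' trial's automatic amplitude is
#' `zeta * (1 - kappa_eff * [CPT = incongruent]) * (zeta_mult if CPT =
#' congruent)`, where CPT is the previous trial's congruency (known from
#' the stimulus sequence). Responses slower than the 1500 ms deadline are
#' censored: scored incorrect with RT 1500 ms.
#'
#' @param subject_params the subject's [dmc_params()].
#' @param condition stimulation condition label.
#' @param config a [cohort_config()].
#' @param seed session seed.
#' @param participant participant id stored in the records.
#' @return data.frame of trial records in the [load_sessions()] schema.
#' @export
simulate_session <- function(subject_params, condition, config = cohort_config(),
                             seed = 1, participant = "s01") {
  stopifnot(inherits(config, "dmc_cohort_config"))
  eff <- config$stim_effects[[condition]]
  if (is.null(eff)) eff <- list(zeta_mult = 1, kappa_mult = 1)
  seeds <- derive_seeds(seed, 6)
  sim <- sim_config()

  practice <- simulate_practice(subject_params, seed = seeds[1], sim = sim)

  stim <- generate_sequence(config$n_per_congruency, stimulus_mapping(),
                            seed = seeds[2])
  cpt <- c("none", stim$congruency[-nrow(stim)])
  kappa_eff <- min(config$kappa * eff$kappa_mult, 0.999)
  zeta_t <- subject_params$zeta *
    ifelse(cpt == "incongruent", 1 - kappa_eff, 1) *
    ifelse(cpt == "congruent", eff$zeta_mult, 1)

  # batch trials sharing (effective zeta, congruency) into single simulator
  # calls, then scatter outcomes back into sequence order
  group <- interaction(round(zeta_t, 10), stim$congruency, drop = TRUE)
  rt <- numeric(nrow(stim)); correct <- logical(nrow(stim))
  group_seeds <- derive_seeds(seeds[3], nlevels(group))
  for (g in seq_len(nlevels(group))) {
    rows <- which(as.integer(group) == g)
    p_g <- subject_params
    p_g$zeta <- zeta_t[rows[1]]
    out <- sim_block(p_g, stim[rows, ], stim$congruency[rows[1]], sim,
                     group_seeds[g])
    rt[rows] <- out$rt_ms
    correct[rows] <- out$correct
  }

  main <- data.frame(word = stim$word, font_color = stim$font_color,
                     congruency = stim$congruency, rt_ms = rt,
                     correct = correct, phase = "main",
                     stringsAsFactors = FALSE)
  all_tr <- rbind(practice[names(main)], main)
  n <- nrow(all_tr)
  buttons <- stimulus_mapping()$buttons
  correct_button <- buttons[all_tr$font_color]
  session <- data.frame(
    participant = participant,
    condition = condition,
    trial_idx = seq_len(n) - 1L,
    phase = all_tr$phase,
    word = all_tr$word,
    font_color = all_tr$font_color,
    congruency = all_tr$congruency,
    prev_congruency = NA_character_,
    response = ifelse(all_tr$correct, correct_button, 3L - correct_button),
    correct = all_tr$correct,
    rt_ms = all_tr$rt_ms,
    isi_s = sample_isi(n, seed = seeds[4]),
    stringsAsFactors = FALSE)
  annotate_sequence(session)
}

#' Simulate a full within-subject cohort
#'
#' Every subject performs every condition (crossover design) with
#' counterbalanced condition order (rotation by subject index). Returns the
#' stacked sessions, a truth table of per-subject generating parameters for
#' recovery studies, and the session order.
#'
#' @param config a [cohort_config()].
#' @return list with `sessions` (data.frame of all trial records), `truth`
#'   (data.frame: participant, parameter, value), and `order` (data.frame:
#'   participant, position, condition).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "dmc_cohort_config"))
  n <- config$n_subjects
  k <- length(config$conditions)
  seeds <- matrix(derive_seeds(config$seed, n * (k + 1)), nrow = n)
  ids <- sprintf("s%02d", seq_len(n))

  sessions <- list(); truth <- list(); order <- list()
  for (i in seq_len(n)) {
    pars <- draw_subject_params(config$means, config$sds, seeds[i, 1])
    truth[[i]] <- data.frame(participant = ids[i],
                             parameter = dmc_param_names(),
                             value = unlist(pars[dmc_param_names()]),
                             row.names = NULL)
    cond_order <- config$conditions[((seq_len(k) + i - 2) %% k) + 1]
    order[[i]] <- data.frame(participant = ids[i], position = seq_len(k),
                             condition = cond_order)
    for (j in seq_len(k))
      sessions[[length(sessions) + 1]] <-
        simulate_session(pars, cond_order[j], config, seeds[i, j + 1], ids[i])
  }
  list(sessions = do.call(rbind, sessions),
       truth = do.call(rbind, truth),
       order = do.call(rbind, order))
}
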