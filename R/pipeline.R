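#' Pipeline configuration
#'
#' Bundles all stage configurations of the end-to-end pipeline:
#' generate synthetic sessions, compute effect tables and sham-vs-active
#' deltas, fit the DMC per participant and session, permutation-test the
#' fitted parameters across conditions, and (optionally) run a recovery
#' study.
#'
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("generate", "effects", "fit", "permtest", "recover")`.
#' @param cohort a [cohort_config()].
#' @param fit a [fit_config()].
#' @param n_perm permutations for the stage-4 tests.
#' @param recovery_datasets datasets for the optional recovery stage.
#' @param seed master seed (stage seeds derive from it).
#' @param paper_scale use reference-scale fitting settings.
#' @return `dmc_pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("generate", "effects", "fit", "permtest"),
                            cohort = cohort_config(),
                            fit = fit_config(),
                            n_perm = 10000,
                            recovery_datasets = 20,
                            seed = 1,
                            paper_scale = FALSE) {
  stages <- match.arg(stages, c("generate", "effects", "fit", "permtest",
                                "recover"), several.ok = TRUE)
  if (paper_scale) fit <- fit_config(paper_scale = TRUE,
                                     start_ranges = fit$start_ranges,
                                     bin_spec = fit$bin_spec)
  structure(list(out_dir = out_dir, stages = stages, cohort = cohort,
                 fit = fit, n_perm = n_perm,
                 recovery_datasets = recovery_datasets, seed = seed,
                 paper_scale = paper_scale),
            class = "dmc_pipeline_config")
}

write_stage_csv <- function(df, path, config_echo) {
  con <- file(path, "w")
  writeLines(paste0("# ", config_echo), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

read_stage_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order (generate, effects, fit,
#' permtest, recover), writing tidy CSVs into `config$out_dir`. Every
#' output carries a `#`-prefixed header echoing the producing stage and
#' seed; re-running with an identical config reproduces identical file
#' checksums. With two conditions the permutation stage runs paired
#' Fisher-Pitman tests per parameter with Holm correction; with three or
#' more it switches to the maxT multivariate Kruskal-Wallis test.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dmc_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4)
  echo <- function(stage) sprintf("dmcstroop stage=%s seed=%d", stage,
                                  config$seed)
  outputs <- character(0)
  t0 <- Sys.time()
  log_stage <- function(stage, info) {
    message(sprintf("[%s] %s (%.1f s elapsed)", stage, info,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  cohort <- NULL
  sessions_path <- file.path(config$out_dir, "sessions.csv")
  if ("generate" %in% stages(config)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- seeds[1]
    cohort <- simulate_cohort(cohort_cfg)
    outputs <- c(outputs,
      write_stage_csv(cohort$sessions, sessions_path, echo("generate")),
      write_stage_csv(cohort$truth,
                      file.path(config$out_dir, "truth_params.csv"),
                      echo("generate")),
      write_stage_csv(cohort$order,
                      file.path(config$out_dir, "session_order.csv"),
                      echo("generate")))
    log_stage("generate", sprintf("%d trials, %d subjects",
                                  nrow(cohort$sessions),
                                  cohort_cfg$n_subjects))
  }
  sessions <- if (!is.null(cohort)) cohort$sessions else
    read_stage_csv(sessions_path)

  if ("effects" %in% stages(config)) {
    rt_trials <- apply_exclusions(sessions, for_rt = TRUE)
    acc_trials <- apply_exclusions(sessions, for_rt = FALSE)
    effects <- effect_table(rt_trials, acc_trials)
    outputs <- c(outputs,
      write_stage_csv(as.data.frame(effects),
                      file.path(config$out_dir, "effects.csv"),
                      echo("effects")))
    if ("sham" %in% names(effects) && length(effects) > 1)
      outputs <- c(outputs,
        write_stage_csv(delta_vs_sham(effects),
                        file.path(config$out_dir, "effect_deltas.csv"),
                        echo("effects")))
    log_stage("effects", sprintf("%d RT trials after exclusions",
                                 nrow(rt_trials)))
  }

  fits <- NULL
  fits_path <- file.path(config$out_dir, "fits.csv")
  if ("fit" %in% stages(config)) {
    main <- sessions[sessions$phase == "main", ]
    cells <- split(main, list(main$participant, main$condition), drop = TRUE)
    fit_seeds <- derive_seeds(seeds[2], length(cells))
    fits <- do.call(rbind, lapply(seq_along(cells), function(i) {
      tr <- cells[[i]]
      obs <- observed_summary(tr$rt_ms, tr$correct, tr$congruency)
      f <- fit_dataset(obs, config$fit, seed = fit_seeds[i])
      vals <- c(unlist(f$best_params[dmc_param_names()]),
                derived_times(f$best_params), g2 = f$g2)
      data.frame(participant = tr$participant[1], condition = tr$condition[1],
                 parameter = names(vals), value = unname(vals),
                 row.names = NULL)
    }))
    outputs <- c(outputs, write_stage_csv(fits, fits_path, echo("fit")))
    log_stage("fit", sprintf("%d participant-sessions fitted", length(cells)))
  }

  if ("permtest" %in% stages(config)) {
    conds <- sort(unique(sessions$condition))
    if (!is.null(fits) || file.exists(fits_path)) {
      if (is.null(fits)) fits <- read_stage_csv(fits_path)
      tests <- permtest_parameters(fits, conds, config$n_perm, seeds[3])
    } else {
      # behavioral fallback: per-subject Stroop effects across conditions
      rt_trials <- apply_exclusions(sessions, for_rt = TRUE)
      tests <- permtest_stroop(rt_trials, conds, config$n_perm, seeds[3])
    }
    outputs <- c(outputs,
      write_stage_csv(tests, file.path(config$out_dir, "permtest.csv"),
                      echo("permtest")))
    log_stage("permtest", sprintf("%d tests", nrow(tests)))
  }

  if ("recover" %in% stages(config)) {
    rec <- run_recovery(n_datasets = config$recovery_datasets,
                        fit_config = config$fit, seed = seeds[4])
    outputs <- c(outputs,
      write_stage_csv(rec$records,
                      file.path(config$out_dir, "recovery_report.csv"),
                      echo("recover")),
      write_stage_csv(rec$summary,
                      file.path(config$out_dir, "recovery_summary.csv"),
                      echo("recover")))
    log_stage("recover", sprintf("%d datasets", config$recovery_datasets))
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         row.names = NULL)
  write_stage_csv(manifest, file.path(config$out_dir, "manifest.csv"),
                  echo("manifest"))
  invisible(manifest)
}

stages <- function(config) config$stages

# paired Fisher-Pitman (2 conditions) or maxT Kruskal-Wallis (3+) on a tidy
# table of fitted parameter values
permtest_parameters <- function(fits, conds, n_perm, seed) {
  fits <- fits[fits$parameter != "g2", ]
  params <- unique(fits$parameter)
  subjects <- sort(unique(fits$participant))
  arr <- array(NA_real_, c(length(subjects), length(conds), length(params)),
               dimnames = list(subjects, conds, params))
  for (r in seq_len(nrow(fits)))
    arr[fits$participant[r], fits$condition[r], fits$parameter[r]] <-
      fits$value[r]
  if (anyNA(arr))
    stop("incomplete participants x conditions grid", call. = FALSE)
  if (length(conds) == 2) {
    res <- do.call(rbind, lapply(params, function(p) {
      t <- fisher_pitman_paired(arr[, 1, p], arr[, 2, p], n_perm, seed)
      data.frame(parameter = p, test = "fisher_pitman",
                 statistic = t$statistic, p_mc = t$p_mc)
    }))
    res$p_adjusted <- holm_adjust(res$p_mc)
  } else {
    kt <- kruskal_maxT(arr, n_perm, seed)
    res <- data.frame(parameter = kt$parameter, test = "kruskal_maxT",
                      statistic = kt$statistic, p_mc = kt$p_mc,
                      p_adjusted = kt$p_mc)  # maxT is already multiplicity-adjusted
  }
  res$n_permutations <- n_perm
  res$seed <- seed
  res
}

permtest_stroop <- function(rt_trials, conds, n_perm, seed) {
  eff <- function(tr) mean(tr$rt_ms[tr$congruency == "incongruent"]) -
    mean(tr$rt_ms[tr$congruency == "congruent"])
  cells <- tapply(seq_len(nrow(rt_trials)),
                  list(rt_trials$participant, rt_trials$condition),
                  function(i) eff(rt_trials[i, ]))
  m <- matrix(unlist(cells), nrow = nrow(cells),
              dimnames = dimnames(cells))[, conds, drop = FALSE]
  if (length(conds) == 2) {
    t <- fisher_pitman_paired(m[, 1], m[, 2], n_perm, seed)
    data.frame(parameter = "stroop_effect", test = "fisher_pitman",
               statistic = t$statistic, p_mc = t$p_mc, p_adjusted = t$p_mc,
               n_permutations = n_perm, seed = seed)
  } else {
    kt <- kruskal_maxT(array(m, c(dim(m), 1),
                             dimnames = c(dimnames(m), list("stroop_effect"))),
                       n_perm, seed)
    data.frame(parameter = kt$parameter, test = "kruskal_maxT",
               statistic = kt$statistic, p_mc = kt$p_mc, p_adjusted = kt$p_mc,
               n_permutations = n_perm, seed = seed)
  }
}
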