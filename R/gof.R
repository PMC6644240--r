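#' Observed RT/accuracy summary
#'
#' Reduce trial-level data to the per-congruency summary the G-squared
#' machinery consumes: sorted correct RTs, sorted error RTs, and the total
#' trial count per condition.
#'
#' @param rt_ms response times (ms).
#' @param correct logical vector, same length.
#' @param congruency character/factor vector of condition labels.
#' @return `dmc_observed` object: a named list (one element per condition)
#'   of `list(correct_rt, error_rt, n_total)`.
#' @export
observed_summary <- function(rt_ms, correct, congruency) {
  stopifnot(length(rt_ms) == length(correct),
            length(rt_ms) == length(congruency))
  if (any(!is.finite(rt_ms)) || any(rt_ms <= 0))
    stop("RTs must be positive and finite", call. = FALSE)
  out <- lapply(split(seq_along(rt_ms), as.character(congruency)), function(i) {
    ok <- as.logical(correct[i])
    list(correct_rt = sort(rt_ms[i][ok]),
         error_rt = sort(rt_ms[i][!ok]),
         n_total = length(i))
  })
  structure(out, class = "dmc_observed")
}

#' Quantile-bin specification
#'
#' Defines the multinomial reduction of an RT distribution: correct RTs are
#' cut at empirical percentiles (default 10/30/50/70/90, giving six bins);
#' error RTs are cut the same way when at least `min_errors` errors exist,
#' and pooled into a single bin otherwise (a condition with zero errors
#' keeps an empty pooled bin, which contributes nothing to G-squared but
#' keeps the predicted accuracy mass accounted for).
#'
#' @param correct_cuts percentiles in (0, 100), strictly increasing.
#' @param error_cuts percentiles for error RTs.
#' @param min_errors minimum error count for quantile-binning errors.
#' @return `dmc_bin_spec` object.
#' @export
bin_spec <- function(correct_cuts = c(10, 30, 50, 70, 90),
                     error_cuts = c(10, 30, 50, 70, 90),
                     min_errors = 11) {
  stopifnot(all(diff(correct_cuts) > 0), all(correct_cuts > 0),
            all(correct_cuts < 100),
            all(diff(error_cuts) > 0), all(error_cuts > 0),
            all(error_cuts < 100), min_errors >= 1)
  structure(list(correct_cuts = correct_cuts, error_cuts = error_cuts,
                 min_errors = min_errors), class = "dmc_bin_spec")
}

bin_counts <- function(rt, edges) {
  # bins (-Inf, e1], (e1, e2], ..., (e_last, Inf)
  breaks <- c(-Inf, edges, Inf)
  tabulate(findInterval(rt, breaks, left.open = TRUE), length(edges) + 1L)
}

#' Bin observed data by empirical RT quantiles
#'
#' @param data a [observed_summary()] object.
#' @param spec a [bin_spec()].
#' @return `dmc_binned` object: per condition, realized `correct_edges`,
#'   `error_edges` (NULL when errors are pooled), bin `counts` and
#'   proportions `props` (summing to 1 over all bins of the condition), and
#'   `n_total`.
#' @export
bin_observed <- function(data, spec = bin_spec()) {
  stopifnot(inherits(data, "dmc_observed"))
  out <- lapply(data, function(cond) {
    if (length(cond$correct_rt) < 1)
      stop("each condition needs at least one correct trial", call. = FALSE)
    ce <- unname(quantile(cond$correct_rt, spec$correct_cuts / 100, type = 7))
    cc <- bin_counts(cond$correct_rt, ce)
    if (length(cond$error_rt) >= spec$min_errors) {
      ee <- unname(quantile(cond$error_rt, spec$error_cuts / 100, type = 7))
      ec <- bin_counts(cond$error_rt, ee)
    } else {
      ee <- NULL
      ec <- length(cond$error_rt)
    }
    counts <- c(correct = cc, error = ec)
    list(correct_edges = ce, error_edges = ee,
         counts = counts, props = counts / cond$n_total,
         n_total = cond$n_total)
  })
  structure(out, class = "dmc_binned")
}

classify_simulation <- function(sim, bins, n_sim) {
  ok <- sim$correct
  cc <- bin_counts(sim$rt_ms[ok], bins$correct_edges)
  if (!is.null(bins$error_edges)) {
    ec <- bin_counts(sim$rt_ms[!ok], bins$error_edges)
  } else {
    ec <- sum(!ok)
  }
  c(cc, ec) / n_sim
}

#' Model-predicted bin proportions
#'
#' Simulate `fit_config$n_sim` trials per congruency from `params` and
#' classify them into the observed bin edges. Predicted proportions are
#' floored at `1/(2 n_sim)` and renormalized so G-squared stays finite.
#'
#' @param params a [dmc_params()] object.
#' @param binned a [bin_observed()] result providing the realized edges;
#'   condition names must be `"congruent"`/`"incongruent"`.
#' @param fit_config a [fit_config()].
#' @param seed seed for the simulation (common random numbers: reuse the
#'   same seed across objective evaluations).
#' @return named list of predicted proportion vectors, aligned with
#'   `binned`.
#' @export
predicted_proportions <- function(params, binned, fit_config = fit_config(),
                                  seed = 1) {
  stopifnot(inherits(binned, "dmc_binned"))
  cfg <- sim_config(dt = fit_config$dt, sigma = fit_config$sigma,
                    n_trials = fit_config$n_sim,
                    max_time = fit_config$max_time, seed = seed)
  floor_p <- 1 / (2 * fit_config$n_sim)
  out <- lapply(names(binned), function(cond) {
    sim <- suppressWarnings(simulate_decisions(params, cond, cfg))
    p <- classify_simulation(sim, binned[[cond]], fit_config$n_sim)
    p <- pmax(p, floor_p)
    p / sum(p)
  })
  names(out) <- names(binned)
  out
}

#' G-squared goodness of fit
#'
#' Likelihood-ratio-type statistic between observed and predicted
#' multinomial bin proportions:
#' \deqn{G^2 = 2 \sum_{c} n_c \sum_{b} p^{obs}_{cb}
#'   \ln(p^{obs}_{cb} / p^{pred}_{cb}),}
#' with zero observed proportions contributing zero. Non-negative, and zero
#' iff observed and predicted agree on every nonzero bin.
#'
#' @param observed_props list (per condition) of observed proportion
#'   vectors, or a `dmc_binned` object.
#' @param predicted_props list of predicted proportion vectors with the
#'   same structure.
#' @param n_per_condition total observation counts per condition (taken
#'   from the `dmc_binned` object when one is supplied).
#' @return the G-squared statistic (scalar).
#' @export
g_squared <- function(observed_props, predicted_props, n_per_condition = NULL) {
  if (inherits(observed_props, "dmc_binned")) {
    if (is.null(n_per_condition))
      n_per_condition <- vapply(observed_props, `[[`, numeric(1), "n_total")
    observed_props <- lapply(observed_props, `[[`, "props")
  }
  if (length(observed_props) != length(predicted_props))
    stop("observed and predicted must have the same number of conditions",
         call. = FALSE)
  if (is.null(n_per_condition))
    stop("n_per_condition is required", call. = FALSE)
  g2 <- 0
  for (i in seq_along(observed_props)) {
    po <- observed_props[[i]]
    pp <- predicted_props[[i]]
    if (length(po) != length(pp))
      stop("bin structure mismatch in condition ", i, call. = FALSE)
    nz <- po > 0
    g2 <- g2 + 2 * n_per_condition[[i]] * sum(po[nz] * log(po[nz] / pp[nz]))
  }
  g2
}

#' Fitting configuration
#'
#' Settings of the simulation-based G-squared minimisation. The reference
#' procedure uses 50,000 simulated observations per congruency per
#' objective evaluation, a 250-iteration Nelder-Mead cap, and 30 random
#' restarts; the desk-scale defaults (5,000 / 100 / 5) keep a single fit in
#' the tens of seconds. Set `paper_scale = TRUE` to restore the reference
#' values.
#'
#' @param n_sim simulated observations per congruency per evaluation.
#' @param max_iterations Nelder-Mead iteration cap per restart.
#' @param n_restarts number of uniform random restarts.
#' @param start_ranges named list of `c(lower, upper)` per parameter from
#'   which starting values are drawn uniformly.
#' @param bin_spec a [bin_spec()].
#' @param dt,sigma,max_time simulator settings, see [sim_config()].
#' @param paper_scale logical; override n_sim/max_iterations/n_restarts
#'   with the reference-scale values 50,000 / 250 / 30.
#' @return `dmc_fit_config` object.
#' @export
fit_config <- function(n_sim = 5000, max_iterations = 100, n_restarts = 5,
                       start_ranges = default_start_ranges(),
                       bin_spec = dmcstroop::bin_spec(),
                       dt = 1, sigma = 4, max_time = 1500,
                       paper_scale = FALSE) {
  if (paper_scale) {
    n_sim <- 50000; max_iterations <- 250; n_restarts <- 30
  }
  stopifnot(n_sim >= 100, n_restarts >= 1, max_iterations >= 1)
  rngs <- start_ranges[dmc_param_names()]
  if (any(vapply(rngs, function(r) is.null(r) || r[1] >= r[2], logical(1))))
    stop("start_ranges must give lower < upper for every parameter",
         call. = FALSE)
  structure(list(n_sim = as.integer(n_sim),
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts),
                 start_ranges = rngs, bin_spec = bin_spec,
                 dt = dt, sigma = sigma, max_time = max_time,
                 paper_scale = paper_scale),
            class = "dmc_fit_config")
}

#' Default uniform start ranges for fitting
#'
#' Plausible parameter ranges for Stroop data (times in ms, evidence units
#' as in [dmc_params()]); the reference study drew starts from unpublished
#' pilot ranges, so these are package defaults, fully configurable.
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_start_ranges <- function() {
  list(a = c(40, 120), mu_c = c(0.2, 0.8), zeta = c(5, 40),
       alpha = c(1.5, 4.5), tau = c(20, 200), ter = c(200, 400),
       sr = c(5, 60))
}

# lower feasibility bounds (strict domain edges nudged inward)
param_domain_lower <- function() {
  c(a = 1e-3, mu_c = -Inf, zeta = 0, alpha = 1 + 1e-3, tau = 1e-3,
    ter = 1e-3, sr = 0)
}

#' Fit DMC parameters to an observed dataset
#'
#' Multi-restart Nelder-Mead minimisation of [g_squared()] between the
#' observed quantile-bin proportions and proportions predicted by
#' simulation. Each restart draws a uniform start point from
#' `fit_config$start_ranges` and holds its own simulation seed fixed across
#' objective evaluations (common random numbers), so the objective is a
#' deterministic function of the parameters within a restart.
#' Out-of-domain proposals receive a penalty of `1e9` plus the squared
#' distance to the domain instead of erroring.
#'
#' @param data an [observed_summary()] object with conditions
#'   `"congruent"` and `"incongruent"`.
#' @param fit_config a [fit_config()].
#' @param seed master seed; restart starts and restart seeds derive from it.
#' @return `dmc_fit` object: `best_params` ([dmc_params()]), `g2`,
#'   `restarts` (data.frame of start points, final G-squared, iteration
#'   counts, seeds), `config`, and `n_sim_total`.
#' @export
fit_dataset <- function(data, fit_config = fit_config(), seed = 1) {
  stopifnot(inherits(data, "dmc_observed"))
  binned <- bin_observed(data, fit_config$bin_spec)
  nm <- dmc_param_names()
  lower <- param_domain_lower()[nm]

  objective <- function(par, sim_seed) {
    viol <- pmax(lower - par, 0)
    viol[!is.finite(lower)] <- 0
    if (any(viol > 0)) return(1e9 + sum(viol^2))
    p <- as_dmc_params(as.list(stats::setNames(par, nm)))
    pred <- predicted_proportions(p, binned, fit_config, seed = sim_seed)
    g_squared(binned, pred)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1, fit_config$n_restarts)
  starts <- lapply(seq_len(fit_config$n_restarts), function(i)
    vapply(fit_config$start_ranges, function(r) runif(1, r[1], r[2]),
           numeric(1)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  records <- vector("list", fit_config$n_restarts)
  best <- NULL
  for (i in seq_len(fit_config$n_restarts)) {
    # parscale from the start-range midpoints: parameters span three orders
    # of magnitude and an unscaled simplex stalls on the small ones
    parscale <- vapply(fit_config$start_ranges, mean, numeric(1))
    fit <- optim(starts[[i]], objective, sim_seed = restart_seeds[i],
                 method = "Nelder-Mead",
                 control = list(maxit = fit_config$max_iterations,
                                parscale = parscale))
    records[[i]] <- data.frame(restart = i,
                               t(stats::setNames(starts[[i]],
                                                 paste0("start_", nm))),
                               g2_final = fit$value,
                               evaluations = unname(fit$counts["function"]),
                               seed = restart_seeds[i])
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$restart <- i
    }
  }
  if (best$value >= 1e9)
    stop("all restarts ended outside the parameter domain", call. = FALSE)

  structure(list(best_params = as_dmc_params(as.list(
                   stats::setNames(best$par, nm))),
                 g2 = best$value,
                 best_restart = best$restart,
                 restarts = do.call(rbind, records),
                 config = fit_config,
                 seed = seed,
                 n_sim_total = 2 * fit_config$n_sim *
                   sum(vapply(records, `[[`, numeric(1), "evaluations"))),
            class = "dmc_fit")
}

#' @export
print.dmc_fit <- function(x, ...) {
  cat(sprintf("DMC fit: G2 = %.3f (best of %d restarts)\n",
              x$g2, nrow(x$restarts)))
  print(x$best_params)
  invisible(x)
}
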