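#' DMC parameter set
#'
#' Bundle the seven free parameters of the diffusion model for conflict
#' tasks (DMC): boundary separation, controlled drift rate, the amplitude /
#' shape / scale of the gamma-shaped automatic activation, and the mean and
#' spread of the residual (nondecision) time.
#'
#' The decision process starts at 0 and is absorbed at +`a` (correct) or
#' -`a` (error). Drift is the sum of a constant controlled rate `mu_c` and
#' the time derivative of the expected automatic activation
#' \deqn{E[X_a(t)] = \zeta \left(\frac{t e}{(\alpha-1)\tau}\right)^{\alpha-1}
#'   e^{-t/\tau},}
#' which rises from 0, peaks at exactly `zeta` at
#' \eqn{t_{max} = (\alpha-1)\tau}, and decays back toward 0. The automatic
#' component aids the correct response on congruent trials and opposes it on
#' incongruent trials.
#'
#' @param a boundary separation (evidence units), > 0.
#' @param mu_c controlled drift rate (evidence/ms).
#' @param zeta amplitude of the automatic activation (evidence units), >= 0.
#' @param alpha gamma shape of the automatic activation, > 1.
#' @param tau gamma scale of the automatic activation (ms), > 0.
#' @param ter mean residual (nondecision) time (ms), > 0.
#' @param sr standard deviation of the residual time (ms), >= 0.
#' @return An object of class `dmc_params` (named list).
#' @examples
#' p <- dmc_params(a = 75, mu_c = 0.5, zeta = 20, alpha = 2, tau = 50,
#'                 ter = 300, sr = 30)
#' derived_times(p) # t_max = 50 ms
#' @export
dmc_params <- function(a, mu_c, zeta, alpha, tau, ter, sr) {
  p <- list(a = a, mu_c = mu_c, zeta = zeta, alpha = alpha, tau = tau,
            ter = ter, sr = sr)
  validate_dmc_params(p)
  class(p) <- "dmc_params"
  p
}

validate_dmc_params <- function(p) {
  num <- vapply(p[dmc_param_names()], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("all DMC parameters must be finite scalars", call. = FALSE)
  bad <- character(0)
  if (p$a <= 0) bad <- c(bad, "a > 0")
  if (p$zeta < 0) bad <- c(bad, "zeta >= 0")
  if (p$alpha <= 1) bad <- c(bad, "alpha > 1")
  if (p$tau <= 0) bad <- c(bad, "tau > 0")
  if (p$ter <= 0) bad <- c(bad, "ter > 0")
  if (p$sr < 0) bad <- c(bad, "sr >= 0")
  if (length(bad))
    stop("invalid DMC parameters; need ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.dmc_params <- function(x, ...) {
  cat("DMC parameters:\n")
  print(unlist(x[dmc_param_names()]))
  dt <- derived_times(x)
  cat(sprintf("derived: t_max = %.2f ms, t_90 = %.2f ms\n",
              dt[["t_max"]], dt[["t_90"]]))
  invisible(x)
}

dmc_param_names <- function() c("a", "mu_c", "zeta", "alpha", "tau", "ter", "sr")

as_dmc_params <- function(x) {
  if (inherits(x, "dmc_params")) return(x)
  x <- as.list(x)[dmc_param_names()]
  do.call(dmc_params, x)
}

#' Simulation configuration
#'
#' Euler integration settings for the DMC simulator. Defaults match the
#' standard DMC discretisation: 1 ms steps, diffusion coefficient 4
#' (evidence per sqrt-ms), and a 1500 ms horizon equal to the Stroop task's
#' trial length.
#'
#' @param dt integration step (ms).
#' @param sigma diffusion coefficient (evidence/sqrt(ms)).
#' @param n_trials number of trials to simulate per call.
#' @param max_time simulation horizon (ms).
#' @param seed integer seed; all randomness in [simulate_decisions()] is a
#'   pure function of this value.
#' @return An object of class `dmc_sim_config`.
#' @export
sim_config <- function(dt = 1, sigma = 4, n_trials = 1000, max_time = 1500,
                       seed = 1) {
  stopifnot(dt > 0, sigma > 0, n_trials >= 1, max_time >= dt)
  structure(list(dt = dt, sigma = sigma, n_trials = as.integer(n_trials),
                 max_time = max_time, seed = seed),
            class = "dmc_sim_config")
}

#' Expected automatic activation
#'
#' Evaluate the expected superimposed automatic activation
#' \eqn{E[X_a(t)] = \zeta (t e / ((\alpha-1)\tau))^{\alpha-1} e^{-t/\tau}}
#' at times `t`. The curve starts at 0, attains its single maximum `zeta`
#' at \eqn{t_{max} = (\alpha-1)\tau}, and decays toward 0.
#'
#' @param t time(s) since stimulus onset (ms), >= 0.
#' @param params a [dmc_params()] object.
#' @return numeric vector of activations (evidence units).
#' @export
automatic_activation <- function(t, params) {
  params <- as_dmc_params(params)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  dmc_activation_cpp(as.numeric(t), params$zeta, params$alpha, params$tau)
}

#' Automatic drift increment over one Euler step
#'
#' The exact increment of the expected automatic activation over step `k`,
#' i.e. \eqn{E[X_a(k \Delta t)] - E[X_a((k-1)\Delta t)]}. Using exact
#' increments (rather than the analytic derivative) telescopes to the
#' activation itself and avoids the derivative's singularity at t = 0 for
#' shape parameters below 2.
#'
#' @param k step index (vector of integers >= 1).
#' @param params a [dmc_params()] object.
#' @param config a [sim_config()] (only `dt` is used).
#' @return numeric vector of evidence increments.
#' @export
automatic_drift_increment <- function(k, params, config = sim_config()) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  automatic_activation(k * config$dt, params) -
    automatic_activation((k - 1) * config$dt, params)
}

#' Derived timing quantities of the automatic process
#'
#' @param params a [dmc_params()] object.
#' @return named numeric vector with `t_max = (alpha - 1) * tau` (location
#'   of the activation peak, ms) and `t_90` (90th percentile of the
#'   Gamma(shape alpha, scale tau) distribution, ms).
#' @export
derived_times <- function(params) {
  params <- as_dmc_params(params)
  c(t_max = (params$alpha - 1) * params$tau,
    t_90 = qgamma(0.9, shape = params$alpha, scale = params$tau))
}

#' Closed-form Wiener first-passage reference
#'
#' Analytic mean decision time and accuracy of a constant-drift Wiener
#' process started at 0 between absorbing bounds at -a and +a: the zeta = 0
#' limit of the DMC. Used as an independent oracle for the simulator.
#'
#' @param a boundary separation (> 0).
#' @param mu drift rate.
#' @param sigma diffusion coefficient (> 0).
#' @return named numeric vector `c(mean_dt = (a/mu) tanh(a mu / sigma^2),
#'   p_correct = 1 / (1 + exp(-2 a mu / sigma^2)))`; for mu = 0 the limits
#'   `(a^2/sigma^2, 0.5)`.
#' @export
wiener_reference <- function(a, mu, sigma) {
  stopifnot(a > 0, sigma > 0)
  if (mu == 0) return(c(mean_dt = a^2 / sigma^2, p_correct = 0.5))
  x <- a * mu / sigma^2
  c(mean_dt = (a / mu) * tanh(x), p_correct = 1 / (1 + exp(-2 * x)))
}
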