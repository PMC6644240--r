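#' Paired Fisher-Pitman Monte-Carlo permutation test
#'
#' Two-sided permutation test for paired samples using the raw-score
#' statistic. The observed statistic is the standardized sum of within-pair
#' differences, \eqn{Z = \sum d_i / \sqrt{\sum d_i^2}}; the null
#' distribution is generated by independently flipping the sign of each
#' pair's difference. The Monte-Carlo p-value uses the +1 correction,
#' \eqn{p = (1 + \#\{|T^*| \ge |T|\}) / (1 + n_{perm})}, so it is never 0.
#'
#' @param x,y paired numeric vectors (condition A and B per participant).
#' @param n_perm number of Monte-Carlo permutations (reference value
#'   10,000).
#' @param seed RNG seed.
#' @return `dmc_test` object: `statistic` (Z), `p_mc`, `n_permutations`,
#'   `seed`.
#' @export
fisher_pitman_paired <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2, n_perm >= 1)
  d <- x - y
  ss <- sqrt(sum(d^2))
  if (ss == 0) {
    res <- list(statistic = 0, p_mc = 1, n_permutations = n_perm, seed = seed)
    class(res) <- "dmc_test"
    return(res)
  }
  z_obs <- sum(d) / ss
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                  nrow = n_perm)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  z_perm <- as.vector(signs %*% d) / ss
  p <- (1 + sum(abs(z_perm) >= abs(z_obs) - 1e-12)) / (1 + n_perm)
  structure(list(statistic = z_obs, p_mc = min(p, 1),
                 n_permutations = n_perm, seed = seed),
            class = "dmc_test")
}

#' @export
print.dmc_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_mc, x$n_permutations))
  invisible(x)
}

kw_statistic <- function(values, groups) {
  # tie-corrected Kruskal-Wallis H on mid-ranks
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) return(0)
  h / correction
}

#' Multivariate Kruskal-Wallis permutation test with maxT adjustment
#'
#' For each endpoint (e.g. each DMC parameter) a tie-corrected
#' Kruskal-Wallis rank statistic compares the three (or more) stimulation
#' conditions. The joint null is generated by permuting condition labels
#' within each participant — the same within-participant permutation is
#' applied to every endpoint, preserving their correlation. Multiplicity is
#' handled single-step: each endpoint's p-value is the proportion of
#' permutations whose maximum statistic across endpoints reaches that
#' endpoint's observed statistic (+1 corrected).
#'
#' @param values numeric array `participants x conditions x parameters`
#'   (dimnames of the third margin label the endpoints), or a matrix for a
#'   single endpoint.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed.
#' @return data.frame with one row per endpoint: `parameter`, `statistic`
#'   (maxT-compared KW statistic), `p_mc`, `n_permutations`, `seed`.
#' @export
kruskal_maxT <- function(values, n_perm = 10000, seed = 1) {
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1)
  stopifnot(length(dim(values)) == 3, n_perm >= 1)
  n_sub <- dim(values)[1]; n_cond <- dim(values)[2]; n_par <- dim(values)[3]
  pnames <- dimnames(values)[[3]]
  if (is.null(pnames)) pnames <- paste0("param", seq_len(n_par))
  groups <- rep(seq_len(n_cond), each = n_sub)

  obs <- vapply(seq_len(n_par), function(j) {
    v <- as.vector(values[, , j])
    if (length(unique(v)) == 1) 0 else kw_statistic(v, groups)
  }, numeric(1))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  count_ge <- numeric(n_par)
  for (b in seq_len(n_perm)) {
    # one label permutation per participant, shared across endpoints
    perm <- vapply(seq_len(n_sub), function(i) sample.int(n_cond),
                   integer(n_cond))
    stat_b <- vapply(seq_len(n_par), function(j) {
      m <- matrix(values[, , j], n_sub, n_cond)
      pm <- m
      for (i in seq_len(n_sub)) pm[i, ] <- m[i, perm[, i]]
      v <- as.vector(pm)
      if (length(unique(v)) == 1) 0 else kw_statistic(v, groups)
    }, numeric(1))
    max_b <- max(stat_b)
    count_ge <- count_ge + (max_b >= obs - 1e-12)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  p <- pmin((1 + count_ge) / (1 + n_perm), 1)
  p[obs == 0] <- 1
  data.frame(parameter = pnames, statistic = obs, p_mc = p,
             n_permutations = n_perm, seed = seed, row.names = NULL)
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction: sort the p-values ascending, multiply the
#' i-th by (m - i + 1), enforce monotonicity with a running maximum, cap at
#' 1, and restore the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  ord <- order(p)
  adj <- pmin(cummax(p[ord] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
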