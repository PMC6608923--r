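#' Prior specification
#'
#' Independent half-Cauchy \eqn{Ca^+(0, scale)} priors on every observation
#' and evolution standard deviation, LKJ(\eqn{v}) priors
#' \eqn{p(\Omega \mid v) \propto |\Omega|^{v-1}} on both correlation
#' matrices (\eqn{v = 1} is uniform over valid correlation matrices), and a
#' diffuse Gaussian prior \eqn{N(0, \kappa I)} on the initial state.
#'
#' @param sd_scale half-Cauchy scale for the standard deviations (default 1).
#' @param corr_shape LKJ shape \eqn{v > 0} (default 1).
#' @param init_state_var diffuse initial-state variance \eqn{\kappa}
#'   (default \eqn{10^7}).
#' @return an object of class `sutse_priors`.
#' @export
prior_spec <- function(sd_scale = 1, corr_shape = 1, init_state_var = 1e7) {
  stopifnot(sd_scale > 0, corr_shape > 0, init_state_var > 0)
  structure(list(sd_scale = sd_scale, corr_shape = corr_shape,
                 init_state_var = init_state_var),
            class = "sutse_priors")
}

#' Half-Cauchy log density
#'
#' Density \eqn{2 / (\pi s (1 + (x/s)^2))} on \eqn{x \ge 0}.
#'
#' @param x nonnegative quantile(s).
#' @param scale scale parameter \eqn{s > 0}.
#' @param log return the log density?
#' @return density values (`-Inf`/0 for negative `x`).
#' @export
dhalfcauchy <- function(x, scale = 1, log = FALSE) {
  ld <- ifelse(x < 0, -Inf,
               log(2) - log(pi) - log(scale) - log1p((x / scale)^2))
  if (log) ld else exp(ld)
}

#' Log prior density of the covariance hyperparameters
#'
#' Sum of half-Cauchy log densities of the \eqn{2C} standard deviations plus
#' \eqn{(v-1) \log\det\Omega} for each correlation matrix.  The LKJ term is
#' unnormalized by default (sufficient for MCMC); `normalized = TRUE` adds
#' the LKJ normalizing constant, useful when comparing against prior draws.
#'
#' @param params a [cov_params()] object.
#' @param priors a [prior_spec()] object.
#' @param normalized include the LKJ normalizing constant?
#' @return the log prior density (scalar).
#' @export
log_prior <- function(params, priors = prior_spec(), normalized = FALSE) {
  stopifnot(inherits(params, "sutse_covparams"), inherits(priors, "sutse_priors"))
  v <- priors$corr_shape
  lkj_term <- function(R) {
    ed <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ed) <= 0) stop("correlation matrix is not positive definite")
    (v - 1) * sum(log(ed)) +
      if (normalized) lkj_log_norm_const(nrow(R), v) else 0
  }
  sum(dhalfcauchy(params$obs_sd, priors$sd_scale, log = TRUE)) +
    sum(dhalfcauchy(params$evo_sd, priors$sd_scale, log = TRUE)) +
    lkj_term(params$obs_corr) + lkj_term(params$evo_corr)
}

# log of the LKJ(v) normalizing constant for dimension d, via the C-vine
# representation: each canonical partial correlation in column j is an
# independent rescaled Beta(b_j, b_j) on (-1, 1) with b_j = v + (d - 1 - j)/2.
lkj_log_norm_const <- function(d, v) {
  lc <- 0
  for (j in seq_len(d - 1)) {
    b <- v + (d - 1 - j) / 2
    lc <- lc - (d - j) * ((2 * b - 1) * log(2) + lbeta(b, b))
  }
  lc
}

#' Sample correlation matrices from the LKJ distribution
#'
#' C-vine construction: canonical partial correlations drawn from rescaled
#' Beta distributions, assembled through the Cholesky factor.  For `v = 1`
#' and dimension `d`, each off-diagonal entry's marginal is a
#' Beta(`d/2`, `d/2`) rescaled to \eqn{(-1, 1)}.
#'
#' Uses R's RNG stream: seed with [set.seed()].
#'
#' @param d matrix dimension (>= 2).
#' @param v LKJ shape (> 0).
#' @param n number of draws.
#' @return a `d x d x n` array of correlation matrices.
#' @export
sample_prior_corr <- function(d, v = 1, n = 1L) {
  stopifnot(d >= 2, v > 0, n >= 1)
  out <- array(NA_real_, c(d, d, n))
  m <- d * (d - 1) / 2
  for (k in seq_len(n)) {
    z <- matrix(0, d, d)
    for (j in seq_len(d - 1)) {
      b <- v + (d - 1 - j) / 2
      nz <- d - j
      z[(j + 1):d, j] <- 2 * stats::rbeta(nz, b, b) - 1
    }
    out[, , k] <- corr_from_cpc(z)
  }
  out
}

# build a correlation matrix from lower-triangular canonical partial
# correlations z (Cholesky construction)
corr_from_cpc <- function(z) {
  d <- nrow(z)
  X <- matrix(0, d, d)
  X[1, 1] <- 1
  for (i in 2:d) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      X[i, j] <- z[i, j] * sqrt(rem)
      rem <- rem * (1 - z[i, j]^2)
    }
    X[i, i] <- sqrt(rem)
  }
  R <- X %*% t(X)
  diag(R) <- 1
  0.5 * (R + t(R))
}

# recover canonical partial correlations from a correlation matrix
cpc_from_corr <- function(R) {
  d <- nrow(R)
  X <- t(chol(R))
  z <- matrix(0, d, d)
  for (i in 2:d) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      z[i, j] <- X[i, j] / sqrt(rem)
      rem <- rem * (1 - z[i, j]^2)
    }
  }
  z
}
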