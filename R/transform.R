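# Unconstrained parameterization of the covariance hyperparameters.
#
# u = (log sigma_1..C, log gamma_1..C, y_eps, y_delta) where each y block has
# C(C-1)/2 entries ordered column-major over the lower triangle.  A
# correlation matrix is parameterized through canonical partial correlations
# z = tanh(y) assembled into a Cholesky factor; the log-Jacobian of y -> Omega
# for the entry in column j is (1 + (C - 1 - j)/2) * log(1 - z^2)
# (the leading 1 from tanh, the rest from the CPC -> Omega map).

n_unconstrained <- function(C) 2L * C + C * (C - 1L)

lower_tri_pairs <- function(C) {
  idx <- which(lower.tri(matrix(0, C, C)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# y (vector) -> list(R = correlation matrix, log_jac)
corr_constrain <- function(y, C) {
  z <- tanh(y)
  pairs <- lower_tri_pairs(C)
  zm <- matrix(0, C, C)
  zm[pairs] <- z
  lj <- sum((1 + (C - 1 - pairs[, "col"]) / 2) * log1p(-z^2))
  list(R = corr_from_cpc(zm), log_jac = lj)
}

corr_unconstrain <- function(R) {
  C <- nrow(R)
  z <- cpc_from_corr(R)
  atanh(z[lower_tri_pairs(C)])
}

#' Map an unconstrained parameter vector to covariance hyperparameters
#'
#' Inverse of [unconstrain_params()].  Also returns the log-Jacobian of the
#' map (log-determinant of `d(constrained)/d(unconstrained)`), the term that
#' must be added to a log density on the constrained scale to obtain the
#' matching density on the unconstrained scale.
#'
#' @param u numeric vector of length `2C + C(C-1)`.
#' @param n_series number of series `C`.
#' @return a list with elements `params` ([cov_params()]) and `log_jac`.
#' @export
constrain_params <- function(u, n_series) {
  C <- as.integer(n_series)
  m <- C * (C - 1L) / 2L
  if (length(u) != n_unconstrained(C))
    stop(sprintf("u must have length %d for %d series", n_unconstrained(C), C))
  sig <- exp(u[seq_len(C)])
  gam <- exp(u[C + seq_len(C)])
  ce <- corr_constrain(u[2L * C + seq_len(m)], C)
  cd <- corr_constrain(u[2L * C + m + seq_len(m)], C)
  list(params = cov_params(sig, ce$R, gam, cd$R),
       log_jac = sum(u[seq_len(2L * C)]) + ce$log_jac + cd$log_jac)
}

#' Map covariance hyperparameters to the unconstrained scale
#'
#' @param params a [cov_params()] object with strictly positive SDs and
#'   positive definite correlation matrices.
#' @return numeric vector of length `2C + C(C-1)`.
#' @export
unconstrain_params <- function(params) {
  stopifnot(inherits(params, "sutse_covparams"))
  c(log(params$obs_sd), log(params$evo_sd),
    corr_unconstrain(params$obs_corr), corr_unconstrain(params$evo_corr))
}

#' Unnormalized log posterior of the hyperparameters (states marginalized)
#'
#' Evaluates, on the unconstrained scale, the log of
#' \eqn{p(\Sigma_\epsilon, \Sigma_\delta \mid Y)}: the Kalman-filter log
#' marginal likelihood plus the log prior plus the transform log-Jacobian.
#' Numerical singularity of the filter (or an invalid parameter point) is
#' reported as `-Inf` rather than an error so samplers can reject the state.
#'
#' @param u unconstrained parameter vector.
#' @param data a [observed_series()] object.
#' @param spec a [build_model()] specification.
#' @param priors a [prior_spec()] object.
#' @return scalar log density (possibly `-Inf`).
#' @export
log_posterior_hyper <- function(u, data, spec, priors = prior_spec()) {
  if (any(!is.finite(u))) return(-Inf)
  cp <- tryCatch(constrain_params(u, spec$n_series), error = function(e) NULL)
  if (is.null(cp)) return(-Inf)
  ll <- tryCatch(
    kalman_loglik(spec, cp$params, data, init_mean = 0,
                  init_var = priors$init_state_var),
    error = function(e) -Inf)
  if (!is.finite(ll)) return(-Inf)
  lp <- tryCatch(log_prior(cp$params, priors), error = function(e) -Inf)
  val <- ll + lp + cp$log_jac
  if (!is.finite(val)) -Inf else val
}
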