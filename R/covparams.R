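#' Covariance hyperparameters of a SUTSE DLM
#'
#' Bundles the standard deviations and correlation matrices of the
#' observation errors and slope evolutions.  The implied covariance matrices
#' are \eqn{\Sigma_\epsilon = D_\sigma \Omega_\epsilon D_\sigma} and
#' \eqn{\Sigma_{\tilde\delta} = D_\gamma \Omega_\delta D_\gamma}; the state
#' evolution covariance \eqn{\Sigma_\delta = R \Sigma_{\tilde\delta} R^\top}
#' has rank at most \eqn{C} because noise enters only the slopes.
#'
#' @param obs_sd length-`C` vector of observation-error standard deviations
#'   \eqn{\sigma} (log-count units).
#' @param obs_corr `C x C` observation-error correlation matrix
#'   \eqn{\Omega_\epsilon}.
#' @param evo_sd length-`C` vector of slope-innovation standard deviations
#'   \eqn{\gamma} (log-count units per month per month).
#' @param evo_corr `C x C` evolution correlation matrix \eqn{\Omega_\delta}.
#' @return an object of class `sutse_covparams`.
#' @examples
#' cov_params(obs_sd = c(0.05, 0.08), obs_corr = diag(2),
#'            evo_sd = c(0.01, 0.01),
#'            evo_corr = matrix(c(1, 0.5, 0.5, 1), 2))
#' @export
cov_params <- function(obs_sd, obs_corr, evo_sd, evo_corr) {
  C <- length(obs_sd)
  check_corr <- function(R, what) {
    if (!is.matrix(R) || nrow(R) != C || ncol(R) != C)
      stop(sprintf("%s must be a %d x %d matrix", what, C, C))
    if (max(abs(R - t(R))) > 1e-8) stop(sprintf("%s must be symmetric", what))
    if (max(abs(diag(R) - 1)) > 1e-8) stop(sprintf("%s must have unit diagonal", what))
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(sprintf("%s must be positive semidefinite", what))
  }
  if (length(evo_sd) != C) stop("obs_sd and evo_sd must have equal length")
  if (any(obs_sd < 0) || any(evo_sd < 0)) stop("standard deviations must be >= 0")
  check_corr(obs_corr, "obs_corr")
  check_corr(evo_corr, "evo_corr")
  structure(list(obs_sd = as.numeric(obs_sd), obs_corr = obs_corr,
                 evo_sd = as.numeric(evo_sd), evo_corr = evo_corr),
            class = "sutse_covparams")
}

#' @rdname cov_params
#' @param params a `sutse_covparams` object.
#' @return `sigma_eps()`: the observation-error covariance
#'   \eqn{\Sigma_\epsilon}.
#' @export
sigma_eps <- function(params) {
  D <- diag(params$obs_sd, nrow = length(params$obs_sd))
  D %*% params$obs_corr %*% D
}

#' @rdname cov_params
#' @return `sigma_delta_tilde()`: the slope-innovation covariance
#'   \eqn{\Sigma_{\tilde\delta}}.
#' @export
sigma_delta_tilde <- function(params) {
  D <- diag(params$evo_sd, nrow = length(params$evo_sd))
  D %*% params$evo_corr %*% D
}

#' @rdname cov_params
#' @param spec a [build_model()] specification.
#' @return `sigma_delta()`: the (rank-deficient) state evolution covariance
#'   \eqn{R \Sigma_{\tilde\delta} R^\top}.
#' @export
sigma_delta <- function(params, spec) {
  R <- spec$evo_selection
  R %*% sigma_delta_tilde(params) %*% t(R)
}

#' @export
print.sutse_covparams <- function(x, ...) {
  cat(sprintf("SUTSE covariance parameters (%d series)\n", length(x$obs_sd)))
  cat("  obs sd:", signif(x$obs_sd, 4), "\n")
  cat("  evo sd:", signif(x$evo_sd, 4), "\n")
  invisible(x)
}
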