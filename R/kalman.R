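#' Kalman filter for a SUTSE DLM
#'
#' Exact Gaussian forward filter with the rank-deficient evolution covariance
#' \eqn{\Sigma_\delta = R \Sigma_{\tilde\delta} R^\top}.  Uses a Joseph-form
#' covariance update with explicit symmetrization each step and solves the
#' innovation system through its Cholesky factor.  Rows (or single entries)
#' of the data that are `NA` are skipped in the measurement update but
#' propagate through the prediction.
#'
#' @param spec a [build_model()] specification.
#' @param params a [cov_params()] object.
#' @param data a [observed_series()] object with `n_series` columns.
#' @param init_mean prior mean of the initial state \eqn{\theta_0} (scalar,
#'   recycled, or length-`p` vector).
#' @param init_var prior variance of \eqn{\theta_0}: a scalar \eqn{\kappa}
#'   (meaning \eqn{\kappa I}) or a `p x p` PSD matrix.  The default
#'   \eqn{10^7} is a diffuse proper prior.
#' @return an object of class `sutse_filter`: per-time predicted and
#'   filtered moments (`pred_mean`, `pred_cov`, `filt_mean`, `filt_cov`;
#'   means are `p x T`, covariances `p x p x T`), the initial moments, and
#'   `loglik`, the accumulated log marginal likelihood
#'   \eqn{\sum_t \log N(Y_t; F a_t, F R_t F^\top + \Sigma_\epsilon)}.
#' @export
kalman_filter <- function(spec, params, data, init_mean = 0, init_var = 1e7) {
  km <- kalman_inputs(spec, params, data, init_mean, init_var)
  out <- kf_filter_cpp(km$y, km$F, km$G, km$W, km$V, km$m0, km$C0)
  structure(c(out, list(init_mean = km$m0, init_cov = km$C0,
                        spec = spec, n_time = nrow(km$y))),
            class = "sutse_filter")
}

#' Log marginal likelihood only (no stored moments)
#'
#' @inheritParams kalman_filter
#' @return the log marginal likelihood (scalar).
#' @export
kalman_loglik <- function(spec, params, data, init_mean = 0, init_var = 1e7) {
  km <- kalman_inputs(spec, params, data, init_mean, init_var)
  kf_loglik_cpp(km$y, km$F, km$G, km$W, km$V, km$m0, km$C0)
}

# validate and assemble the matrices the C++ core consumes
kalman_inputs <- function(spec, params, data, init_mean, init_var) {
  stopifnot(inherits(spec, "sutse_model"), inherits(params, "sutse_covparams"))
  y <- if (inherits(data, "sutse_series")) data$log_counts else as.matrix(data)
  C <- spec$n_series; p <- spec$state_dim
  if (ncol(y) != C)
    stop(sprintf("data has %d columns but model expects %d series", ncol(y), C))
  if (length(params$obs_sd) != C)
    stop("params dimension does not match model n_series")
  m0 <- rep_len(as.numeric(init_mean), p)
  if (is.matrix(init_var)) {
    if (nrow(init_var) != p || ncol(init_var) != p)
      stop(sprintf("init_var matrix must be %d x %d", p, p))
    C0 <- init_var
  } else {
    if (length(init_var) != 1 || init_var < 0) stop("init_var must be a PSD scalar or matrix")
    C0 <- diag(as.numeric(init_var), p)
  }
  R <- spec$evo_selection
  list(y = y, F = spec$obs_matrix, G = spec$transition,
       W = R %*% sigma_delta_tilde(params) %*% t(R),
       V = sigma_eps(params), m0 = m0, C0 = C0)
}

#' Fixed-interval (RTS) smoother
#'
#' Posterior moments of every state \eqn{\theta_t}, \eqn{t = 0..T}, given all
#' observations and the covariance hyperparameters.
#'
#' @inheritParams kalman_filter
#' @return a list with `mean` (`p x (T+1)`, column 1 = \eqn{\theta_0}),
#'   `cov` (`p x p x (T+1)`), and the filter's `loglik`.
#' @export
kalman_smooth <- function(spec, params, data, init_mean = 0, init_var = 1e7) {
  f <- kalman_filter(spec, params, data, init_mean, init_var)
  sm <- rts_smooth_cpp(f$pred_mean, f$pred_cov, f$filt_mean, f$filt_cov,
                       spec$transition, f$init_mean, f$init_cov)
  list(mean = sm$mean, cov = sm$cov, loglik = f$loglik)
}

#' Forward-filtering backward-sampling (FFBS)
#'
#' Draws exact joint samples from
#' \eqn{p(\theta_{0:T} \mid Y, \Sigma_\epsilon, \Sigma_\delta)}.  Because the
#' evolution covariance is singular (noise enters only the slopes), the
#' backward pass samples the C-dimensional slope disturbance
#' \eqn{\tilde\delta_t} conditionally and reconstructs the remaining,
#' deterministic coordinates exactly, rather than inverting the rank-deficient
#' \eqn{p \times p} evolution covariance.
#'
#' Uses R's RNG stream: seed with [set.seed()] for reproducibility.
#'
#' @param filter_result a [kalman_filter()] result computed with the same
#'   `spec`/`params`/data.
#' @param spec,params the specification and hyperparameters used for the
#'   filter.
#' @param n_draws number of independent trajectories.
#' @return an array `n_draws x (T+1) x p`; `[, 1, ]` is \eqn{\theta_0}.
#' @export
ffbs <- function(filter_result, spec, params, n_draws = 1L) {
  stopifnot(inherits(filter_result, "sutse_filter"),
            inherits(spec, "sutse_model"))
  if (nrow(filter_result$filt_mean) != spec$state_dim)
    stop("filter result does not match model state dimension")
  if (length(params$obs_sd) != spec$n_series)
    stop("params dimension does not match model n_series")
  G <- spec$transition
  draws <- ffbs_cpp(filter_result$pred_mean, filter_result$pred_cov,
                    filter_result$filt_mean, filter_result$filt_cov,
                    G, solve(G), spec$evo_selection,
                    sigma_delta_tilde(params),
                    filter_result$init_mean, filter_result$init_cov,
                    as.integer(n_draws))
  aperm(draws, c(3L, 2L, 1L))  # n_draws x (T+1) x p
}

#' Export filter or smoother moments as a long-format data frame
#'
#' One row per (time, state coordinate) with posterior mean and standard
#' deviation; suitable for writing to CSV.
#'
#' @param mean `p x n` matrix of means.
#' @param cov `p x p x n` array of covariances.
#' @param spec the model specification (for coordinate labels).
#' @param t0 time index of the first column (0 for smoother output).
#' @return a data frame with columns `time`, `series`, `role`, `mean`, `sd`.
#' @export
state_moments_table <- function(mean, cov, spec, t0 = 0L) {
  n <- ncol(mean)
  sds <- vapply(seq_len(n), function(i) sqrt(pmax(diag(cov[, , i]), 0)),
                numeric(nrow(mean)))
  data.frame(time = rep(t0 + seq_len(n) - 1L, each = nrow(mean)),
             series = rep(spec$coord_labels$series, n),
             role = rep(spec$coord_labels$role, n),
             mean = as.vector(mean), sd = as.vector(sds))
}
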