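#' Simulation configuration
#'
#' Bundles a model specification, covariance hyperparameters, an initial
#' state, and a horizon for forward simulation of the SUTSE DLM.
#'
#' @param spec a [build_model()] specification.
#' @param params a [cov_params()] object.
#' @param init_state length-`p` initial state \eqn{\theta_0} (levels,
#'   slopes, seasonal coordinates per series).
#' @param n_months horizon `T` (>= 2).
#' @param seed integer seed (stored; used by [simulate_sutse()]).
#' @param start_month first month label, `"YYYY-MM"`.
#' @return an object of class `sutse_sim_config`.
#' @export
sim_config <- function(spec, params, init_state, n_months, seed = 1L,
                       start_month = "2007-01") {
  stopifnot(inherits(spec, "sutse_model"), inherits(params, "sutse_covparams"))
  if (length(init_state) != spec$state_dim)
    stop(sprintf("init_state must have length %d", spec$state_dim))
  if (n_months < 2) stop("n_months must be >= 2")
  if (length(params$obs_sd) != spec$n_series)
    stop("params dimension does not match spec")
  structure(list(spec = spec, params = params,
                 init_state = as.numeric(init_state),
                 n_months = as.integer(n_months), seed = as.integer(seed),
                 start_month = start_month),
            class = "sutse_sim_config")
}

#' Simulate from the SUTSE DLM generative model
#'
#' Runs the state equation \eqn{\theta_t = G\theta_{t-1} + R\tilde\delta_t},
#' \eqn{\tilde\delta_t \sim N(0, \Sigma_{\tilde\delta})}, and observation
#' equation \eqn{Y_t = F\theta_t + \epsilon_t},
#' \eqn{\epsilon_t \sim N(0, \Sigma_\epsilon)}, forward for `n_months`
#' steps.  Counts are `round(exp(Y))` clipped below at 1: the model is
#' Gaussian on the log scale, so rounding (rather than Poisson sampling)
#' keeps generator and likelihood consistent.
#'
#' @param config a [sim_config()] object.
#' @param series_names optional series labels.
#' @return a list with `log_series` (a [observed_series()] holding the
#'   Gaussian draws \eqn{Y}), `counts` (`T x C` integer matrix), and
#'   `true_states` (`(T+1) x p` matrix, row 1 = \eqn{\theta_0}).
#' @export
simulate_sutse <- function(config, series_names = NULL) {
  stopifnot(inherits(config, "sutse_sim_config"))
  set.seed(config$seed)
  spec <- config$spec
  C <- spec$n_series; p <- spec$state_dim; T_ <- config$n_months
  G <- spec$transition; F_ <- spec$obs_matrix; R <- spec$evo_selection
  Ld <- chol_psd(sigma_delta_tilde(config$params))
  Le <- chol_psd(sigma_eps(config$params))
  theta <- matrix(NA_real_, T_ + 1L, p)
  theta[1L, ] <- config$init_state
  Y <- matrix(NA_real_, T_, C)
  for (t in seq_len(T_)) {
    delta <- drop(Ld %*% stats::rnorm(C))
    th <- drop(G %*% theta[t, ]) + drop(R %*% delta)
    theta[t + 1L, ] <- th
    Y[t, ] <- drop(F_ %*% th) + drop(Le %*% stats::rnorm(C))
  }
  counts <- matrix(pmax(1, round(exp(Y))), T_, C)
  if (is.null(series_names)) series_names <- paste0("series_", seq_len(C))
  colnames(counts) <- series_names
  list(log_series = observed_series(Y, months = month_seq(config$start_month, T_),
                                    series_names = series_names),
       counts = counts,
       true_states = theta)
}

# lower-triangular square root tolerating PSD (zero-variance) matrices
chol_psd <- function(S) {
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Preset emulating monthly big-city incident-report counts
#'
#' Six series over 120 months with four seasonal harmonics (state dimension
#' 60), initial levels placed so simulated monthly counts lie predominantly
#' in the 500-5000 band, heterogeneous seasonal amplitudes (three strongly
#' seasonal series, three weak), mild negative slopes, correlated lognormal
#' observation noise, and a mix of positive, negative, and zero evolution
#' correlations between the slope innovations.
#'
#' @param seed integer seed for the resulting configuration.
#' @return a [sim_config()] object.
#' @export
chicago_like_preset <- function(seed = 1L) {
  spec <- build_model(n_series = 6L, n_harmonics = 4L, period = 12L)
  obs_sd <- c(0.045, 0.05, 0.035, 0.07, 0.055, 0.06)
  obs_corr <- 0.35 + diag(0.65, 6)  # uniform moderate same-month co-deviation
  evo_sd <- c(0.0007, 0.0007, 0.0006, 0.0010, 0.0007, 0.0008)
  evo_corr <- diag(6)
  evo_corr[1, 2] <- evo_corr[2, 1] <- 0.7    # co-moving trends
  evo_corr[1, 5] <- evo_corr[5, 1] <- 0.5
  evo_corr[2, 5] <- evo_corr[5, 2] <- 0.5
  evo_corr[3, 4] <- evo_corr[4, 3] <- -0.5   # opposed trends
  evo_corr[4, 6] <- evo_corr[6, 4] <- 0.6    # remaining pairs uncorrelated
  params <- cov_params(obs_sd, obs_corr, evo_sd, evo_corr)

  levels <- log(c(1500, 1200, 2200, 2800, 1400, 950))
  slopes <- c(-0.002, -0.001, -0.0015, -0.004, -0.002, -0.001)
  # (harm1, conj1, ..., harm4, conj4); strong annual cycle for series 1-3
  seas <- list(c(0.18, 0.06, 0.03, 0.01, 0.01, 0.00, 0.00, 0.00),
               c(0.15, -0.05, 0.04, 0.01, 0.00, 0.01, 0.00, 0.00),
               c(0.12, 0.04, 0.02, 0.00, 0.01, 0.00, 0.00, 0.00),
               c(0.03, 0.01, 0.01, 0.00, 0.00, 0.00, 0.00, 0.00),
               c(0.04, -0.02, 0.00, 0.01, 0.00, 0.00, 0.00, 0.00),
               c(0.02, 0.01, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))
  init <- unlist(lapply(1:6, function(cc) c(levels[cc], slopes[cc], seas[[cc]])))
  sim_config(spec, params, init, n_months = 120L, seed = seed)
}

#' Randomized small fixture for testing
#'
#' Draws stable covariance hyperparameters (half-Cauchy-derived SDs
#' truncated to ranges where a 120-month trajectory stays well-behaved, LKJ
#' correlation matrices) and a modest initial state; intended for test
#' suites and pipeline smoke runs.
#'
#' @param C number of series (<= 4).
#' @param T_ number of months (<= 200).
#' @param q number of harmonics.
#' @param seed integer seed.
#' @return a [sim_config()] object.
#' @export
make_fixture <- function(C, T_, q = 1L, seed = 1L) {
  if (C > 4 || T_ > 200) stop("make_fixture is for small instances (C <= 4, T <= 200)")
  spec <- build_model(C, q)
  set.seed(seed)
  trunc_hc <- function(n, lo, hi) {
    x <- abs(stats::rcauchy(n))
    while (any(x < lo | x > hi))
      x[x < lo | x > hi] <- abs(stats::rcauchy(sum(x < lo | x > hi)))
    x
  }
  obs_sd <- trunc_hc(C, 0.02, 0.15)
  evo_sd <- trunc_hc(C, 0.0005, 0.004)
  corr_draw <- function() {
    R <- sample_prior_corr(max(C, 2), 1, 1)[, , 1]
    R[seq_len(C), seq_len(C), drop = FALSE]
  }
  params <- cov_params(obs_sd, corr_draw(), evo_sd, corr_draw())
  n_seas <- spec$block_size - 2L
  init <- unlist(lapply(seq_len(C), function(cc) {
    seas <- if (n_seas > 0) stats::rnorm(n_seas, 0, 0.08 / seq_len(n_seas)) else numeric(0)
    c(stats::rnorm(1, 7, 0.5), stats::runif(1, -0.004, 0.004), seas)
  }))
  sim_config(spec, params, init, n_months = T_, seed = seed + 1L)
}
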