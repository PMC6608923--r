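# Brute-force joint-Gaussian oracle for the SUTSE DLM.
#
# Builds the exact linear map from the independent Gaussian inputs
# (theta_0, deltatilde_{1:T}, eps_{1:T}) to the stacked observation vector,
# so likelihoods, smoother moments, and missing-data marginals can be
# computed by direct multivariate-normal algebra, fully independently of the
# Kalman recursions under test.

joint_gaussian_oracle <- function(spec, params, T_, init_var) {
  C <- spec$n_series; p <- spec$state_dim
  G <- spec$transition; F_ <- spec$obs_matrix; R <- spec$evo_selection
  Sd <- sigma_delta_tilde(params); Se <- sigma_eps(params)
  nin <- p + 2 * C * T_
  Svars <- matrix(0, nin, nin)
  Svars[1:p, 1:p] <- diag(init_var, p)
  for (t in 1:T_) {
    i <- p + (t - 1) * C + seq_len(C)
    Svars[i, i] <- Sd
    j <- p + C * T_ + (t - 1) * C + seq_len(C)
    Svars[j, j] <- Se
  }
  Gp <- vector("list", T_ + 1)
  Gp[[1]] <- diag(p)
  for (t in 1:T_) Gp[[t + 1]] <- G %*% Gp[[t]]
  # observation map: rows are Y_1, ..., Y_T stacked
  A <- matrix(0, C * T_, nin)
  # state map for every theta_t, t = 0..T (rows stacked by t)
  B <- matrix(0, p * (T_ + 1), nin)
  B[1:p, 1:p] <- diag(p)
  for (t in 1:T_) {
    obs_rows <- (t - 1) * C + seq_len(C)
    st_rows <- t * p + seq_len(p)
    B[st_rows, 1:p] <- Gp[[t + 1]]
    for (s in 1:t)
      B[st_rows, p + (s - 1) * C + seq_len(C)] <- Gp[[t - s + 1]] %*% R
    A[obs_rows, ] <- F_ %*% B[st_rows, , drop = FALSE]
    A[obs_rows, p + C * T_ + (t - 1) * C + seq_len(C)] <- diag(C)
  }
  list(SY = A %*% Svars %*% t(A),            # Cov(vec Y)
       cross = B %*% Svars %*% t(A),         # Cov(theta_stack, vec Y)
       Sstate = B %*% Svars %*% t(B),        # Cov(theta_stack)
       C = C, p = p, T_ = T_)
}

# log density of the observed (finite) entries of y (T x C, row-major time)
oracle_loglik <- function(orc, y) {
  v <- as.vector(t(y))
  obs <- which(is.finite(v))
  S <- orc$SY[obs, obs, drop = FALSE]
  L <- chol(S)
  z <- backsolve(L, v[obs], transpose = TRUE)
  -0.5 * length(obs) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# conditional mean / covariance of theta_t (t in 0..T) given observed y
oracle_smooth <- function(orc, y, t) {
  v <- as.vector(t(y))
  obs <- which(is.finite(v))
  rows <- t * orc$p + seq_len(orc$p)
  S <- orc$SY[obs, obs, drop = FALSE]
  Cx <- orc$cross[rows, obs, drop = FALSE]
  mu <- drop(Cx %*% solve(S, v[obs]))
  Sig <- orc$Sstate[rows, rows] - Cx %*% solve(S, t(Cx))
  list(mean = mu, cov = Sig)
}

random_pd_corr <- function(C) {
  A <- matrix(stats::rnorm(C * C), C)
  S <- crossprod(A) + diag(C) * 0.5
  stats::cov2cor(S)
}

random_cov_params <- function(C, sd_lo = 0.1, sd_hi = 0.6) {
  cov_params(stats::runif(C, sd_lo, sd_hi), random_pd_corr(C),
             stats::runif(C, sd_lo / 4, sd_hi / 4), random_pd_corr(C))
}
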