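# All oracle comparisons here are against the brute-force joint-Gaussian
# construction in helper-oracles.R, never against the recursions themselves.

test_that("iid limit: filter likelihood reduces to standard-normal density", {
  spec <- build_model(1, 0)
  params <- cov_params(1, matrix(1), 0, matrix(1))
  ll <- kalman_loglik(spec, params, matrix(c(0, 0), 2, 1),
                      init_mean = 0, init_var = 0)
  expect_equal(ll, 2 * log(1 / sqrt(2 * pi)), tolerance = 1e-9)
})

test_that("filter log marginal likelihood matches the joint-Gaussian oracle", {
  spec <- build_model(2, 1)
  set.seed(101)
  for (rep in 1:3) {
    params <- random_cov_params(2)
    y <- matrix(rnorm(12, 7, 1), 6, 2)
    for (kap in c(10, 1e7)) {
      orc <- joint_gaussian_oracle(spec, params, 6, kap)
      ll <- kalman_loglik(spec, params, observed_series(y), 0, kap)
      expect_equal(ll, oracle_loglik(orc, y), tolerance = 1e-6)
    }
  }
})

test_that("missing months marginalize exactly (full and partial rows)", {
  spec <- build_model(2, 1)
  set.seed(7)
  params <- random_cov_params(2)
  y <- matrix(rnorm(12, 7, 1), 6, 2)
  y[3, ] <- NA          # whole month missing
  y[5, 2] <- NA         # single entry missing
  orc <- joint_gaussian_oracle(spec, params, 6, 1e7)
  ll <- kalman_loglik(spec, params, observed_series(y), 0, 1e7)
  expect_equal(ll, oracle_loglik(orc, y), tolerance = 1e-6)
})

test_that("smoother moments equal joint-Gaussian conditioning", {
  spec <- build_model(2, 1)
  set.seed(33)
  params <- random_cov_params(2)
  y <- matrix(rnorm(12, 7, 1), 6, 2)
  orc <- joint_gaussian_oracle(spec, params, 6, 100)
  sm <- kalman_smooth(spec, params, observed_series(y), 0, 100)
  for (t in c(0, 1, 3, 6)) {
    os <- oracle_smooth(orc, y, t)
    expect_equal(sm$mean[, t + 1], os$mean, tolerance = 1e-6)
    expect_equal(sm$cov[, , t + 1], os$cov, tolerance = 1e-6)
  }
})

test_that("smoothed variances never exceed filtered variances", {
  spec <- build_model(2, 2)
  set.seed(5)
  params <- random_cov_params(2)
  y <- matrix(rnorm(40, 7, 1), 20, 2)
  f <- kalman_filter(spec, params, observed_series(y))
  sm <- kalman_smooth(spec, params, observed_series(y))
  for (t in 1:20)
    expect_true(all(diag(sm$cov[, , t + 1]) <=
                      diag(f$filt_cov[, , t]) + 1e-10))
})

test_that("single-observation smoother equals the filter", {
  spec <- build_model(2, 0)
  params <- random_cov_params(2)
  y <- matrix(c(7.1, 6.9), 1, 2)
  # T = 1 via a 2-row series with the second row missing
  y2 <- rbind(y, c(NA, NA))
  f <- kalman_filter(spec, params, observed_series(y2))
  sm <- kalman_smooth(spec, params, observed_series(y2))
  expect_equal(sm$mean[, 2], f$filt_mean[, 1], tolerance = 1e-9)
  expect_equal(sm$cov[, , 2], f$filt_cov[, , 1], tolerance = 1e-9)
})

test_that("noiseless limit reproduces perfectly linear data", {
  spec <- build_model(1, 0)
  params <- cov_params(1e-4, matrix(1), 0, matrix(1))
  y <- matrix(5 + 0.3 * (1:10), 10, 1)
  sm <- kalman_smooth(spec, params, observed_series(y))
  expect_equal(sm$mean[1, -1], drop(y), tolerance = 1e-6)
  expect_equal(unname(sm$mean[2, -1]), rep(0.3, 10), tolerance = 1e-6)
})

test_that("likelihood is invariant under series permutation", {
  spec <- build_model(3, 1)
  set.seed(11)
  params <- random_cov_params(3)
  y <- matrix(rnorm(24, 7, 1), 8, 3)
  perm <- c(3, 1, 2)
  pperm <- cov_params(params$obs_sd[perm], params$obs_corr[perm, perm],
                      params$evo_sd[perm], params$evo_corr[perm, perm])
  ll1 <- kalman_loglik(spec, params, observed_series(y), 0, 100)
  ll2 <- kalman_loglik(spec, pperm, observed_series(y[, perm]), 0, 100)
  expect_equal(ll1, ll2, tolerance = 1e-8)
  # under the diffuse 1e7 prior, agreement is limited by the ~7 decimal
  # digits the ill-conditioned first updates consume
  lld1 <- kalman_loglik(spec, params, observed_series(y))
  lld2 <- kalman_loglik(spec, pperm, observed_series(y[, perm]))
  expect_equal(lld1, lld2, tolerance = 1e-4)
})

test_that("doubling the diffuse prior variance shifts the likelihood by a
           parameter-free constant and leaves the smoother unchanged", {
  # the marginal likelihood necessarily scales with the diffuse prior
  # (each prior-dominated state dimension contributes -log(2)/2 to the
  # shift); diffuseness means that shift is constant in the parameters, so
  # posteriors and state estimates are unaffected
  cfg <- chicago_like_preset(seed = 3)
  sim <- simulate_sutse(cfg)
  spec <- build_model(6, 4)
  other <- cov_params(cfg$params$obs_sd * 1.5, cfg$params$obs_corr,
                      cfg$params$evo_sd * 0.5, diag(6))
  shift1 <- kalman_loglik(spec, cfg$params, sim$log_series, 0, 2e7) -
    kalman_loglik(spec, cfg$params, sim$log_series, 0, 1e7)
  shift2 <- kalman_loglik(spec, other, sim$log_series, 0, 2e7) -
    kalman_loglik(spec, other, sim$log_series, 0, 1e7)
  expect_lt(abs(shift1 - shift2), 0.01)
  sm1 <- kalman_smooth(spec, cfg$params, sim$log_series, 0, 1e7)
  sm2 <- kalman_smooth(spec, cfg$params, sim$log_series, 0, 2e7)
  expect_lt(max(abs(sm1$mean - sm2$mean)), 1e-5)
})

test_that("singular innovation covariance reports the offending time index", {
  spec <- build_model(1, 0)
  params <- cov_params(0, matrix(1), 0, matrix(1))
  expect_error(
    kalman_loglik(spec, params, matrix(c(1, 2), 2, 1), 0, 0),
    "positive definite at time 1")
})

test_that("FFBS draws match smoother moments and respect degenerate evolution", {
  spec <- build_model(2, 1)
  set.seed(19)
  params <- random_cov_params(2)
  y <- matrix(rnorm(12, 7, 0.5), 6, 2)
  data <- observed_series(y)
  f <- kalman_filter(spec, params, data)
  sm <- kalman_smooth(spec, params, data)
  n <- 4000
  set.seed(1)
  dr <- ffbs(f, spec, params, n)
  for (t in c(1, 4, 7)) {
    for (j in c(1, 2, 5)) {
      x <- dr[, t, j]
      se_m <- sd(x) / sqrt(n)
      expect_lt(abs(mean(x) - sm$mean[j, t]), 4 * se_m)
      se_v <- sd((x - mean(x))^2) / sqrt(n)
      expect_lt(abs(var(x) - sm$cov[j, j, t]), 4 * se_v)
    }
  }
  # gamma = 0: slopes exactly constant, level second differences exactly 0
  p0 <- cov_params(params$obs_sd, params$obs_corr, c(0, 0), diag(2))
  f0 <- kalman_filter(spec, p0, data)
  set.seed(2)
  d0 <- ffbs(f0, spec, p0, 10)
  for (j in c(2, 6))  # slope coordinates of both series
    expect_lt(max(apply(d0[, , j], 1, function(s) diff(range(s)))), 1e-10)
  lev <- d0[, , 1]
  expect_lt(max(abs(apply(lev, 1, function(l) diff(l, differences = 2)))), 1e-10)
})

test_that("FFBS is deterministic under a fixed seed", {
  spec <- build_model(2, 0)
  params <- random_cov_params(2)
  data <- observed_series(matrix(rnorm(10, 7, 1), 5, 2))
  f <- kalman_filter(spec, params, data)
  set.seed(99); a <- ffbs(f, spec, params, 4)
  set.seed(99); b <- ffbs(f, spec, params, 4)
  expect_identical(a, b)
})

test_that("state moments export to a labeled long table", {
  spec <- build_model(2, 1)
  params <- random_cov_params(2)
  data <- observed_series(matrix(rnorm(10, 7, 1), 5, 2))
  sm <- kalman_smooth(spec, params, data)
  tab <- state_moments_table(sm$mean, sm$cov, spec, t0 = 0L)
  expect_equal(nrow(tab), 6 * spec$state_dim)
  expect_setequal(unique(tab$role),
                  c("level", "slope", "harmonic_1", "conjugate_1"))
  expect_true(all(tab$sd >= 0))
})
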