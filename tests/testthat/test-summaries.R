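test_that("prob_positive counts strictly positive draws", {
  expect_equal(prob_positive(c(0.5, 0.2, -0.1, 0.3)), 0.75)
  expect_equal(prob_positive(c(-1, -0.2)), 0)
  expect_equal(prob_positive(c(0, 0, 1)), 1 / 3)  # zeros are not positive
  set.seed(3)
  x <- rnorm(12000, 0.1, 1)
  expect_equal(prob_positive(x), sum(x > 0) / 12000)
  expect_error(prob_positive(numeric(0)), "non-empty")
})

test_that("one-sided lower bound is the ceiling order statistic", {
  expect_equal(one_sided_lower(seq(0.01, 1, by = 0.01), 0.95), 0.05)
  expect_equal(one_sided_lower(rep(0.3, 7)), 0.3)
  set.seed(9)
  x <- rnorm(1234)
  expect_equal(one_sided_lower(x, 0.9), sort(x)[ceiling(0.1 * 1234)])
  expect_error(one_sided_lower(x, 1), "level")
  expect_error(one_sided_lower(x, 0), "level")
})

test_that("partial correlations: known closed forms and 2x2 involution", {
  expect_equal(partial_correlations(diag(3)), diag(3))
  for (rho in seq(-0.9, 0.9, by = 0.3)) {
    R <- matrix(c(1, rho, rho, 1), 2)
    expect_equal(partial_correlations(R), R, tolerance = 1e-10)
  }
  # 3x3 equicorrelation 0.5: all partials are 1/3
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  P <- partial_correlations(R3)
  expect_equal(P[lower.tri(P)], rep(1 / 3, 3), tolerance = 1e-10)
  # scale invariance: covariance vs its correlation
  S <- diag(c(2, 0.5, 3)) %*% R3 %*% diag(c(2, 0.5, 3))
  expect_equal(partial_correlations(S), P, tolerance = 1e-10)
  expect_error(partial_correlations(matrix(c(1, 1, 1, 1), 2)), "singular")
})

make_degenerate_posterior <- function(rho_delta, rho_eps = 0.1, n = 50) {
  # a sutse_posterior whose every draw carries the same correlation values
  chains <- list(data.frame(sigma_1 = 0.05, sigma_2 = 0.05, gamma_1 = 0.01,
                            gamma_2 = 0.01, rho_eps_2_1 = rho_eps,
                            rho_delta_2_1 = rho_delta, loglik = 0,
                            log_post = 0)[rep(1, n), ])
  structure(list(chains = chains, n_series = 2L, priors = prior_spec(),
                 series_names = c("a", "b"),
                 config = list(n_chains = 1L, n_warmup = 0L, n_keep = n)),
            class = "sutse_posterior")
}

test_that("correlation summary tables: degenerate, composed, and permuted", {
  post <- make_degenerate_posterior(0.3)
  tab <- correlation_summary(post, "evolution")
  expect_equal(tab$table[1, 2], 1)     # P(rho > 0) above the diagonal
  expect_equal(tab$table[2, 1], 0.3)   # lower bound below
  expect_true(all(is.na(diag(tab$table))))
  # 2 series: partial correlation equals the correlation
  ptab <- correlation_summary(post, "partial-evolution")
  expect_equal(ptab$table[2, 1], 0.3, tolerance = 1e-10)
  # composition: table entries equal scalar recomputation on pooled draws
  sim <- simulate_sutse(make_fixture(3, 30, 0, seed = 13))
  spec <- build_model(3, 0)
  fit <- sample_posterior(sim$log_series, spec, n_chains = 2, n_warmup = 60,
                          n_keep = 150, seed = 2, control = list(n_try = 1))
  df <- pooled_draws(fit)
  tab3 <- correlation_summary(fit, "error")
  for (nm in c("rho_eps_2_1", "rho_eps_3_2")) {
    ij <- as.integer(strsplit(nm, "_")[[1]][3:4])
    expect_equal(tab3$prob_positive[ij[1], ij[2]], prob_positive(df[[nm]]))
    expect_equal(tab3$lower_bound[ij[1], ij[2]], one_sided_lower(df[[nm]]))
  }
  # chain concatenation order does not matter
  fit_rev <- fit
  fit_rev$chains <- rev(fit$chains)
  expect_equal(correlation_summary(fit_rev, "error")$table, tab3$table)
  # prob > 0.5 iff median > 0 (sign agreement over every pair and kind)
  for (kind in c("evolution", "error", "partial-evolution")) {
    tt <- correlation_summary(fit, kind)
    med_sign <- sign(apply(
      cbind(df[, grep(if (kind == "error") "rho_eps" else "rho_delta",
                      names(df))]), 2, median))
    if (kind != "partial-evolution")
      expect_equal(unname(tt$long$prob_positive > 0.5),
                   unname(med_sign > 0))
  }
})

test_that("smoothed series: band collapse, linearity, and Jensen gap", {
  spec <- build_model(1, 0)
  # single draw: intervals collapse onto the draw
  one <- array(rnorm(11 * 2, 7, 0.1), c(1, 11, 2))
  tab <- smoothed_series(one, spec, "log", "trend")
  expect_equal(tab$mean, tab$lower95)
  expect_equal(tab$mean, tab$upper95)
  expect_equal(tab$mean, one[1, -1, 1])
  # gamma = 0 posterior draws have exactly linear trends
  params <- cov_params(0.05, matrix(1), 0, matrix(1))
  y <- matrix(6 + 0.02 * (1:20) + rnorm(20, 0, 0.05), 20, 1)
  f <- kalman_filter(spec, params, observed_series(y))
  set.seed(3)
  dr <- ffbs(f, spec, params, 50)
  tr <- smoothed_series(dr, spec, "log", "trend")
  for (k in 1:5)
    expect_lt(max(abs(diff(dr[k, -1, 1], differences = 2))), 1e-9)
  # count scale: mean of exponentials strictly exceeds exp of mean
  set.seed(4)
  disp <- array(rnorm(200 * 6 * 1, 7, 0.5), c(200, 6, 1))
  lg <- smoothed_series(disp, spec, "log", "trend")
  ct <- smoothed_series(disp, spec, "count", "trend")
  expect_true(all(ct$mean > exp(lg$mean)))
})

test_that("fit component includes seasonal coordinates, trend does not", {
  spec <- build_model(1, 1)
  th <- c(5, 0, 2, 1)  # level 5, harmonic 2
  dr <- array(rep(th, each = 2 * 2), c(2, 2, 4))
  expect_equal(smoothed_series(dr, spec, "log", "trend")$mean, rep(5, 1))
  expect_equal(smoothed_series(dr, spec, "log", "fit")$mean, rep(7, 1))
})

test_that("residuals are data minus posterior mean fit", {
  spec <- build_model(2, 0)
  params <- random_cov_params(2)
  y <- matrix(rnorm(20, 7, 0.5), 10, 2)
  data <- observed_series(y)
  f <- kalman_filter(spec, params, data)
  set.seed(6)
  dr <- ffbs(f, spec, params, 200)
  res <- fit_residuals(data, dr, spec)
  fitted1 <- colMeans(dr[, -1, 1])
  expect_equal(unname(res[, 1]), unname(y[, 1] - fitted1))
  # pure subtraction contract: shifting the data shifts residuals
  res_shift <- fit_residuals(observed_series(y + 1), dr, spec)
  expect_equal(res_shift, res + 1)
  # perfect-fit draws give ~zero residuals
  perfect <- array(0, c(3, 11, 4))
  for (t in 1:10) perfect[, t + 1, c(1, 3)] <- rep(y[t, ], each = 3)
  expect_equal(max(abs(fit_residuals(data, perfect, spec))), 0)
})

test_that("energy statistic matches term-by-term evaluation in d = 1", {
  # 3-point hand oracle: E|a - Z| = 2 phi(a) + a (2 Phi(a) - 1)
  y <- c(-1, 0, 2)
  ys <- sutse:::standardize_whiten(matrix(y, 3, 1))
  e_az <- 2 * dnorm(ys) + ys * (2 * pnorm(ys) - 1)
  hand <- 3 * (2 * mean(e_az) - 2 / sqrt(pi) -
                 sum(abs(outer(ys, ys, "-"))) / 9)
  expect_equal(sutse:::energy_stat(ys), hand, tolerance = 1e-9)
  # the noncentral-chisquare series agrees with the d = 1 closed form
  a <- c(0, 0.3, 1.7, 4)
  expect_equal(sutse:::e_norm_to_gaussian(a^2, 1),
               2 * dnorm(a) + a * (2 * pnorm(a) - 1), tolerance = 1e-10)
})

test_that("energy test calibrates under the null and detects heavy tails", {
  set.seed(77)
  pvals_null <- vapply(1:20, function(r) {
    x <- matrix(rnorm(120 * 6), 120, 6)
    energy_normality_test(x, n_boot = 99)$p_value
  }, numeric(1))
  expect_gte(sum(pvals_null > 0.05), 18)
  pvals_t <- vapply(1:20, function(r) {
    x <- matrix(rt(120 * 6, df = 2), 120, 6)
    energy_normality_test(x, n_boot = 99)$p_value
  }, numeric(1))
  expect_gte(sum(pvals_t < 0.05), 18)
  expect_error(energy_normality_test(matrix(rnorm(10), 5, 2), n_boot = 50),
               "n_boot")
})

test_that("raw correlations: proportional, negated, and textbook formula", {
  t_ <- 1:24
  x <- cbind(a = 100 + 3 * t_, b = 2 * (100 + 3 * t_), c = -(100 + 3 * t_))
  R <- raw_correlations(x)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  set.seed(10)
  y <- matrix(rnorm(60), 20, 3)
  R2 <- raw_correlations(y)
  manual <- sum(scale(y[, 1]) * scale(y[, 2])) / 19
  expect_equal(R2[1, 2], manual)
  expect_error(raw_correlations(cbind(1:5, rep(2, 5))), "constant")
})

test_that("density summary integrates to one and finds the median", {
  set.seed(12)
  x <- tanh(rnorm(5000, 0, 0.5))
  ds <- density_summary(x)
  integral <- sum(diff(ds$grid) * (head(ds$density, -1) + tail(ds$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.02)
  expect_equal(ds$median, sort(x)[2500])
  expect_lt(abs(ds$median), 0.05)
  expect_error(density_summary(rnorm(5)), "at least 10")
})
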