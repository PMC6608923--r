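#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF with its 95% upper bound (Brooks & Gelman 1998,
#' corrected-scale version).  Each chain is split in half before the
#' between/within variance comparison, so stationarity failures within a
#' chain also inflate the statistic.
#'
#' @param chains a numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors; at least 2 chains after splitting.
#' @param split split each chain in half first? (default `TRUE`;
#'   `FALSE` reproduces the classic unsplit diagnostic.)
#' @return a list with `point` and `upper95`.
#' @export
psrf <- function(chains, split = TRUE) {
  x <- as_chain_matrix(chains)
  if (ncol(x) < 2 && !split) stop("psrf needs at least 2 chains")
  if (split) {
    n2 <- nrow(x) %/% 2L
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(x); m <- ncol(x)
  if (n < 2) stop("chains too short")
  s2 <- apply(x, 2, stats::var)
  xbar <- colMeans(x)
  W <- mean(s2)
  B <- n * stats::var(xbar)
  muhat <- mean(xbar)
  if (W < .Machine$double.eps) {
    # constant chains: no variance anywhere -> R = 1 by convention
    if (B < .Machine$double.eps) return(list(point = 1, upper95 = 1))
    return(list(point = Inf, upper95 = Inf))
  }
  var_w <- stats::var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(s2, xbar^2) - 2 * muhat * stats::cov(s2, xbar))
  sig2hat <- (n - 1) * W / n + B / n
  Vhat <- sig2hat + B / (m * n)
  var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  df_V <- 2 * Vhat^2 / var_V
  df_adj <- (df_V + 3) / (df_V + 1)
  point <- sqrt(df_adj * Vhat / W)
  R2_fixed <- (n - 1) / n
  R2_random <- (1 + 1 / m) * (1 / n) * (B / W)
  df_w <- 2 * W^2 / var_w
  upper <- sqrt(df_adj * (R2_fixed + stats::qf(0.975, m - 1, df_w) * R2_random))
  list(point = point, upper95 = upper)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS for multiple chains: combined-chain variance
#' estimate, per-chain autocovariances, and Geyer initial-monotone-sequence
#' truncation of the paired autocorrelation sums.
#'
#' @inheritParams psrf
#' @return the effective sample size (scalar).
#' @export
ess <- function(chains) {
  x <- as_chain_matrix(chains)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) stop("chains too short for ESS")
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  if (W < .Machine$double.eps) return(NaN)
  varplus <- (n - 1) * W / n +
    if (m > 1) stats::var(colMeans(x)) else 0
  # per-chain autocovariances (biased estimator), averaged over chains
  maxlag <- n - 2L
  acov <- matrix(0, maxlag + 1L, m)
  for (j in seq_len(m)) {
    a <- stats::acf(x[, j], lag.max = maxlag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acov[, j] <- a * (n - 1) / n
  }
  rho <- 1 - (W - rowMeans(acov)) / varplus  # rho[1] = lag 0
  # Geyer: sum pairs while positive, enforce monotone nonincreasing
  tau <- rho[1]
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pr <- rho[t] + rho[t + 1L]
    if (pr < 0) break
    pr <- min(pr, prev)
    tau <- tau + 2 * pr
    prev <- pr
    t <- t + 2L
  }
  m * n / max(tau, .Machine$double.eps)
}

as_chain_matrix <- function(chains) {
  if (is.list(chains) && !is.matrix(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) stop("chains must have equal lengths")
    chains <- do.call(cbind, lapply(chains, as.numeric))
  }
  x <- as.matrix(chains)
  storage.mode(x) <- "double"
  x
}

#' Convergence diagnostics for every sampled parameter
#'
#' @param posterior a [sample_posterior()] result.
#' @return a data frame with one row per parameter: split-chain PSRF point
#'   estimate, its 95% upper bound, and ESS.
#' @export
posterior_diagnostics <- function(posterior) {
  stopifnot(inherits(posterior, "sutse_posterior"))
  pars <- setdiff(colnames(posterior$chains[[1]]), c("loglik", "log_post"))
  rows <- lapply(pars, function(pn) {
    x <- vapply(posterior$chains, function(ch) ch[[pn]],
                numeric(nrow(posterior$chains[[1]])))
    r <- psrf(x)
    data.frame(parameter = pn, psrf = r$point, psrf_upper95 = r$upper95,
               ess = ess(x))
  })
  do.call(rbind, rows)
}
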