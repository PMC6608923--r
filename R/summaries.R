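#' Posterior probability of positivity
#'
#' The proportion of draws strictly greater than zero,
#' \eqn{K^{-1} \sum_k 1[x_k > 0]} (zeros count as not positive).
#'
#' @param samples non-empty numeric vector of posterior draws.
#' @return a probability in `[0, 1]`.
#' @export
prob_positive <- function(samples) {
  if (length(samples) == 0) stop("samples must be non-empty")
  mean(samples > 0)
}

#' One-sided lower credible bound
#'
#' The empirical `(1 - level)` quantile defined as the
#' \eqn{\lceil (1-level) K \rceil}-th order statistic of the draws.
#'
#' @param samples non-empty numeric vector of posterior draws.
#' @param level one-sided credibility level in (0, 1); default 0.95.
#' @return the lower bound of the one-sided `level` credible interval.
#' @export
one_sided_lower <- function(samples, level = 0.95) {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  # small guard against floating-point excess in (1 - level) * K
  k <- ceiling((1 - level) * length(samples) - 1e-9)
  sort(samples)[max(1L, k)]
}

#' Partial correlations from a covariance (or correlation) matrix
#'
#' With \eqn{P = \Sigma^{-1}}, entry \eqn{(i,j)} is
#' \eqn{-P_{ij} / \sqrt{P_{ii} P_{jj}}}: the correlation between components
#' \eqn{i} and \eqn{j} given all others.  Diagonal set to 1.
#'
#' @param cov a positive definite matrix.
#' @return the matrix of partial correlations.
#' @export
partial_correlations <- function(cov) {
  P <- tryCatch(chol2inv(chol(cov)), error = function(e)
    stop("covariance matrix is singular or not positive definite"))
  D <- sqrt(diag(P))
  R <- -P / outer(D, D)
  diag(R) <- 1
  R
}

#' Correlation summary table (probabilities above, bounds below)
#'
#' Applies [prob_positive()] (upper triangle) and [one_sided_lower()]
#' (lower triangle) elementwise to the pooled posterior draws of the chosen
#' correlation family.  `kind = "partial-evolution"` first maps each draw of
#' the slope-innovation covariance \eqn{\Sigma_{\tilde\delta}} through
#' [partial_correlations()].
#'
#' @param posterior a [sample_posterior()] result.
#' @param kind one of `"evolution"`, `"error"`, `"partial-evolution"`.
#' @param level one-sided credibility level for the lower bounds.
#' @return an object of class `sutse_corr_table`: a square matrix `table`
#'   (upper triangle = probabilities, lower = bounds, diagonal `NA`), plus
#'   `prob_positive` and `lower_bound` matrices and a tidy long-format
#'   data frame `long`.
#' @export
correlation_summary <- function(posterior, kind = c("evolution", "error",
                                                    "partial-evolution"),
                                level = 0.95) {
  stopifnot(inherits(posterior, "sutse_posterior"))
  kind <- match.arg(kind)
  C <- posterior$n_series
  df <- pooled_draws(posterior)
  pairs <- lower_tri_pairs(C)
  draw_mat <- switch(kind,
    evolution = as.matrix(df[, rho_names(C, "rho_delta"), drop = FALSE]),
    error = as.matrix(df[, rho_names(C, "rho_eps"), drop = FALSE]),
    "partial-evolution" = {
      out <- matrix(NA_real_, nrow(df), nrow(pairs))
      for (i in seq_len(nrow(df))) {
        Sd <- sigma_delta_tilde(row_to_params(df[i, ], C))
        out[i, ] <- partial_correlations(Sd)[pairs]
      }
      out
    })
  prob <- lb <- matrix(NA_real_, C, C,
                       dimnames = list(posterior$series_names,
                                       posterior$series_names))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "row"]; j <- pairs[k, "col"]
    prob[i, j] <- prob[j, i] <- prob_positive(draw_mat[, k])
    lb[i, j] <- lb[j, i] <- one_sided_lower(draw_mat[, k], level)
  }
  tab <- matrix(NA_real_, C, C, dimnames = dimnames(prob))
  tab[upper.tri(tab)] <- prob[upper.tri(prob)]
  tab[lower.tri(tab)] <- lb[lower.tri(lb)]
  long <- data.frame(series_i = posterior$series_names[pairs[, "row"]],
                     series_j = posterior$series_names[pairs[, "col"]],
                     prob_positive = prob[pairs],
                     lower95 = lb[pairs],
                     kind = kind)
  structure(list(table = tab, prob_positive = prob, lower_bound = lb,
                 long = long, kind = kind, level = level,
                 series_names = posterior$series_names),
            class = "sutse_corr_table")
}

#' @export
print.sutse_corr_table <- function(x, digits = 2, ...) {
  cat(sprintf("%s correlations: P(rho > 0 | Y) above diagonal, one-sided %d%% lower bounds below\n",
              x$kind, round(100 * x$level)))
  print(round(x$table, digits), na.print = "-")
  invisible(x)
}

#' Smoothed series summaries from posterior state draws
#'
#' Pointwise posterior mean and 95% interval of either the trend (level
#' coordinate only) or the full fit (\eqn{F\theta}: level + seasonal) for
#' each series, on the log or count scale.  On the count scale each draw is
#' exponentiated before the pointwise mean and 2.5%/97.5% quantiles are
#' taken.
#'
#' @param state_draws an `n_draws x (T+1) x p` array (e.g. the
#'   `state_draws` element filled in by [sample_states()]).
#' @param spec the model specification.
#' @param scale `"log"` or `"count"`.
#' @param component `"trend"` or `"fit"`.
#' @param months optional length-`T` month labels.
#' @param series_names optional series labels.
#' @return a data frame with columns `series`, `month`, `time`, `mean`,
#'   `lower95`, `upper95`.
#' @export
smoothed_series <- function(state_draws, spec, scale = c("log", "count"),
                            component = c("trend", "fit"),
                            months = NULL, series_names = NULL) {
  scale <- match.arg(scale)
  component <- match.arg(component)
  if (is.null(dim(state_draws)) || length(dim(state_draws)) != 3)
    stop("state_draws must be an n_draws x (T+1) x p array")
  n_draws <- dim(state_draws)[1]
  if (n_draws < 1) stop("no state draws")
  T_ <- dim(state_draws)[2] - 1L
  C <- spec$n_series
  if (is.null(series_names)) series_names <- paste0("series_", seq_len(C))
  if (is.null(months)) months <- seq_len(T_)
  out <- vector("list", C)
  for (cc in seq_len(C)) {
    vals <- series_component_draws(state_draws, spec, cc, component)  # draws x T
    if (scale == "count") vals <- exp(vals)
    qs <- apply(vals, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    out[[cc]] <- data.frame(series = series_names[cc], month = months,
                            time = seq_len(T_), mean = colMeans(vals),
                            lower95 = qs[1, ], upper95 = qs[2, ])
  }
  do.call(rbind, out)
}

# draws x T matrix of one series' trend or fit, excluding t = 0
series_component_draws <- function(state_draws, spec, series, component) {
  nd <- dim(state_draws)[1]
  T_ <- dim(state_draws)[2] - 1L
  b <- spec$block_size
  off <- (series - 1L) * b
  if (component == "trend") {
    matrix(state_draws[, -1L, off + 1L], nd, T_)
  } else {
    out <- matrix(0, nd, T_)
    for (j in which(spec$obs_matrix[series, ] != 0))
      out <- out + matrix(state_draws[, -1L, j], nd, T_)
    out
  }
}

#' Residuals: data minus posterior mean fit
#'
#' Subtracts the pointwise posterior mean of \eqn{F\theta_t} (log scale)
#' from the observed log counts.
#'
#' @param data a [observed_series()] object.
#' @param state_draws an `n_draws x (T+1) x p` array of posterior state
#'   draws.
#' @param spec the model specification.
#' @return a `T x C` matrix of residuals.
#' @export
fit_residuals <- function(data, state_draws, spec) {
  y <- if (inherits(data, "sutse_series")) data$log_counts else as.matrix(data)
  C <- spec$n_series
  if (ncol(y) != C) stop("data and model dimension mismatch")
  if (dim(state_draws)[2] - 1L != nrow(y))
    stop("state draws and data length mismatch")
  fitted <- vapply(seq_len(C), function(cc)
    colMeans(series_component_draws(state_draws, spec, cc, "fit")),
    numeric(nrow(y)))
  res <- y - fitted
  dimnames(res) <- dimnames(y)
  res
}

#' Energy test of multivariate normality
#'
#' Computes the energy statistic for multinormality on standardized
#' residuals (centered, whitened by the sample covariance),
#' \deqn{E_n = n\left(\frac{2}{n}\sum_i E\|y_i - Z\| - E\|Z - Z'\|
#'   - \frac{1}{n^2}\sum_{i,j}\|y_i - y_j\|\right),}
#' with \eqn{Z, Z'} independent standard d-variate normals.
#' \eqn{E\|a - Z\|} is evaluated in closed form through the series for the
#' mean of the square root of a noncentral chi-square variable.  The p-value
#' is a parametric-bootstrap Monte Carlo estimate: the statistic is
#' recomputed on `n_boot` standard-normal samples pushed through the same
#' standardization.
#'
#' Uses R's RNG stream: seed with [set.seed()].
#'
#' @param residuals an `n x d` numeric matrix, `n > d`.
#' @param n_boot number of bootstrap samples (>= 99; default 500).
#' @return a list with `statistic` and `p_value`.
#' @export
energy_normality_test <- function(residuals, n_boot = 500L) {
  x <- as.matrix(residuals)
  n <- nrow(x); d <- ncol(x)
  if (n <= d) stop("need more observations than dimensions")
  if (n_boot < 99) stop("n_boot must be >= 99")
  stat <- energy_stat(standardize_whiten(x))
  boots <- vapply(seq_len(n_boot), function(b) {
    z <- matrix(stats::rnorm(n * d), n, d)
    energy_stat(standardize_whiten(z))
  }, numeric(1))
  list(statistic = stat, p_value = (1 + sum(boots >= stat)) / (n_boot + 1))
}

standardize_whiten <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  S <- stats::cov(x)
  L <- tryCatch(chol(S), error = function(e)
    stop("sample covariance of residuals is singular"))
  t(backsolve(L, t(xc), transpose = TRUE))
}

# the energy statistic on already-standardized data
energy_stat <- function(y) {
  n <- nrow(y); d <- ncol(y)
  mean_aZ <- mean(e_norm_to_gaussian(rowSums(y^2), d))
  mean_ZZ <- 2 * exp(lgamma((d + 1) / 2) - lgamma(d / 2))
  dd <- as.matrix(stats::dist(y))
  n * (2 * mean_aZ - mean_ZZ - sum(dd) / n^2)
}

# E || a - Z || for Z ~ N(0, I_d) with lambda = ||a||^2:
# sqrt of a noncentral chi-square; Poisson-mixture series for E sqrt(X).
e_norm_to_gaussian <- function(lambda, d) {
  kmax <- max(60, ceiling(max(lambda) / 2 + 10 * sqrt(max(lambda) / 2 + 1) + 25))
  k <- 0:kmax
  lg <- lgamma((d + 2 * k + 1) / 2) - lgamma((d + 2 * k) / 2) - lgamma(k + 1)
  vapply(lambda, function(l) {
    h <- l / 2
    if (h == 0) return(sqrt(2) * exp(lgamma((d + 1) / 2) - lgamma(d / 2)))
    sqrt(2) * sum(exp(-h + k * log(h) + lg))
  }, numeric(1))
}

#' Pearson correlations of raw monthly counts
#'
#' @param counts a `T x C` numeric table of monthly counts (`T >= 3`).
#' @return the `C x C` Pearson correlation matrix.
#' @export
raw_correlations <- function(counts) {
  x <- as.matrix(counts)
  if (nrow(x) < 3) stop("need at least 3 months")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant column in counts")
  stats::cor(x)
}

#' Kernel density summary of posterior correlation draws
#'
#' Gaussian KDE with Silverman's bandwidth on a grid over \eqn{[-1, 1]},
#' plus the posterior median (50% order statistic).
#'
#' @param samples at least 10 draws.
#' @param n grid size.
#' @return a list with `grid`, `density`, and `median`.
#' @export
density_summary <- function(samples, n = 512L) {
  if (length(samples) < 10) stop("need at least 10 samples")
  dn <- stats::density(samples, bw = "nrd0", from = -1, to = 1, n = n)
  list(grid = dn$x, density = dn$y,
       median = sort(samples)[ceiling(length(samples) / 2)])
}
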