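# Posterior sampling for the covariance hyperparameters.
#
# The latent states are marginalized exactly by the Kalman filter, so the
# target is the low-dimensional density exp(log_posterior_hyper(u)).  The
# default sampler is a two-stage scheme:
#   1. find the posterior mode by BFGS on the unconstrained scale and build a
#      multivariate-t independence proposal from a finite-difference Hessian;
#   2. run multiple-try Metropolis with independence proposals (Liu, Liang &
#      Wong 2000): several candidates per step, selected by importance
#      weight, which pushes acceptance well above what single-try
#      independence MH achieves.  The proposal is refitted from warm-up
#      draws as a Gaussian mixture (capturing posterior skew) and frozen
#      before inference; if the independence proposal is poor the chain
#      falls back to adaptive random-walk Metropolis.
# The kernel is frozen at the end of warm-up, so the inference phase is a
# valid time-homogeneous chain.

#' Sample the marginal posterior of the covariance hyperparameters
#'
#' MCMC draws targeting \eqn{p(\Sigma_\epsilon, \Sigma_\delta \mid Y)} with
#' the states integrated out by the Kalman filter (see
#' [log_posterior_hyper()]).  Chain initial values are drawn from the priors
#' truncated to \eqn{\sigma, \gamma \in (0.001, 2)}; per-chain seeds are
#' derived deterministically from `seed`, so a fixed seed yields identical
#' draws.
#'
#' @param data a [observed_series()] object.
#' @param spec a [build_model()] specification.
#' @param priors a [prior_spec()] object.
#' @param n_chains,n_warmup,n_keep MCMC configuration (defaults 3 chains,
#'   1000 warm-up, 4000 kept draws per chain).
#' @param seed integer seed governing all randomness.
#' @param control optional list: `max_opt_iter` (BFGS iterations, default
#'   150), `hessian` (`"full"`, `"diag"`, or `"auto"` = full up to 24
#'   parameters), `prop_df` (t proposal degrees of freedom, default 8),
#'   `prop_scale` (proposal covariance inflation, default 1.2),
#'   `min_accept` (warm-up acceptance below which the sampler falls back to
#'   adaptive random-walk Metropolis, default 0.15), `init_tries` (default
#'   100), `n_try` (multiple-try candidates per step, default 4; 1 gives
#'   plain independence MH -- useful for expensive large-state models).
#' @return an object of class `sutse_posterior`: `chains` (one data frame
#'   per chain with columns `sigma_<i>`, `gamma_<i>`, `rho_eps_<i>_<j>`,
#'   `rho_delta_<i>_<j>`, `loglik`, `log_post`), `config`, `sampler` (per
#'   chain kind and acceptance rate), and the model dimensions.
#' @export
sample_posterior <- function(data, spec, priors = prior_spec(),
                             n_chains = 3L, n_warmup = 1000L, n_keep = 4000L,
                             seed = 1L, control = list()) {
  stopifnot(inherits(spec, "sutse_model"), n_chains >= 1, n_warmup >= 2,
            n_keep >= 1)
  ctl <- utils::modifyList(
    list(max_opt_iter = 150L, hessian = "auto", prop_df = 8,
         prop_scale = 1.2, min_accept = 0.15, init_tries = 100L,
         n_try = 4L),
    control)
  C <- spec$n_series
  d <- n_unconstrained(C)
  lp2 <- make_fast_lp(data, spec, priors)     # list(lp, ll) per point
  lp <- function(u) lp2(u)$lp

  # --- stage 1: mode + proposal (deterministic given the data) ---
  u_start <- moment_init(data, spec)
  opt <- tryCatch(
    stats::optim(u_start, fn = function(u) -lp(u), method = "BFGS",
                 control = list(maxit = ctl$max_opt_iter, reltol = 1e-10)),
    error = function(e) list(par = u_start, value = -lp(u_start)))
  mode_u <- opt$par
  hess_kind <- ctl$hessian
  if (hess_kind == "auto") hess_kind <- if (d <= 24L) "full" else "diag"
  Sig0 <- proposal_cov(function(u) -lp(u), mode_u, hess_kind)
  prop0 <- make_t_proposal(mode_u, ctl$prop_scale^2 * Sig0, ctl$prop_df)

  chains <- vector("list", n_chains)
  sampler_info <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seed(seed, ch))
    u0 <- init_from_prior(spec, priors, lp, ctl$init_tries)
    run <- run_chain(lp2, u0, prop0, n_warmup, n_keep, ctl)
    chains[[ch]] <- draws_to_table(run$draws, run$loglik, run$log_post, C)
    sampler_info[[ch]] <- run$info
  }

  structure(list(chains = chains,
                 config = list(n_chains = n_chains, n_warmup = n_warmup,
                               n_keep = n_keep, seed = seed),
                 sampler = sampler_info,
                 mode = mode_u,
                 n_series = C, priors = priors,
                 series_names = if (inherits(data, "sutse_series"))
                   data$series_names else paste0("series_", seq_len(C))),
            class = "sutse_posterior")
}

# Lean closure evaluating the unconstrained log posterior and the log
# marginal likelihood in one pass.  Same quantity as log_posterior_hyper()
# (asserted in the test suite) but with the structural matrices precomputed
# and the correlation determinant taken from the canonical-partial-
# correlation identity det(Omega) = prod(1 - z^2), so the per-call cost is
# essentially one C++ filter sweep.
make_fast_lp <- function(data, spec, priors) {
  y <- if (inherits(data, "sutse_series")) data$log_counts else as.matrix(data)
  C <- spec$n_series
  if (ncol(y) != C) stop("data and model dimension mismatch")
  p <- spec$state_dim
  F_ <- spec$obs_matrix; G <- spec$transition
  m0 <- rep(0, p); C0 <- diag(priors$init_state_var, p)
  slope_idx <- which(spec$coord_labels$role == "slope")
  m <- C * (C - 1L) / 2L
  pairs <- lower_tri_pairs(C)
  # per-CPC coefficient on log(1 - z^2): prior exponent (v - 1) from
  # det(Omega)^(v-1) plus the transform Jacobian 1 + (C - 1 - j)/2
  zcoef <- (priors$corr_shape - 1) + 1 + (C - 1 - pairs[, "col"]) / 2
  v <- priors$corr_shape
  scale <- priors$sd_scale
  bad <- list(lp = -Inf, ll = -Inf)

  function(u) {
    if (any(!is.finite(u)) || any(abs(u) > 200)) return(bad)
    sig <- exp(u[seq_len(C)])
    gam <- exp(u[C + seq_len(C)])
    ze <- tanh(u[2 * C + seq_len(m)])
    zd <- tanh(u[2 * C + m + seq_len(m)])
    if (any(abs(c(ze, zd)) >= 1)) return(bad)
    zme <- matrix(0, C, C); zme[pairs] <- ze
    zmd <- matrix(0, C, C); zmd[pairs] <- zd
    Re_ <- corr_from_cpc(zme)
    Rd_ <- corr_from_cpc(zmd)
    V <- outer(sig, sig) * Re_
    W <- matrix(0, p, p)
    W[slope_idx, slope_idx] <- outer(gam, gam) * Rd_
    ll <- tryCatch(kf_loglik_cpp(y, F_, G, W, V, m0, C0),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(bad)
    lprior <- sum(dhalfcauchy(c(sig, gam), scale, log = TRUE))
    lcorr <- sum(zcoef * log1p(-ze^2)) + sum(zcoef * log1p(-zd^2))
    lp <- ll + lprior + lcorr + sum(u[seq_len(2 * C)])
    if (!is.finite(lp)) return(bad)
    list(lp = lp, ll = ll)
  }
}

chain_seed <- function(seed, chain) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(chain)
}

#' @export
print.sutse_posterior <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sutse_posterior: %d chains x %d draws (%d warm-up), %d series\n",
              cfg$n_chains, cfg$n_keep, cfg$n_warmup, x$n_series))
  acc <- vapply(x$sampler, function(s) s$accept_rate, numeric(1))
  kinds <- vapply(x$sampler, function(s) s$kind, character(1))
  cat("  sampler:", paste(sprintf("%s (%.2f)", kinds, acc), collapse = ", "), "\n")
  invisible(x)
}

# deterministic moment-based starting point: residual scale from a
# polynomial + month-of-year regression per series
moment_init <- function(data, spec) {
  y <- if (inherits(data, "sutse_series")) data$log_counts else as.matrix(data)
  C <- spec$n_series; T_ <- nrow(y)
  sig <- numeric(C)
  res <- matrix(0, T_, C)
  tt <- seq_len(T_)
  X <- cbind(1, tt / T_, (tt / T_)^2)
  if (spec$n_harmonics > 0 && T_ > 2 * spec$period) {
    mon <- factor(((tt - 1) %% spec$period))
    X <- cbind(X, stats::model.matrix(~ mon)[, -1, drop = FALSE])
  }
  for (cc in seq_len(C)) {
    yc <- y[, cc]
    ok <- is.finite(yc)
    fit <- stats::lm.fit(X[ok, , drop = FALSE], yc[ok])
    r <- numeric(T_)
    r[ok] <- fit$residuals
    res[, cc] <- r
    sig[cc] <- min(max(stats::sd(fit$residuals), 1e-3), 1)
  }
  gam <- pmax(sig / 20, 1e-3)
  Re <- suppressWarnings(stats::cor(res))  # zero-variance residuals -> NA
  Re[!is.finite(Re)] <- 0
  diag(Re) <- 1
  Re <- 0.5 * Re + 0.5 * diag(C)  # shrink toward identity: guaranteed PD
  u <- tryCatch(
    unconstrain_params(cov_params(sig, Re, gam, diag(C))),
    error = function(e) c(log(sig), log(gam), rep(0, C * (C - 1))))
  u
}

# inverse of a finite-difference Hessian of the negative log posterior,
# regularized until positive definite
proposal_cov <- function(nlp, at, kind) {
  d <- length(at)
  H <- if (kind == "full") {
    tryCatch(stats::optimHess(at, nlp), error = function(e) NULL)
  } else {
    h <- 1e-3
    f0 <- nlp(at)
    dd <- vapply(seq_len(d), function(i) {
      e <- replace(numeric(d), i, h)
      (nlp(at + e) - 2 * f0 + nlp(at - e)) / h^2
    }, numeric(1))
    diag(pmax(dd, 1e-4), d)
  }
  if (is.null(H) || any(!is.finite(H))) H <- diag(d)
  H <- 0.5 * (H + t(H))
  for (ridge in c(0, 10^(-8:2))) {
    Hr <- H + ridge * diag(d)
    ch <- tryCatch(chol(Hr), error = function(e) NULL)
    if (!is.null(ch)) return(chol2inv(ch))
  }
  diag(d)
}

# Independence proposals are finite mixtures of multivariate t / Gaussian
# components (df = Inf means Gaussian).  A small heavy-tailed safeguard
# component keeps the proposal-to-target ratio bounded in under-proposed
# directions so the chain cannot get stuck.
mix_comp <- function(mu, Sigma, df, w) {
  Sigma <- 0.5 * (Sigma + t(Sigma))
  L <- tryCatch(chol(Sigma),
                error = function(e) chol(Sigma + 1e-8 * diag(nrow(Sigma))))
  list(mu = mu, chol = L, df = df, w = w, logdet = 2 * sum(log(diag(L))))
}

make_t_proposal <- function(mu, Sigma, df) {
  list(d = length(mu), comps = list(mix_comp(mu, Sigma, df, 1)))
}

# Gaussian-mixture proposal fitted to warm-up draws (model-based clustering
# captures the skew a single ellipse cannot), plus a 10% wide-t safeguard.
make_gmm_proposal <- function(draws, df_safe = 4) {
  d <- ncol(draws)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(draws, G = 1:3, modelNames = "VVV",
                                    verbose = FALSE)),
    error = function(e) NULL)
  comps <- list()
  if (!is.null(fit) && fit$G >= 1) {
    pr <- fit$parameters
    for (k in seq_len(fit$G)) {
      Sig <- pr$variance$sigma[, , k] * 1.2
      comps[[k]] <- tryCatch(mix_comp(pr$mean[, k], Sig, Inf, 0.9 * pr$pro[k]),
                             error = function(e) NULL)
    }
    comps <- Filter(Negate(is.null), comps)
  }
  if (length(comps) == 0) {
    comps <- list(mix_comp(colMeans(draws), stats::cov(draws) * 1.2, 10, 0.9))
  } else {
    # renormalize the matched part to weight 0.9
    wsum <- sum(vapply(comps, `[[`, numeric(1), "w"))
    comps <- lapply(comps, function(cp) { cp$w <- 0.9 * cp$w / wsum; cp })
  }
  comps[[length(comps) + 1L]] <-
    mix_comp(colMeans(draws), stats::cov(draws) * 6 + 1e-8 * diag(d),
             df_safe, 0.1)
  list(d = d, comps = comps)
}

rmvt_prop <- function(prop) {
  ws <- vapply(prop$comps, `[[`, numeric(1), "w")
  k <- sample.int(length(ws), 1L, prob = ws)
  cp <- prop$comps[[k]]
  z <- stats::rnorm(prop$d)
  sc <- if (is.finite(cp$df)) sqrt(stats::rchisq(1, cp$df) / cp$df) else 1
  cp$mu + drop(crossprod(cp$chol, z)) / sc
}

ldmvt_prop <- function(prop, u) {
  d <- prop$d
  lds <- vapply(prop$comps, function(cp) {
    z <- backsolve(cp$chol, u - cp$mu, transpose = TRUE)
    q <- sum(z^2)
    lk <- if (is.finite(cp$df)) {
      lgamma((cp$df + d) / 2) - lgamma(cp$df / 2) -
        0.5 * d * log(cp$df * pi) - 0.5 * (cp$df + d) * log1p(q / cp$df)
    } else {
      -0.5 * d * log(2 * pi) - 0.5 * q
    }
    log(cp$w) + lk - 0.5 * cp$logdet
  }, numeric(1))
  mx <- max(lds)
  mx + log(sum(exp(lds - mx)))
}

init_from_prior <- function(spec, priors, lp, tries) {
  C <- spec$n_series
  for (k in seq_len(tries)) {
    draw_sd <- function() {
      x <- abs(stats::rcauchy(C, 0, priors$sd_scale))
      while (any(x <= 0.001 | x >= 2))
        x[x <= 0.001 | x >= 2] <- abs(stats::rcauchy(sum(x <= 0.001 | x >= 2),
                                                     0, priors$sd_scale))
      x
    }
    p0 <- tryCatch(
      cov_params(draw_sd(), sample_prior_corr(C, priors$corr_shape, 1)[, , 1],
                 draw_sd(), sample_prior_corr(C, priors$corr_shape, 1)[, , 1]),
      error = function(e) NULL)
    if (is.null(p0)) next
    u0 <- tryCatch(unconstrain_params(p0), error = function(e) NULL)
    if (!is.null(u0) && is.finite(lp(u0))) return(u0)
  }
  stop("could not find a finite-posterior initial value after ", tries, " attempts")
}

# one chain: warm-up with proposal tuning, then a frozen kernel
logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

run_chain <- function(lp2, u0, prop0, n_warmup, n_keep, ctl) {
  d <- length(u0)
  k <- max(1L, as.integer(ctl$n_try))
  st0 <- lp2(u0)
  state <- list(u = u0, lp = st0$lp, ll = st0$ll)
  half <- max(2L, n_warmup %/% 2L)

  # one multiple-try independence-Metropolis step (k = 1 is plain
  # independence MH); importance weights w = pi/q
  mtm_step <- function(state, prop) {
    cand <- vector("list", k)
    lw <- numeric(k)
    for (j in seq_len(k)) {
      uj <- rmvt_prop(prop)
      ev <- lp2(uj)
      cand[[j]] <- list(u = uj, lp = ev$lp, ll = ev$ll)
      lw[j] <- ev$lp - ldmvt_prop(prop, uj)
    }
    num <- logsumexp(lw)
    if (!is.finite(num))
      return(list(u = state$u, lp = state$lp, ll = state$ll, acc = FALSE))
    pr <- exp(lw - num)
    J <- sample.int(k, 1L, prob = pr)
    lw_ref <- state$lp - ldmvt_prop(prop, state$u)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        ur <- rmvt_prop(prop)
        lw_ref <- c(lw_ref, lp2(ur)$lp - ldmvt_prop(prop, ur))
      }
    }
    lr <- num - logsumexp(lw_ref)
    if (is.finite(lr) && log(stats::runif(1)) < lr)
      list(u = cand[[J]]$u, lp = cand[[J]]$lp, ll = cand[[J]]$ll, acc = TRUE)
    else list(u = state$u, lp = state$lp, ll = state$ll, acc = FALSE)
  }

  phase <- function(state, n, prop, record = FALSE) {
    draws <- matrix(NA_real_, n, d)
    ll <- lpost <- if (record) numeric(n) else NULL
    acc <- 0L
    for (i in seq_len(n)) {
      state <- mtm_step(state, prop)
      acc <- acc + state$acc
      draws[i, ] <- state$u
      if (record) { ll[i] <- state$ll; lpost[i] <- state$lp }
    }
    list(state = state, draws = draws, ll = ll, lpost = lpost, rate = acc / n)
  }

  ph1 <- phase(state, half, prop0)
  kind <- "mtm-independence"
  if (ph1$rate >= ctl$min_accept) {
    # refit the proposal from first-half warm-up draws (a Gaussian-mixture
    # fit corrects the Laplace approximation for posterior skew), run the
    # second half, then freeze a final kernel refit from all warm-up draws
    refit <- function(draws, fallback) {
      tryCatch(make_gmm_proposal(draws), error = function(e) fallback)
    }
    ph2 <- phase(ph1$state, n_warmup - half, refit(ph1$draws, prop0))
    prop <- refit(rbind(ph1$draws, ph2$draws), prop0)
    if (ph2$rate < ctl$min_accept) prop <- prop0  # refits unreliable: revert
    inf <- phase(ph2$state, n_keep, prop, record = TRUE)
    return(list(draws = inf$draws, loglik = inf$ll, log_post = inf$lpost,
                info = list(kind = kind, accept_rate = inf$rate,
                            warmup_accept = c(ph1$rate, ph2$rate))))
  }

  # fallback: adaptive random-walk Metropolis (Haario), frozen after warm-up
  kind <- "adaptive-rwm"
  state <- ph1$state
  scale <- 2.38 / sqrt(d)
  cov_emp <- stats::cov(ph1$draws)
  if (any(!is.finite(cov_emp)) || sum(diag(cov_emp)) < 1e-12)
    cov_emp <- diag(d) * 0.01
  Lrw <- chol(cov_emp + 1e-8 * diag(d))
  rwm_step <- function(state, scale) {
    up <- state$u + scale * drop(crossprod(Lrw, stats::rnorm(d)))
    ev <- lp2(up)
    alpha <- if (is.finite(ev$lp)) min(1, exp(min(0, ev$lp - state$lp))) else 0
    if (alpha > 0 && stats::runif(1) < alpha)
      list(u = up, lp = ev$lp, ll = ev$ll, acc = TRUE, alpha = alpha)
    else list(u = state$u, lp = state$lp, ll = state$ll, acc = FALSE, alpha = alpha)
  }
  n2 <- n_warmup - half
  hist <- matrix(NA_real_, n2, d)
  for (i in seq_len(n2)) {
    state <- rwm_step(state, scale)
    hist[i, ] <- state$u
    scale <- scale * exp((state$alpha - 0.3) / sqrt(i + 10))
    if (i %% 100L == 0L && i >= 2 * d) {
      cv <- stats::cov(hist[seq_len(i), , drop = FALSE])
      Lrw <- tryCatch(chol(cv + 1e-8 * diag(d)), error = function(e) Lrw)
    }
  }
  draws <- matrix(NA_real_, n_keep, d)
  ll <- lpost <- numeric(n_keep)
  acc <- 0L
  for (i in seq_len(n_keep)) {
    state <- rwm_step(state, scale)
    acc <- acc + state$acc
    draws[i, ] <- state$u; ll[i] <- state$ll; lpost[i] <- state$lp
  }
  list(draws = draws, loglik = ll, log_post = lpost,
       info = list(kind = kind, accept_rate = acc / n_keep,
                   warmup_accept = ph1$rate))
}

rho_names <- function(C, prefix) {
  pairs <- lower_tri_pairs(C)
  sprintf("%s_%d_%d", prefix, pairs[, "row"], pairs[, "col"])
}

draws_to_table <- function(draws, loglik, log_post, C) {
  n <- nrow(draws)
  m <- C * (C - 1L) / 2L
  pairs <- lower_tri_pairs(C)
  out <- matrix(NA_real_, n, 2L * C + 2L * m)
  for (i in seq_len(n)) {
    cp <- constrain_params(draws[i, ], C)$params
    out[i, ] <- c(cp$obs_sd, cp$evo_sd, cp$obs_corr[pairs], cp$evo_corr[pairs])
  }
  colnames(out) <- c(paste0("sigma_", seq_len(C)), paste0("gamma_", seq_len(C)),
                     rho_names(C, "rho_eps"), rho_names(C, "rho_delta"))
  df <- as.data.frame(out)
  df$loglik <- loglik
  df$log_post <- log_post
  df
}

#' Pooled posterior draws
#'
#' Row-binds the per-chain draw tables (chains concatenated in order).
#'
#' @param posterior a [sample_posterior()] result.
#' @return a data frame of all draws.
#' @export
pooled_draws <- function(posterior) {
  stopifnot(inherits(posterior, "sutse_posterior"))
  do.call(rbind, posterior$chains)
}

# rebuild covariance matrices from one row of the draw table
row_to_params <- function(row, C) {
  pairs <- lower_tri_pairs(C)
  mk <- function(prefix) {
    R <- diag(C)
    vals <- as.numeric(row[rho_names(C, prefix)])
    R[pairs] <- vals
    R[pairs[, c(2, 1), drop = FALSE]] <- vals
    R
  }
  cov_params(as.numeric(row[paste0("sigma_", seq_len(C))]), mk("rho_eps"),
             as.numeric(row[paste0("gamma_", seq_len(C))]), mk("rho_delta"))
}

#' Deviance information criterion (marginal focus)
#'
#' Deviance \eqn{D(\Sigma) = -2 \log p(Y \mid \Sigma_\epsilon,
#' \Sigma_{\tilde\delta})} with the states integrated out by the Kalman
#' filter; \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\bar\Sigma)},
#' the plug-in evaluated at the posterior mean of the covariance matrices on
#' the natural (\eqn{\Sigma}) scale.
#'
#' @param posterior a [sample_posterior()] result (>= 2 draws).
#' @param data,spec the data and model used to fit it.
#' @return a list with `dic`, `p_d`, and `mean_deviance`.
#' @export
dic <- function(posterior, data, spec) {
  stopifnot(inherits(posterior, "sutse_posterior"))
  df <- pooled_draws(posterior)
  if (nrow(df) < 2) stop("need at least 2 posterior draws")
  C <- posterior$n_series
  dbar <- mean(-2 * df$loglik)
  Se <- matrix(0, C, C); Sd <- matrix(0, C, C)
  for (i in seq_len(nrow(df))) {
    cp <- row_to_params(df[i, ], C)
    Se <- Se + sigma_eps(cp)
    Sd <- Sd + sigma_delta_tilde(cp)
  }
  Se <- Se / nrow(df); Sd <- Sd / nrow(df)
  plug <- cov_params(sqrt(diag(Se)), stats::cov2cor(Se),
                     sqrt(diag(Sd)), stats::cov2cor(Sd))
  ll_hat <- kalman_loglik(spec, plug, data, 0, posterior$priors$init_state_var)
  if (!is.finite(ll_hat))
    stop("deviance at the posterior-mean covariances is not finite")
  d_hat <- -2 * ll_hat
  p_d <- dbar - d_hat
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

#' Draw latent-state trajectories for thinned posterior draws
#'
#' Runs FFBS once per thinned hyperparameter draw, giving samples from the
#' marginal posterior \eqn{p(\theta_{0:T} \mid Y)}.  Uses R's RNG stream:
#' seed with [set.seed()] for reproducibility.
#'
#' @param posterior a [sample_posterior()] result.
#' @param data,spec the data and model used to fit it.
#' @param thin keep every `thin`-th pooled draw; default targets
#'   `n_target` trajectories.
#' @param n_target used to choose `thin` when `thin` is `NULL`
#'   (default 1000 trajectories, a memory-control default).
#' @return the posterior object with a `state_draws` element: an array
#'   `n_draws x (T+1) x p` (`[, 1, ]` is \eqn{\theta_0}).
#' @export
sample_states <- function(posterior, data, spec, thin = NULL, n_target = 1000L) {
  stopifnot(inherits(posterior, "sutse_posterior"))
  df <- pooled_draws(posterior)
  total <- nrow(df)
  if (is.null(thin)) thin <- max(1L, total %/% n_target)
  thin <- as.integer(thin)
  if (thin < 1) stop("thin must be >= 1")
  idx <- seq(thin, total, by = thin)
  p <- spec$state_dim
  T_ <- nrow(if (inherits(data, "sutse_series")) data$log_counts else data)
  out <- array(NA_real_, c(length(idx), T_ + 1L, p))
  for (k in seq_along(idx)) {
    cp <- row_to_params(df[idx[k], ], posterior$n_series)
    f <- kalman_filter(spec, cp, data, 0, posterior$priors$init_state_var)
    out[k, , ] <- ffbs(f, spec, cp, 1L)[1L, , ]
  }
  posterior$state_draws <- out
  posterior
}
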