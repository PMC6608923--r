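---
title: "Multivariate trend inference with SUTSE dynamic linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate trend inference with SUTSE dynamic linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sutse)
```

## The model

`sutse` treats the natural logs of several parallel monthly count series
$Y_t = (Y_{1,t}, \dots, Y_{C,t})^\top$ as a Gaussian dynamic linear model

$$Y_t = F\theta_t + \epsilon_t, \qquad
  \theta_t = G\theta_{t-1} + \delta_t,$$

with independent Gaussian observation errors
$\epsilon_t \sim N(0, \Sigma_\epsilon)$ and state innovations
$\delta_t = R\tilde\delta_t$, $\tilde\delta_t \sim N(0, \Sigma_{\tilde\delta})$.
Each series occupies one block of the state vector containing

* a **local linear trend** pair (level, slope) with trend transition
  $\begin{pmatrix}1&1\\0&1\end{pmatrix}$.  Innovation noise enters *only*
  the slope (the selection matrix $R$ has a single 1 per column, at the
  slope coordinate), so the level is an integrated random walk — a smooth
  curve whose direction drifts, which is what "trend" should mean at a
  monthly resolution;
* $q$ **Fourier harmonics** of an $s$-month seasonal cycle: sine–cosine
  pairs at frequency $2\pi j/s$ propagated by rotation blocks of $G$.  The
  observation row of $F$ picks up each harmonic (not its conjugate).  At
  the Nyquist harmonic $q = s/2$ the rotation degenerates to the $1\times1$
  transition $-1$, giving state dimension $C(2 + 2q - 1)$ instead of
  $C(2 + 2q)$; with $C = 6$, $s = 12$ this is 12 states for $q=0$, 60 for
  $q=4$, 78 for $q=6$.

The series interact *only* through the two unstructured covariance
matrices, decomposed as $\Sigma = D\,\Omega\,D$ with standard deviations
$D$ and correlation matrix $\Omega$:

* **error correlations** $\Omega_\epsilon$ capture same-month co-deviation
  (weather, recording artifacts — anything transient);
* **evolution correlations** $\Omega_\delta$ capture co-movement of the
  *slopes*, i.e. whether two series' long-term trends bend together.  The
  corresponding **partial correlations**, computed per posterior draw from
  the negated, normalized inverse of $\Sigma_{\tilde\delta}$, measure
  conditional trend dependence given all other series.

This structure — univariate structural models tied only through their
noise covariances — is the SUTSE (seemingly unrelated time series
equations) family.

### Parameters that matter

| parameter | units | default / typical | role |
|---|---|---|---|
| $\sigma_i$ | log counts | ~0.03–0.07 | observation noise; 0.05 is ±5% month-to-month scatter |
| $\gamma_i$ | log counts · month$^{-2}$ | ~$10^{-3}$ | slope innovation scale; over $T$ months the level wanders by $O(\gamma T^{3/2})$, so even $7\times10^{-4}$ moves a 120-month trend by a factor ~2 |
| $q$ | harmonics | 4 (configurable 0–6) | seasonal flexibility; $q = 6$ equals a full 11-df monthly-dummy pattern |
| $s$ | months | 12 | seasonal period (kept configurable; only evenness is required) |
| $v$ | — | 1 | LKJ shape; 1 is uniform over correlation matrices, with implied marginals Beta$(C/2, C/2)$ rescaled to $(-1,1)$ — mild shrinkage toward 0 |
| $\kappa$ | — | $10^7$ | diffuse initial-state variance |

## Priors and posterior computation

Standard deviations get independent half-Cauchy $Ca^+(0,1)$ priors;
correlation matrices get LKJ($v$) priors $p(\Omega) \propto
|\Omega|^{v-1}$ with $v = 1$; the initial state gets $N(0, \kappa I)$ with
$\kappa = 10^7$.  The latent states are marginalized *exactly* by the
Kalman filter, so MCMC runs on the $2C + C(C-1)$ covariance
hyperparameters only, on an unconstrained scale: logs of the standard
deviations, and for each correlation matrix the canonical partial
correlations (CPCs) through `atanh`, with the analytic log-Jacobian
$\sum_{i>j}\bigl(1 + \tfrac{C-1-j}{2}\bigr)\log(1 - z_{ij}^2)$ (verified
against a finite-difference Jacobian in the tests).  Two identities make
the hot path cheap: $\det\Omega = \prod_{i>j}(1 - z_{ij}^2)$, and the
C-vine construction of $\Omega$ from Beta-distributed CPCs, which is also
how `sample_prior_corr()` draws exact LKJ samples.

The sampler is deliberately gradient-free and contract-first — any correct
MCMC targeting this marginal posterior is acceptable, and the built-in one
is:

1. **Mode and curvature.** BFGS from a deterministic moment-based start
   (residual scale of a polynomial-plus-month regression per series), then
   a finite-difference Hessian (full up to 24 parameters, diagonal above)
   giving a multivariate-$t$ Laplace proposal.
2. **Multiple-try independence Metropolis.** Each step draws `n_try`
   candidates (default 4), selects one by importance weight, and accepts
   against a freshly drawn reference set — the Liu–Liang–Wong scheme.
   This lifts acceptance from ~0.6 (single-try) to ~0.8 on well-behaved
   targets, which is what pushes the effective sample size of the
   correlation parameters past the reporting gate.
3. **Warm-up refits.** Halfway through warm-up, and again at its end, the
   proposal is refit to the warm-up draws as a Gaussian mixture
   (`mclust`, up to 3 components, covariances inflated 1.2×, plus a 10%
   wide-$t$ safeguard component that bounds the proposal-to-target ratio).
   The mixture captures the left skew of weakly identified $\log\gamma$
   directions that a single ellipse cannot.  The kernel is frozen before
   the inference phase, so the kept draws come from a valid
   time-homogeneous chain.
4. **Fallback.** If warm-up acceptance stays below 0.15 the chain switches
   to adaptive random-walk Metropolis (Haario-style covariance adaptation,
   Robbins–Monro scale targeting 0.3, frozen after warm-up).  This is what
   engages for the six-series, four-harmonic model (42 hyperparameters),
   where a Laplace-style independence proposal is hopeless; expect to need
   the full reference run length there and consult
   `posterior_diagnostics()` before trusting results.

Chain initial values are drawn from the priors truncated to $\sigma,
\gamma \in (0.001, 2)$ (retrying on a non-finite posterior); per-chain
seeds derive deterministically from the user seed, so runs are bitwise
reproducible.

### FFBS with a singular evolution covariance

$\Sigma_\delta = R \Sigma_{\tilde\delta} R^\top$ has rank $C \ll p$, so the
textbook backward sampler (which conditions $\theta_t$ on $\theta_{t+1}$
through a $p \times p$ covariance) is numerically fragile.  Instead the
backward pass samples the $C$-dimensional slope disturbance
$\tilde\delta_{t+1} \mid \theta_{t+1}, Y_{1:t}$ — its conditional
covariance $\Sigma_{\tilde\delta} - M R \Sigma_{\tilde\delta}$ is a small
PSD matrix, square-rooted by eigendecomposition with clipping — and
reconstructs $\theta_t = G^{-1}(\theta_{t+1} - R\tilde\delta_{t+1})$
exactly ($G$ is invertible: unit-triangular trend blocks and rotations).
With $\gamma = 0$ this reproduces *exactly* constant slopes, a property the
tests assert to $10^{-10}$.  Forward filtering uses Joseph-form covariance
updates, symmetrization each step, and Cholesky solves of the innovation
system; missing observations (whole rows or single entries) skip the
measurement update.

### Numerical notes

* The diffuse prior is a proper $N(0, 10^7 I)$, exactly as specified, not
  an exact-diffuse filter.  Two consequences are worth knowing.  First,
  the *level* of the log marginal likelihood depends on $\kappa$ — each
  prior-dominated state dimension contributes about $-\frac12\log 2$ when
  $\kappa$ doubles — but the shift is constant in the parameters, so
  posteriors, smoothers, and DIC *differences* are unaffected (tested).
  Second, the first updates are ill-conditioned: roughly seven decimal
  digits of the log likelihood are consumed, which is why oracle
  agreement is asserted at $10^{-6}$ rather than machine precision.
* DIC uses the **marginal focus**: deviance $-2\log p(Y \mid \Sigma)$ with
  states integrated out, and the plug-in at the posterior mean of
  $\Sigma_\epsilon$ and $\Sigma_{\tilde\delta}$ on the natural scale.
  With latent states a DIC is only defined once this focus is chosen; the
  marginal focus is the reproducible one for DLMs and is recorded in the
  output metadata.
* One-sided 95% lower bounds are the $\lceil 0.05K \rceil$-th order
  statistic of the pooled draws (all chains pooled, as the reporting
  formula with $K = 12000$ implies); a $10^{-9}$ guard absorbs
  floating-point excess in $(1-\text{level})K$.
* The energy statistic for residual multinormality standardizes the
  residuals (center, whiten by sample covariance) and evaluates
  $E\|a - Z\|$ in closed form through the series for
  $E\sqrt{\chi^2_d(\lambda)}$; the p-value is a parametric bootstrap
  (default 500 samples) pushing standard-normal panels through the same
  standardization.

## What the generator emulates — and what it does not

`chicago_like_preset()` produces six series over 120 months that mimic the
published scale of big-city monthly incident reports: counts predominantly
in [500, 5000] (97% pooled over ten seeds), three strongly and three weakly
seasonal series, mildly declining trends, uniformly positive error
correlations (0.35), and a mix of positive (0.5–0.7), negative (−0.5), and
zero evolution correlations.  The slope-innovation scales (~$7 \times
10^{-4}$) were chosen once so that decade-long trajectories stay in that
band; counts are `round(exp(Y))` clipped at 1, because the model is
Gaussian on logs and rounding keeps generator and likelihood consistent
(Poisson observation models are a different, dynamic-generalized-linear
extension, out of scope here).  Initial slopes are kept below 0.01/month
for the same reason.

Passing tests on these simulations show the *machinery* is correct —
filter/smoother/FFBS exactness, prior correctness, recovery of a known
evolution correlation, convergence of the sampler.  They do not show that
real incident-report series follow a log-Gaussian SUTSE model: real data
bring reporting-practice discontinuities, heavy tails, population drift,
and category reclassifications that this generator deliberately omits.
The energy test on residuals is the in-model check for the Gaussian
assumption; it cannot detect misspecification of the trend structure
itself.

## Design choices where the design was open

* **Harmonic time origin**: the seasonal rotation is applied from $t = 1$
  at the first observed month; any consistent origin is equivalent because
  the phase is absorbed into the initial seasonal state.
* **Coordinate order** within a series block is (level, slope, harmonic₁,
  conjugate₁, …), blocks concatenated in input-series order, which makes
  $F$, $G$, $R$ Kronecker products and keeps indexing mechanical.
* **Pooling**: all reported probabilities/bounds pool the chains'
  inferential draws; per-chain behavior is the business of the
  diagnostics, not the summaries.
* **Trend vs fit ambiguity** in smoothed-series displays: both are
  exposed (`component = "trend"` for the level alone, `"fit"` for
  $F\theta$ including seasonality); the summarize driver writes both.
* **Count-scale intervals** exponentiate each draw and take empirical
  quantiles (simulation-consistent; the posterior mean on the count scale
  is the mean of exponentials, deliberately larger than the exponential of
  the log-scale mean).
* **Problem sizes in the test suite** were chosen as the smallest that
  exercise each claim: oracle checks on $C=2$, $T=6$, $q=1$ (a 12-variate
  joint normal is still brute-forceable); recovery on $C=3$, $T=120$,
  $q=2$ with 3×500+1000 MCMC; convergence gates on a $C=2$, $T=120$
  fixture at the full 3×1000+4000 configuration; the end-to-end run on the
  six-series preset at a reduced 2×200+300 configuration.

## Known limitations

* No gradient-based sampler: for $C \ge 4$ with several harmonics the
  fallback random-walk kernel mixes slowly; plan for long runs and check
  PSRF/ESS.  (The architecture is sampler-agnostic: anything that targets
  `log_posterior_hyper()` can be dropped in.)
* The diffuse initialization is proper, not exact-diffuse; likelihood
  *levels* are $\kappa$-dependent (see above).
* Gaussianity on logs requires counts large enough that a lognormal
  approximates a count distribution; series with frequent months below a
  few dozen incidents need the Poisson extension, not this package.
* No calendar effects (trading days, moving holidays), no time-varying
  $F$ or $G$, and no spatial structure.
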