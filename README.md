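# sutse: Bayesian SUTSE dynamic linear models for co-evolving count series

`sutse` models several parallel monthly count series — the motivating case
is city-level incident reports of different categories — as *seemingly
unrelated time series equations* (SUTSE): a multivariate Gaussian dynamic
linear model on the log counts,

```
Y_t = F θ_t + ε_t,        ε_t ~ N(0, Σ_ε)
θ_t = G θ_{t-1} + δ_t,    δ_t = R δ̃_t,  δ̃_t ~ N(0, Σ_δ̃)
```

Each series carries a **local linear trend** (level + slope; only the slope
receives innovation noise, so the level is a smooth integrated random walk)
and a **Fourier-form seasonal component** with `q ≤ s/2` harmonics
propagated by rotation blocks of `G` (at `q = s/2` the last harmonic
degenerates to a single alternating state). The series are tied together
*only* through the unstructured covariances:

* `Σ_ε` — same-month co-deviation of the observation errors
  ("error correlations");
* `Σ_δ̃` — correlation of the slope innovations ("evolution correlations"),
  the model's measure of co-moving long-term trends; the corresponding
  **partial** correlations (off-diagonal entries of the normalized negated
  inverse of `Σ_δ̃`) measure conditional trend dependence.

Inference is Bayesian: independent half-Cauchy `Ca⁺(0,1)` priors on all
standard deviations, LKJ(v = 1) priors (uniform over correlation matrices)
on both correlation matrices, and a diffuse `N(0, 10⁷ I)` prior on the
initial state. The latent states are marginalized exactly by a Kalman
filter (RcppArmadillo core), the covariance hyperparameters are sampled by
MCMC (multiple-try independence Metropolis with a mode + warm-up-refitted
mixture proposal, adaptive random-walk fallback), and state trajectories
are drawn by forward-filtering backward-sampling (FFBS) that handles the
rank-deficient evolution covariance exactly. Model comparison uses DIC
with the marginal (states-integrated) deviance; convergence is monitored
with split-chain Gelman–Rubin PSRF and autocorrelation-based ESS; residual
multinormality is checked with the energy test.

Who this is for: analysts comparing long-term trends across several
aggregated count series who want probability statements such as
`P(ρ_δ(i,j) > 0 | Y)` — "how likely is it that these two series' trends
co-evolve?" — rather than point correlations.

## Worked example

Two monthly series over ten years with one annual harmonic each, slope
innovations correlated at 0.6, fitted at the reference MCMC configuration
(3 chains × 1000 warm-up + 4000 kept; about 3 minutes on one core):

```r
library(sutse)

spec   <- build_model(n_series = 2, n_harmonics = 1)
params <- cov_params(obs_sd  = c(0.05, 0.07),
                     obs_corr = matrix(c(1, 0.4, 0.4, 1), 2),
                     evo_sd  = c(0.002, 0.003),
                     evo_corr = matrix(c(1, 0.6, 0.6, 1), 2))
init <- c(7.2, -0.001, 0.15, 0.05,   6.8, 0.002, 0.1, -0.04)
sim  <- simulate_sutse(sim_config(spec, params, init, n_months = 120,
                                  seed = 11))

post <- sample_posterior(sim$log_series, spec, seed = 1)
posterior_diagnostics(post)
#>       parameter psrf psrf_upper95  ess
#> 1       sigma_1    1            1 8419
#> ...
#> 6 rho_delta_2_1    1            1 8079

set.seed(1)
post <- sample_states(post, sim$log_series, spec)
correlation_summary(post, "evolution")
#> evolution correlations: P(rho > 0 | Y) above diagonal,
#>                         one-sided 95% lower bounds below
#>          series_1 series_2
#> series_1        -     0.89
#> series_2     -0.2        -
```

Read it as: the posterior probability that the two trends co-evolve
positively is 0.89 (the generating value was 0.6), and the one-sided 95%
credible interval for that correlation extends down to −0.2 — ten years of
monthly data leave real uncertainty about trend co-movement, which is
exactly what these tables quantify. `correlation_summary(post, "error")`
and `correlation_summary(post, "partial-evolution")` give the same layout
for the error and partial evolution correlations, and

```r
head(smoothed_series(post$state_draws, spec, scale = "count",
                     component = "trend"), 3)
#>     series month time     mean  lower95  upper95
#> 1 series_1     1    1 1304.631 1247.171 1363.681
#> 2 series_1     2    2 1302.276 1253.490 1355.029
#> 3 series_1     3    3 1299.550 1255.893 1346.538
```

returns each series' smoothed trend with pointwise 95% bands on the count
scale (the generating initial level was `exp(7.2) ≈ 1339`).
`dic(post, sim$log_series, spec)` gives the marginal-deviance DIC for
model comparison (−483.3 with `p_D` = 4.0 here).

The `analysis/` directory runs the same pipeline at full scale as numbered
drivers (`01_simulate.R` — six-series big-city preset, `02_fit.R`,
`03_summarize.R`, `04_report.R`), writing their tables under `results/`;
each accepts `--seed` and `--out-dir`. For the six-series model (42
covariance hyperparameters) the sampler falls back to adaptive random-walk
Metropolis; check `posterior_diagnostics()` and lengthen the run before
trusting the tables.

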