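#!/usr/bin/env Rscript
# Step 3: turn the posterior draws into the inferential outputs: the three
# correlation summary tables (probability of a positive correlation above
# the diagonal, one-sided 95% lower credible bounds below), smoothed trend
# and fit curves with pointwise 95% intervals on the count scale, posterior
# correlation densities, and the residual multinormality check.

suppressPackageStartupMessages({
  library(optparse)
  library(sutse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--counts", default = "results/synthetic/monthly_counts.csv"),
  make_option("--fit-dir", dest = "fit_dir", default = "results/fit"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", dest = "out_dir", default = "results/summary")
)))

dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
obs <- load_monthly_counts(opts$counts)
meta <- jsonlite::fromJSON(file.path(opts$fit_dir, "metadata.json"))
spec <- build_model(meta$model$n_series, meta$model$n_harmonics,
                    meta$model$period)

# reassemble a posterior object from the saved tables
draws <- utils::read.csv(file.path(opts$fit_dir, "posterior_draws.csv"))
long <- utils::read.csv(file.path(opts$fit_dir, "state_draws.csv"))
nd <- max(long$draw)
state_draws <- array(long$value[order(long$coord, long$time, long$draw)],
                     c(nd, max(long$time) + 1L, max(long$coord)))
post <- structure(list(chains = list(draws), n_series = spec$n_series,
                       priors = prior_spec(), series_names = obs$series_names,
                       config = meta$mcmc, state_draws = state_draws),
                  class = "sutse_posterior")

for (kind in c("evolution", "error", "partial-evolution")) {
  tab <- correlation_summary(post, kind)
  print(tab)
  stem <- file.path(opts$out_dir, paste0("corr_", gsub("-", "_", kind)))
  utils::write.csv(round(tab$table, 3), paste0(stem, ".csv"))
  utils::write.csv(tab$long, paste0(stem, "_long.csv"), row.names = FALSE)
}

for (component in c("trend", "fit")) {
  tab <- smoothed_series(post$state_draws, spec, scale = "count",
                         component = component, months = obs$months,
                         series_names = obs$series_names)
  utils::write.csv(tab, file.path(opts$out_dir,
                                  paste0("smoothed_", component, ".csv")),
                   row.names = FALSE)
}

# posterior evolution-correlation densities on a common grid
dens <- do.call(rbind, lapply(grep("^rho_delta", names(draws), value = TRUE),
  function(nm) {
    ds <- density_summary(draws[[nm]])
    data.frame(parameter = nm, grid = ds$grid, density = ds$density,
               median = ds$median)
  }))
utils::write.csv(dens, file.path(opts$out_dir, "evolution_corr_densities.csv"),
                 row.names = FALSE)

res <- fit_residuals(obs, post$state_draws, spec)
set.seed(opts$seed)
en <- energy_normality_test(res, n_boot = 500)
cat(sprintf("energy test of residual multinormality: statistic %.3f, p = %.3f\n",
            en$statistic, en$p_value))
utils::write.csv(data.frame(statistic = en$statistic, p_value = en$p_value),
                 file.path(opts$out_dir, "energy_test.csv"), row.names = FALSE)
cat("wrote summary tables to", opts$out_dir, "\n")
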