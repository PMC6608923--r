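#!/usr/bin/env Rscript
# Step 4 (optional): render simple PNG panels of the smoothed trends with
# 95% bands and the posterior evolution-correlation densities.

suppressPackageStartupMessages({
  library(optparse)
  library(sutse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--summary-dir", dest = "summary_dir",
              default = "results/summary"),
  make_option("--out-dir", dest = "out_dir", default = "results/figures")
)))

dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
trend <- utils::read.csv(file.path(opts$summary_dir, "smoothed_trend.csv"))
series <- unique(trend$series)

grDevices::png(file.path(opts$out_dir, "smoothed_trends.png"),
               width = 1200, height = 800)
graphics::par(mfrow = c(ceiling(length(series) / 2), 2),
              mar = c(3, 4, 2, 1))
for (s in series) {
  d <- trend[trend$series == s, ]
  graphics::plot(d$time, d$mean, type = "l", lwd = 2, ylab = "monthly count",
                 xlab = "", main = s, ylim = range(d$lower95, d$upper95))
  graphics::lines(d$time, d$lower95, lty = 2)
  graphics::lines(d$time, d$upper95, lty = 2)
}
grDevices::dev.off()

dens <- utils::read.csv(file.path(opts$summary_dir,
                                  "evolution_corr_densities.csv"))
pars <- unique(dens$parameter)
grDevices::png(file.path(opts$out_dir, "evolution_corr_densities.png"),
               width = 1200, height = 800)
graphics::par(mfrow = c(ceiling(length(pars) / 3), 3), mar = c(3, 4, 2, 1))
for (pn in pars) {
  d <- dens[dens$parameter == pn, ]
  graphics::plot(d$grid, d$density, type = "l", lwd = 2, xlab = "",
                 ylab = "density", main = pn)
  graphics::abline(v = d$median[1], lty = 2)
  graphics::abline(v = 0, col = "grey")
}
grDevices::dev.off()
cat("wrote figures to", opts$out_dir, "\n")
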