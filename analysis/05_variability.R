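#!/usr/bin/env Rscript
# Variability analysis per differentiation stage: bootstrap confidence
# intervals for median spot intensity, Fano factors, Fano-versus-mean
# regressions with slope ratios against the pooled regression, the share
# of intensity variance explained by ON fraction, and Mann-Whitney
# comparisons between early, peak and late stages.

suppressPackageStartupMessages(library(burststage))
cfg <- read_config("results/config.yaml")
traces <- read_traces_csv("results/traces.csv")
staged <- read.csv("results/staged_cells.csv", stringsAsFactors = FALSE)
summary <- read.csv("results/burst_summary.csv", stringsAsFactors = FALSE)

summary <- merge(summary, staged[, c("cell_id", "stage", "position")],
                 by = "cell_id")
summary$fano <- vapply(traces[summary$cell_id],
                       function(tr) fano_factor(tr)$fano, numeric(1))
n_excl <- sum(!is.finite(summary$fano))
if (n_excl > 0)
  cat(sprintf("excluded %d cells with non-positive mean from Fano analyses\n",
              n_excl))

stages <- sort(unique(summary$stage))
stats <- do.call(rbind, lapply(seq_along(stages), function(i) {
  rows <- summary[summary$stage == stages[i], ]
  ci <- bootstrap_median_ci(rows$mean_intensity,
                            subsample_n = cfg$bootstrap_n,
                            n_resamples = cfg$bootstrap_resamples,
                            seed = cfg$seed + i)
  slope <- tryCatch(fano_mean_regression(rows$mean_intensity,
                                         rows$fano)$slope,
                    error = function(e) NA_real_)
  data.frame(stage = stages[i], n = nrow(rows),
             median_mean_intensity = ci$point_median,
             ci_low = ci$ci_low, ci_high = ci$ci_high,
             median_on_fraction = median(rows$on_fraction),
             fano_slope = slope)
}))
ok <- is.finite(summary$fano)
pooled <- fano_mean_regression(summary$mean_intensity[ok],
                               summary$fano[ok])$slope
stats$slope_ratio <- relative_variability(stats$fano_slope, pooled)
write.csv(stats, "results/stage_stats.csv", row.names = FALSE)
print(stats, digits = 3)

r2 <- explained_variance(summary$on_fraction, summary$mean_intensity)
cat(sprintf(
  "ON fraction explains %.0f%% of the variance in mean spot intensity\n",
  100 * r2))

tests <- rbind(
  cbind(metric = "mean_intensity",
        compare_stages(split(summary$mean_intensity, summary$stage))),
  cbind(metric = "on_fraction",
        compare_stages(split(summary$on_fraction, summary$stage))))
write.csv(tests, "results/pairwise_tests.csv", row.names = FALSE)
print(tests, digits = 3)
cat("wrote results/stage_stats.csv, results/pairwise_tests.csv\n")
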