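#!/usr/bin/env Rscript
# Stage 5: tests of neutrality at locus and genome scale.
#
# Per-locus S, k_hat, theta_W, theta_T and Tajima's D with the beta
# approximation test (BH-corrected within each estuary); genome-wide null
# distributions of D from fixed-S constant-size coalescents (250 replicates
# per estuary for desk time; the study convention is 1,000); Mann-Whitney
# comparisons of per-locus theta between estuaries and basins.

library(microhapgen)

seed <- 20260929L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 1) seed <- as.integer(args[1])
R <- 250L

ds <- load_dataset("results/data/haplotypes.tsv", "results/data/metadata.csv")
ds <- filter_dataset(ds, min_group_n = 18L)

set.seed(stage_seed(seed, "neutrality"))
stats <- dataset_neutrality(ds, "estuary")
write.table(stats, "results/neutrality_per_locus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- summarize_neutrality(stats)
cat(sprintf("loci significant in >= 1 estuary (raw p): %d (+%d / -%d / both %d)\n",
            summ$raw$n_any, summ$raw$n_positive, summ$raw$n_negative,
            summ$raw$n_both))
cat(sprintf("after BH by estuary: %d\n", summ$bh$n_any))

gw_rows <- list()
for (est in unique(stats$group)) {
  gw <- genome_wide_null_test(stats[stats$group == est, ], R = R)
  gw_rows[[est]] <- data.frame(
    estuary = est, observed_mean = gw$observed_mean,
    observed_median = gw$observed_median,
    null_mean = mean(gw$replicate_means),
    p_mean_lower = gw$p_mean_lower, p_median_lower = gw$p_median_lower,
    n_loci = gw$n_loci)
  cat(sprintf("%-6s mean D %+0.3f vs null %+0.3f  p(mean lower) = %.3g\n",
              est, gw$observed_mean, mean(gw$replicate_means), gw$p_mean_lower))
}
write.table(do.call(rbind, gw_rows), "results/genome_wide_D_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

theta_est <- compare_theta(stats)
write.table(theta_est, "results/theta_comparisons_estuary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
basin_stats <- dataset_neutrality(ds, "basin")
theta_basin <- compare_theta(basin_stats)
cat("basin theta_W Mann-Whitney p:",
    theta_basin$p[theta_basin$estimator == "theta_W"], "\n")
write.table(theta_basin, "results/theta_comparisons_basin.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
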