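#!/usr/bin/env Rscript
# Stage 6: landscape genomics in the Gulf.
#
# Allele dosages for all Gulf individuals (no >= 18 filter here, matching
# the study's RDA design), PCA of the 39 environmental variables, forward
# selection of environmental PCs and of a spatial polynomial of coastal
# distance (degree up to 5), variance partitioning between environment and
# space, and Mahalanobis flagging (D^2 > 25) of environment-associated
# alleles with linkage-group annotation.

library(microhapgen)

seed <- 20260929L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 1) seed <- as.integer(args[1])
n_perm <- 499L

ds <- load_dataset("results/data/haplotypes.tsv", "results/data/metadata.csv",
                   "results/data/environment.csv", "results/data/linkage_map.csv")
gulf_ids <- ds$metadata$individual_id[ds$metadata$basin == "gulf"]
md <- ds$metadata[match(gulf_ids, ds$metadata$individual_id), ]

set.seed(stage_seed(seed, "rda"))
Y <- code_alleles(ds$genotypes, gulf_ids)
cat("response:", nrow(Y$matrix), "individuals x", ncol(Y$matrix), "allele columns\n")

pc <- env_pca(ds$env[ds$env$estuary %in% unique(md$estuary), ])
scores_ind <- pc$scores[match(md$estuary, rownames(pc$scores)), , drop = FALSE]
sel_env <- forward_select(Y, scores_ind, n_perm = n_perm)
cat("selected environmental PCs:", paste(sel_env$selected, collapse = ", "), "\n")

sp_full <- spatial_design(md$coastal_distance_km, degree = 5L, jitter_sd_km = 2)
sel_xy <- forward_select(Y, sp_full, n_perm = n_perm)
cat("selected spatial polynomial terms:", paste(sel_xy$selected, collapse = ", "), "\n")

X_env <- scores_ind[, sel_env$selected, drop = FALSE]
if (!ncol(X_env)) X_env <- scores_ind[, 1:2]
X_xy <- sp_full[, sel_xy$selected, drop = FALSE]
if (!ncol(X_xy)) X_xy <- sp_full[, 1:3]

set.seed(stage_seed(seed, "varpart"))
vp <- varpart(Y, X_env, X_xy, n_perm = n_perm)
tab4 <- data.frame(
  partition = c("residuals", "env + shared", "env + xy + shared", "shared",
                "xy + shared", "env", "xy"),
  adjR2 = c(vp$residual, vp$adjR2_env_total, vp$adjR2_full, vp$shared,
            vp$adjR2_xy_total, vp$env_unique, vp$xy_unique),
  p = c(NA, vp$p_env_total, vp$p_full, NA, vp$p_xy_total,
        vp$p_env_unique, vp$p_xy_unique))
print(tab4, digits = 3)
write.table(tab4, "results/varpart_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

set.seed(stage_seed(seed, "gea"))
env_model <- rda_fit(Y, X_env, n_perm = n_perm)
cat(sprintf("environmental model: R2 = %.4g, adjR2 = %.4g, p = %.3g\n",
            env_model$R2, env_model$adjR2, env_model$p_perm))
fl <- mahalanobis_flags(env_model, threshold = 25, map = ds$map)
cat("alleles flagged (D^2 > 25):", sum(fl$table$flagged),
    "| loci:", length(fl$flagged_loci), "\n")
write.table(fl$table, "results/gea_allele_loadings.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(fl$linkage_group_counts)) {
  write.table(fl$linkage_group_counts, "results/gea_linkage_groups.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(data.frame(individual = gulf_ids,
                       env_model$site_scores[, 1:2]),
            "results/rda_site_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
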