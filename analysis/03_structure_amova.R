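#!/usr/bin/env Rscript
# Stage 3: population structure.
#
# Hierarchical locus-by-locus AMOVA (estuaries nested in basins), single
# level AMOVA within each basin, and pairwise F_ST with BH correction.
# 1,000 permutations keep the stage in desk time (the study convention is
# 10,000; p-value resolution scales accordingly).

library(microhapgen)

seed <- 20260929L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 1) seed <- as.integer(args[1])
n_perm <- 1000L

ds <- load_dataset("results/data/haplotypes.tsv", "results/data/metadata.csv")
ds <- filter_dataset(ds, min_group_n = 18L)
pops <- assignment(ds, "estuary")
basin_of <- with(unique(ds$metadata[, c("estuary", "basin")]),
                 setNames(basin, estuary))

set.seed(stage_seed(seed, "amova"))
hier <- amova(ds$genotypes, pops, groups = basin_of, n_perm = n_perm)
print(hier)
tab2 <- data.frame(
  source = c("among_basins", "among_estuaries_within_basins",
             "within_estuaries"),
  percent_variation = unname(hier$percent_variation),
  F_statistic = c(hier$f_ct, hier$f_sc, hier$f_st),
  p = c(hier$p_f_ct, hier$p_f_sc, hier$p_f_st))
write.table(tab2, "results/amova_hierarchical.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (b in unique(basin_of)) {
  keep <- names(pops)[basin_of[pops] == b]
  if (length(unique(pops[keep])) < 2) next
  g <- microhapgen:::.subset_genotypes(ds$genotypes, keep)
  res <- amova(g, pops[keep], n_perm = n_perm)
  cat(sprintf("%s single-level F_ST = %.4f (p = %.4g)\n", b, res$fst, res$p_fst))
}

set.seed(stage_seed(seed, "pairwise_fst"))
pw <- pairwise_fst(ds$genotypes, pops, n_perm = n_perm)
write.table(round(pw$fst, 5), "results/pairwise_fst.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(round(pw$q_bh, 5), "results/pairwise_fst_q.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
sig <- sum(pw$q_bh < 0.05, na.rm = TRUE) / 2
cat("significant pairs after BH:", sig, "of", choose(nrow(pw$fst), 2), "\n")
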