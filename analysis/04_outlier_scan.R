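#!/usr/bin/env Rscript
# Stage 4: F_ST outlier scan.
#
# fdist-style scan under a strict island model, run within each basin
# (the study's within-basin scans found no outliers) with individuals
# grouped by estuary. Desk-time choices, stated here: estuaries are
# subsampled to 18 individuals for the scan (the filter floor; background
# within-basin F_ST is tiny, so the calibrated island model is extremely
# migration-heavy and cost scales with gene copies), with 5,000 simulated
# loci over 50 demes. The study conventions are all individuals, 20,000
# simulations, and these are plain function arguments. The consensus
# partition intersects our flags with an optional external flag list
# (results/external_outliers.txt, one locus id per line); absent, the
# partition is conservative (all neutral).

library(microhapgen)

seed <- 20260929L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 1) seed <- as.integer(args[1])

ds <- load_dataset("results/data/haplotypes.tsv", "results/data/metadata.csv")
ds <- filter_dataset(ds, min_group_n = 18L)
pops <- assignment(ds, "estuary")
basin_of <- with(unique(ds$metadata[, c("estuary", "basin")]),
                 setNames(basin, estuary))

set.seed(stage_seed(seed, "outliers"))
flagged_any <- character()
for (b in unique(basin_of)) {
  keep <- names(pops)[basin_of[pops] == b]
  if (length(unique(pops[keep])) < 2) next
  keep <- unlist(lapply(split(keep, pops[keep]), head, 18L), use.names = FALSE)
  g <- microhapgen:::.subset_genotypes(ds$genotypes, keep)
  scan <- fdist_scan(g, pops[keep], n_sims = 5000L, d_sim = 50L)
  out <- scan$table
  cat(sprintf("%s: global F_ST %.4f, calibrated M %.1f, %d loci flagged\n",
              b, scan$meta$global_fst, scan$meta$M, sum(out$flagged)))
  write.table(out, sprintf("results/outlier_scan_%s.tsv", b), sep = "\t",
              quote = FALSE, row.names = FALSE)
  flagged_any <- union(flagged_any, out$locus_id[out$flagged])
}

ext <- "results/external_outliers.txt"
all_ids <- vapply(ds$genotypes$loci, `[[`, "", "locus_id")
part <- partition_loci(flagged_any,
                       if (file.exists(ext)) ext else character(), all_ids)
cat("consensus outliers:", length(part$outlier_set),
    "| neutral:", length(part$neutral_set), "\n")
writeLines(part$outlier_set, "results/consensus_outlier_loci.txt")
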