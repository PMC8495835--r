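#!/usr/bin/env Rscript
# Stage 2: per-estuary genomic diversity.
#
# Nei's gene diversity, rarefied allele counts (per-locus minimum depth) and
# E5 evenness for estuaries with >= 18 individuals; Friedman tests of
# homogeneity with pairwise Wilcoxon signed-rank post hocs (BH-corrected);
# fixed-allele sets and their exclusive intersections.

library(microhapgen)

ds <- load_dataset("results/data/haplotypes.tsv", "results/data/metadata.csv",
                   "results/data/environment.csv", "results/data/linkage_map.csv")
ds <- filter_dataset(ds, min_group_n = 18L)
grp <- assignment(ds, "estuary")

rec <- diversity_records(ds$genotypes, grp)
write.table(rec, "results/diversity_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (metric in c("H", "A_g", "E5")) {
  cmp <- compare_diversity(rec, metric)
  cat(sprintf("%-4s Friedman Q[%d] = %.1f, p = %.3g (%d complete loci)\n",
              metric, cmp$friedman$df, cmp$friedman$Q, cmp$friedman$p,
              cmp$n_blocks))
  write.table(cmp$pairwise, sprintf("results/diversity_pairwise_%s.tsv", metric),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

fa <- fixed_allele_analysis(ds$genotypes, grp)
write.table(fa$intersections, "results/fixed_allele_intersections.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(fa$global_diversity)) {
  write.table(fa$global_diversity, "results/fixed_allele_global_diversity.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("fixed loci per estuary:",
    paste(names(fa$fixed_sets), lengths(fa$fixed_sets), sep = "=", collapse = " "),
    "\n")
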