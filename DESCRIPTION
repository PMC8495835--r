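Package: microhapgen
Title: Population Genomics of Multiallelic Microhaplotype Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis stack for RAD-derived microhaplotype genotypes in a
    hierarchical sampling design (populations nested in regions): data model
    and readers for haplotype tables, phased VCF collapsing, Nei gene
    diversity, rarefied allele counts and evenness, hierarchical locus-by-locus
    AMOVA with permutation tests, pairwise F_ST, an fdist-style F_ST outlier
    scan under a strict island model, per-locus and genome-wide Tajima's D
    tests against fixed-S coalescent null distributions, redundancy-analysis
    landscape genomics with forward selection, variance partitioning and
    Mahalanobis genotype-environment flagging, plus a coalescent scenario
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
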