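# Data model, haplotype-table IO, filtering, BH adjustment.

test_that("haplotype table round-trips calls and allele catalogues", {
  g <- toy_genotypes()
  path <- withr::local_tempfile()
  write_haplotype_table(g, path)
  g2 <- read_haplotype_table(path)
  expect_identical(g2$a1, g$a1)
  expect_identical(g2$a2, g$a2)
  expect_identical(lapply(g2$loci, `[[`, "alleles"),
                   lapply(g$loci, `[[`, "alleles"))

  set.seed(404)
  est <- default_paperlike_config()$estuaries[c(1, 10), ]
  est$n_ind <- c(5L, 4L)
  sc <- generate_scenario(scenario_config(est, n_loci = 15L, missing_rate = 0.1))
  p2 <- withr::local_tempfile()
  write_haplotype_table(sc$dataset$genotypes, p2)
  back <- read_haplotype_table(p2)
  expect_identical(back$a1, sc$dataset$genotypes$a1)
  expect_identical(back$a2, sc$dataset$genotypes$a2)
})

test_that("load_dataset cross-references ids and tracks gene copies", {
  g <- toy_genotypes()
  gp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_haplotype_table(g, gp)
  write.csv(toy_metadata(), mp, row.names = FALSE, quote = FALSE)
  ds <- load_dataset(gp, mp)
  expect_s3_class(ds, "mh_dataset")
  expect_equal(unname(gene_copies(ds$genotypes)), c(6L, 6L))

  # one missing call reduces n at that locus only
  g$a1[1, 2] <- NA; g$a2[1, 2] <- NA
  write_haplotype_table(g, gp)
  ds <- load_dataset(gp, mp)
  expect_equal(unname(gene_copies(ds$genotypes)), c(4L, 6L))

  # unknown individual in metadata is an error, not a silent drop
  md_bad <- rbind(toy_metadata(), data.frame(
    individual_id = "ghost", estuary = "E9", basin = "gulf",
    life_stage = "yoy", coastal_distance_km = 1))
  write.csv(md_bad, mp, row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(gp, mp), "mismatch")
})

test_that("malformed inputs are format errors", {
  expect_error(mh_locus("L1", "c", c("AX")), "non-ACGT")
  expect_error(mh_locus("L1", "c", c("AA", "AA")), "duplicated")
  expect_error(mh_locus("L1", "c", c("AA", "ACG")), "length")
  g <- toy_genotypes()
  path <- withr::local_tempfile()
  write_haplotype_table(g, path)
  tab <- readLines(path)
  writeLines(c(tab, tab[2]), path)  # duplicate locus row
  expect_error(read_haplotype_table(path), "duplicated locus_id")
})

test_that("filter_dataset applies the >= 18 rule to the study's sample sizes", {
  # Figure-1 sample sizes: 9 of 15 estuaries have >= 18 individuals
  cfg <- default_paperlike_config()
  sizes <- cfg$estuaries
  set.seed(11)
  sc <- generate_scenario(scenario_config(sizes, n_loci = 4L,
                                          missing_rate = 0))
  ds <- sc$dataset
  f <- filter_dataset(ds, min_group_n = 18L)
  expect_equal(sort(unique(f$metadata$estuary)),
               sort(c("SA", "SL", "BB", "WMS", "MB", "AP", "SJR", "CH", "WB")))
  expect_equal(length(unique(f$metadata$estuary)), 9L)

  # min_group_n = 1 is the identity on groups; filtering is idempotent
  f1 <- filter_dataset(ds, min_group_n = 1L)
  expect_equal(sort(unique(f1$metadata$estuary)), sort(unique(ds$metadata$estuary)))
  f2 <- filter_dataset(f, min_group_n = 18L)
  expect_identical(f2$genotypes$a1, f$genotypes$a1)
  expect_identical(f2$metadata, f$metadata)
})

test_that("max_locus_missing = 0 drops any locus with a missing call", {
  g <- toy_genotypes()
  g$a1[1, 2] <- NA; g$a2[1, 2] <- NA
  ds <- mh_dataset(g, toy_metadata())
  f <- filter_dataset(ds, min_group_n = 1L, max_locus_missing = 0)
  expect_equal(length(f$genotypes$loci), 1L)
  expect_equal(f$genotypes$loci[[1]]$locus_id, "L2")
  expect_error(filter_dataset(ds, min_group_n = 99L), "every estuary")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # order preserved, monotone on sorted input
  p <- c(0.04, 0.001, 0.2, 0.03)
  q <- bh_adjust(p)
  expect_equal(q[order(p)], bh_adjust(sort(p)))
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("genepop export uses 3-digit codes in catalogue order", {
  g <- toy_genotypes()
  pops <- setNames(c("a", "a", "b"), g$individuals)
  path <- withr::local_tempfile()
  write_genepop(g, pops, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "Pop"), 2L)
  expect_match(lines[5], "^i1 , 001002 001002$")
})
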