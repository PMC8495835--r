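# Diversity metrics: closed forms, rarefaction properties, evenness, fixed
# alleles, Friedman/Wilcoxon comparisons.

test_that("closed-form diversity values are exact", {
  expect_equal(nei_gene_diversity(c(2, 2)), 2 / 3)
  expect_equal(nei_gene_diversity(c(4, 0)), 0)
  expect_equal(rarefied_allele_count(c(9, 1), 2), 1.2)
  expect_equal(rarefied_allele_count(c(9, 1), 10), 2)
  expect_equal(rarefied_allele_count(c(3, 5, 2), 1), 1)
  expect_equal(evenness_e5(c(3, 1)), 0.795, tolerance = 1e-3)
  expect_equal(as.numeric(evenness_e5(c(5, 5))), 1)
  expect_error(rarefied_allele_count(c(2, 2), 5), "\\[1, N\\]")
})

test_that("large-n equifrequent diversity approaches 1 - 1/k", {
  for (k in c(2, 5, 10)) {
    expect_equal(nei_gene_diversity(rep(1e6, k)), 1 - 1 / k, tolerance = 1e-5)
  }
})

test_that("rarefaction is monotone in g and matches the A2 identity", {
  counts <- c(12, 5, 2, 1)
  N <- sum(counts)
  ag <- vapply(1:N, function(g) rarefied_allele_count(counts, g), 0)
  expect_true(all(diff(ag) >= -1e-12))
  expect_equal(ag[N], 4)
  # A_2 - 1 = 1 - sum C(N_i,2)/C(N,2)
  expect_equal(ag[2] - 1, 1 - sum(choose(counts, 2)) / choose(N, 2))
})

test_that("evenness is scale-invariant and depressed by dominance", {
  expect_equal(evenness_e5(c(30, 10)), evenness_e5(c(0.75, 0.25)))
  # direct evaluation: lambda = 0.9802, H' = 0.0560 -> E5 = 0.3507
  expect_equal(evenness_e5(c(99, 1)), 0.3507, tolerance = 1e-3)
  expect_lt(evenness_e5(c(99, 1)), evenness_e5(c(75, 25)))
  expect_true(attr(evenness_e5(c(7, 0)), "monomorphic"))
})

test_that("fixed-allele sets recover a planted fixation pattern", {
  # 4 loci: fixed in A only, fixed in B only, fixed in both, polymorphic
  loci <- lapply(1:4, function(l) mh_locus(paste0("L", l), "c", c("AA", "CC")))
  # pops A (i1, i2), B (i3, i4)
  a1 <- rbind(c(1L, 1L, 1L, 2L),   # A fixed, B polymorphic
              c(1L, 2L, 2L, 2L),   # A polymorphic, B fixed
              c(1L, 1L, 1L, 1L),   # fixed everywhere
              c(1L, 2L, 1L, 2L))   # polymorphic in both
  a2 <- rbind(c(1L, 1L, 2L, 2L),
              c(2L, 1L, 2L, 2L),
              c(1L, 1L, 1L, 1L),
              c(2L, 1L, 2L, 1L))
  g <- mh_genotypes(paste0("i", 1:4), loci, a1, a2)
  pops <- setNames(c("A", "A", "B", "B"), g$individuals)
  fa <- fixed_allele_analysis(g, pops)
  expect_setequal(fa$fixed_sets$A, c("L1", "L3"))
  expect_setequal(fa$fixed_sets$B, c("L2", "L3"))
  inter <- setNames(fa$intersections$count, fa$intersections$combination)
  expect_equal(unname(inter["A"]), 1)
  expect_equal(unname(inter["B"]), 1)
  expect_equal(unname(inter["A+B"]), 1)
  # inclusion-exclusion consistency: per-set sizes recovered from combos
  expect_equal(sum(inter[c("A", "A+B")]), length(fa$fixed_sets$A))
})

test_that("Friedman/Wilcoxon comparisons: null calibration and power", {
  set.seed(501)
  # identical groups: all paired differences zero -> Wilcoxon p = 1
  rec <- data.frame(group = rep(c("A", "B"), each = 20),
                    locus_id = rep(sprintf("L%02d", 1:20), 2),
                    H = rep(runif(20), 2))
  cmp <- compare_diversity(rec, "H")
  expect_equal(cmp$pairwise$p, 1)
  # a uniformly shifted group is detected
  rec2 <- rec
  rec2$H[rec2$group == "B"] <- rec2$H[rec2$group == "B"] + 0.2
  cmp2 <- compare_diversity(rec2, "H")
  expect_lt(cmp2$friedman$p, 0.001)
  expect_lt(cmp2$pairwise$q_bh, 0.001)
  # null rejection rate near alpha over label permutations
  set.seed(502)
  rej <- replicate(150, {
    h <- matrix(runif(60), 30, 2)
    r <- data.frame(group = rep(c("A", "B"), each = 30),
                    locus_id = rep(sprintf("L%02d", 1:30), 2),
                    H = c(h[, 1], h[, 2]))
    compare_diversity(r, "H")$friedman$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.06)
})

test_that("Friedman statistic is invariant to monotone per-block transforms", {
  set.seed(503)
  h <- matrix(runif(40), 20, 2)
  mk <- function(vals) data.frame(group = rep(c("A", "B"), each = 20),
                                  locus_id = rep(sprintf("L%02d", 1:20), 2),
                                  H = c(vals[, 1], vals[, 2]))
  q1 <- compare_diversity(mk(h), "H")$friedman$Q
  # per-block monotone transform: add a block-specific offset and cube
  h2 <- (h + rowMeans(h))^3
  q2 <- compare_diversity(mk(h2), "H")$friedman$Q
  expect_equal(q1, q2)
})

test_that("diversity_records uses the per-locus minimum depth", {
  g <- toy_genotypes()
  pops <- setNames(c("A", "A", "B"), g$individuals)
  rec <- diversity_records(g, pops)
  expect_true(all(rec$g == 2))
  expect_true(all(rec$A_g >= 1 & rec$A_g <= 2))
  expect_true(all(rec$H >= 0 & rec$H <= 1))
})
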