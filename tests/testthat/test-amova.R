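# AMOVA engine against the brute-force double-sum oracle, F-statistic
# semantics, permutation calibration, pairwise F_ST.

test_that("single-level components equal the brute-force oracle", {
  set.seed(301)
  for (rep in 1:5) {
    sim <- random_genotypes(L = 3, n_per_pop = c(3, 2, 4), n_alleles = 4,
                            missing = 0.1)
    res <- amova(sim$geno, sim$pops, n_perm = 0)
    oracle <- brute_amova(sim$geno, sim$pops)
    expect_equal(sum(res$per_locus$sigma_among), oracle$sigma_among,
                 tolerance = 1e-12)
    expect_equal(sum(res$per_locus$sigma_within), oracle$sigma_within,
                 tolerance = 1e-12)
    expect_equal(res$fst, oracle$fst, tolerance = 1e-12)
  }
})

test_that("hierarchical components equal the brute-force oracle", {
  set.seed(302)
  groups <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  for (rep in 1:5) {
    sim <- random_genotypes(L = 3, n_per_pop = c(3, 4, 3, 5), n_alleles = 3,
                            missing = 0.05)
    res <- amova(sim$geno, sim$pops, groups = groups, n_perm = 0)
    oracle <- brute_amova(sim$geno, sim$pops, groups)
    expect_equal(res$f_ct, oracle$f_ct, tolerance = 1e-12)
    expect_equal(res$f_sc, oracle$f_sc, tolerance = 1e-12)
    expect_equal(res$f_st, oracle$f_st, tolerance = 1e-12)
    expect_equal(sum(res$percent_variation), 100, tolerance = 1e-9)
  }
})

test_that("fixed differences give F_ST = 1, identical pools give F_ST <= 0", {
  loci <- list(mh_locus("L1", "c", c("AA", "CC")))
  a <- matrix(rep(c(1L, 2L), each = 3), 1, 6)
  g <- mh_genotypes(paste0("i", 1:6), loci, a, a)
  pops <- setNames(rep(c("x", "y"), each = 3), g$individuals)
  expect_equal(amova(g, pops, n_perm = 0)$fst, 1)

  # identical allele-count vectors in both populations
  a1 <- matrix(c(1L, 1L, 2L, 1L, 1L, 2L), 1, 6)
  a2 <- matrix(c(1L, 2L, 2L, 1L, 2L, 2L), 1, 6)
  g2 <- mh_genotypes(paste0("i", 1:6), loci, a1, a2)
  res <- amova(g2, pops, n_perm = 0)
  expect_lte(res$fst, 0)
  expect_true(res$negative_components)
})

test_that("F-statistics are invariant to allele relabeling and order", {
  set.seed(303)
  sim <- random_genotypes(L = 2, n_per_pop = c(4, 4), n_alleles = 3)
  res <- amova(sim$geno, sim$pops, n_perm = 0)
  # relabel alleles 1<->3 at locus 1
  g2 <- sim$geno
  sw <- function(m) { m[1, ] <- c(3L, 2L, 1L)[m[1, ]]; m }
  g2 <- mh_genotypes(g2$individuals, g2$loci, sw(g2$a1), sw(g2$a2))
  expect_equal(amova(g2, sim$pops, n_perm = 0)$fst, res$fst)
  # reorder individuals
  ord <- sample(sim$geno$individuals)
  g3 <- microhapgen:::.subset_genotypes(sim$geno, ord)
  expect_equal(amova(g3, sim$pops, n_perm = 0)$fst, res$fst)
})

test_that("hierarchical with a single group collapses to single-level", {
  set.seed(304)
  sim <- random_genotypes(L = 2, n_per_pop = c(4, 3, 5), n_alleles = 3)
  single <- amova(sim$geno, sim$pops, n_perm = 0)
  expect_message(
    hier <- amova(sim$geno, sim$pops,
                  groups = c(p1 = "g", p2 = "g", p3 = "g"), n_perm = 0),
    "single group")
  expect_equal(hier$fst, single$fst)
})

test_that("permutation p is uniform under a true null", {
  set.seed(305)
  pvals <- replicate(120, {
    sim <- random_genotypes(L = 2, n_per_pop = c(5, 5), n_alleles = 3)
    amova(sim$geno, sim$pops, n_perm = 49)$p_fst
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise F_ST: duplicated labels give near-zero F and BH matrices", {
  set.seed(306)
  sim <- random_genotypes(L = 10, n_per_pop = c(6, 6), n_alleles = 4)
  # split p1 into two identically distributed halves
  pops <- sim$pops
  pops[1:3] <- "p1a"; pops[4:6] <- "p1b"
  res <- pairwise_fst(sim$geno, pops, n_perm = 99)
  expect_lt(abs(res$fst["p1a", "p1b"]), 0.15)
  expect_true(is.na(res$fst["p1a", "p1a"]))
  expect_equal(res$fst, t(res$fst))
  up <- upper.tri(res$q_bh)
  expect_equal(sort(res$q_bh[up]), sort(bh_adjust(res$p_raw[up])))
})

test_that("locus components add over loci (concatenation additivity)", {
  set.seed(307)
  sim <- random_genotypes(L = 4, n_per_pop = c(4, 4), n_alleles = 3)
  full <- amova(sim$geno, sim$pops, n_perm = 0)
  parts <- vapply(1:4, function(l) {
    gl <- mh_genotypes(sim$geno$individuals, sim$geno$loci[l],
                       sim$geno$a1[l, , drop = FALSE],
                       sim$geno$a2[l, , drop = FALSE])
    res <- amova(gl, sim$pops, n_perm = 0)
    c(res$sigma2["among_pops"], res$sigma2["within_pops"])
  }, numeric(2))
  expect_equal(sum(parts[1, ]), unname(full$sigma2["among_pops"]))
  expect_equal(sum(parts[2, ]), unname(full$sigma2["within_pops"]))
})
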