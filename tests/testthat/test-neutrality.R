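# Tajima constants, per-locus statistics, beta test, genome-wide null test,
# theta comparisons.

test_that("Tajima constants match hand evaluation at n = 4", {
  tc <- tajima_constants(4)
  expect_equal(tc$a1, 1 + 1/2 + 1/3)
  expect_equal(tc$e1, 0.00551, tolerance = 1e-3)
  expect_equal(tc$e2, 0.002689, tolerance = 1e-3)
  expect_error(tajima_constants(3), "n >= 4")
  # a1 strictly increasing; asymptotically log(n) + gamma
  a1s <- vapply(4:10, function(n) tajima_constants(n)$a1, 0)
  expect_true(all(diff(a1s) > 0))
  n <- 1e4
  expect_equal(tajima_constants(n)$a1, log(n) + 0.5772157, tolerance = 1e-4)
})

test_that("locus_stats reproduces the hand-worked example", {
  # gene copies {AC, AC, AT, GT}: k_hat = 7/6, theta_W = 2/a1(4), D ~ +0.592
  st <- locus_stats(c("AC", "AT", "GT"), c(2, 1, 1))
  expect_equal(st$n, 4)
  expect_equal(st$S, 2L)
  expect_equal(st$k_hat, 7 / 6)
  expect_equal(st$theta_W, 2 / (1 + 1/2 + 1/3))
  expect_equal(st$D, 0.592, tolerance = 1e-3)
  expect_equal(st$sign, "positive")
})

test_that("monomorphic and n = 2 edge cases behave", {
  st <- locus_stats(c("AAAA"), 5)
  expect_equal(st$S, 0L)
  expect_true(is.na(st$D))
  expect_equal(st$theta_W, 0)
  expect_equal(st$theta_T, 0)
  expect_equal(st$sign, "undefined")
  # n = 2: a1 = 1 so k_hat = S = theta_W
  st2 <- locus_stats(c("AAA", "CCC"), c(1, 1))
  expect_equal(st2$S, 3L)
  expect_equal(st2$k_hat, 3)
  expect_equal(st2$theta_W, 3)
})

test_that("site-matrix and haplotype routes agree and are order-invariant", {
  set.seed(201)
  for (i in 1:10) {
    sim <- drop_mutations(sim_genealogy(12L), S = sample(1:15, 1))
    a <- locus_stats_sites(sim$site_matrix)
    haps <- sim_haplotypes(sim)
    b <- locus_stats(haps, rep(1, length(haps)))
    expect_equal(a$D, b$D)
    expect_equal(a$k_hat, b$k_hat)
    # sample order invariance
    cshuf <- locus_stats(sample(haps), rep(1, length(haps)))
    expect_equal(cshuf$k_hat, b$k_hat)
    # allele relabeling (complement strings) leaves theta_W unchanged
    flip <- chartr("AC", "CA", haps)
    expect_equal(locus_stats(flip, rep(1, length(haps)))$theta_W, b$theta_W)
  }
})

test_that("fixed-S neutral replicates have mean D near zero", {
  set.seed(202)
  S <- sample(2:30, 4000, replace = TRUE)
  D <- microhapgen:::null_tajima_D_cpp(rep(40L, 4000), S, 1L, 1e7)
  expect_lt(abs(mean(D)), 0.1)
})

test_that("beta test is centered, vanishes in the tails, matches quadrature", {
  expect_gt(tajima_test_beta(0, 20), 0.9)
  tc <- tajima_constants(20)
  Dmax <- ((20 + 1) / 40 - 1 / tc$a1) / sqrt(tc$e2)
  expect_lt(tajima_test_beta(Dmax - 1e-6, 20), 1e-4)
  # independent oracle: numerical integration of the beta density
  for (case in list(c(-1.8, 20), c(0.7, 12), c(-0.9, 40))) {
    D <- case[1]; n <- case[2]
    tcn <- tajima_constants(n)
    Dmin <- (2 / n - 1 / tcn$a1) / sqrt(tcn$e2)
    lower <- integrate(tajima_beta_density, Dmin, D, n = n,
                       rel.tol = 1e-10)$value
    p_expected <- 2 * min(lower, 1 - lower)
    expect_equal(tajima_test_beta(D, n), p_expected, tolerance = 1e-6)
  }
  # density integrates to 1
  tcn <- tajima_constants(20)
  Dmin <- (2 / 20 - 1 / tcn$a1) / sqrt(tcn$e2)
  Dmax <- ((20 + 1) / 40 - 1 / tcn$a1) / sqrt(tcn$e2)
  expect_equal(integrate(tajima_beta_density, Dmin, Dmax, n = 20)$value, 1,
               tolerance = 1e-6)
})

test_that("genome-wide null test bookkeeping and determinism", {
  set.seed(203)
  obs <- data.frame(n = rep(20L, 30), S = sample(2:10, 30, TRUE))
  obs$D <- as.numeric(microhapgen:::null_tajima_D_cpp(obs$n, obs$S, 1L, 1e7))
  expect_error(genome_wide_null_test(obs, R = 0), "R must be")
  set.seed(7); a <- genome_wide_null_test(obs, R = 25)
  set.seed(7); b <- genome_wide_null_test(obs, R = 25)
  expect_identical(a, b)
  expect_equal(a$R, 25)
  expect_equal(a$n_loci, 30)
  # p_lower + p_upper >= 1 (ties counted on both sides)
  expect_gte(a$p_mean_lower + a$p_mean_upper, 1)
  # locus order invariance
  set.seed(9); c1 <- genome_wide_null_test(obs, R = 25)
  set.seed(9); c2 <- genome_wide_null_test(obs[order(obs$S), ], R = 25)
  expect_equal(c1$observed_mean, c2$observed_mean)
  # monomorphic loci are excluded and counted
  obs2 <- rbind(obs, data.frame(n = 20L, S = 0L, D = NA_real_))
  set.seed(10)
  expect_equal(genome_wide_null_test(obs2, R = 5)$n_excluded, 1L)
})

test_that("growth-shifted observations are detected by the null test", {
  set.seed(204)
  S <- sample(3:15, 50, TRUE)
  D <- vapply(S, function(s) {
    sim <- drop_mutations(sim_genealogy(30L, alpha = 20), S = s)
    locus_stats_sites(sim$site_matrix)$D
  }, 0)
  gw <- genome_wide_null_test(data.frame(n = 30L, S = S, D = D), R = 199)
  expect_lt(gw$p_mean_lower, 0.01)
  expect_lt(gw$observed_mean, mean(gw$replicate_means))
})

test_that("theta comparisons: ties, extremes, and power", {
  id <- sprintf("L%02d", 1:40)
  base <- data.frame(group = rep(c("A", "B"), each = 40),
                     locus_id = c(id, id),
                     theta_W = rep(1, 80), theta_T = rep(1, 80),
                     theta_W_site = rep(0.01, 80), theta_T_site = rep(0.01, 80))
  expect_warning(res <- compare_theta(base), "tied")
  expect_true(all(res$p == 1))
  # strict separation gives the minimal attainable p
  sep <- base
  sep$theta_W <- c(rep(2, 40), rep(1, 40)) + runif(80, 0, 0.01)
  sep$theta_T <- sep$theta_W
  res2 <- compare_theta(sep)
  expect_lt(max(res2$p), 1e-10)
  # simulated theta = 1 vs theta = 2 separates with a few hundred loci
  set.seed(205)
  mk <- function(theta, n_loci) {
    vapply(seq_len(n_loci), function(i) {
      drop_mutations(sim_genealogy(20L), theta = theta)$S / sum(1 / (1:19))
    }, 0)
  }
  d <- data.frame(group = rep(c("lo", "hi"), each = 300),
                  locus_id = c(sprintf("L%03d", 1:300), sprintf("L%03d", 1:300)),
                  theta_W = c(mk(1, 300), mk(2, 300)))
  d$theta_T <- d$theta_W; d$theta_W_site <- d$theta_W; d$theta_T_site <- d$theta_W
  expect_lt(compare_theta(d)$p[1], 0.05)
})
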