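# RDA machinery: dosage coding, environmental PCA, spatial design,
# ordination against brute-force and vegan oracles, forward selection,
# variance partitioning, Mahalanobis flagging.

test_that("dosage coding: homozygote rows, centering, mean imputation", {
  g <- toy_genotypes()
  # make i1 homozygous at L1 and i3 missing at L2
  g$a1[1, 1] <- 2L; g$a2[1, 1] <- 2L
  g$a1[2, 3] <- NA; g$a2[2, 3] <- NA
  ad <- code_alleles(g)
  raw <- sweep(ad$matrix, 2, -ad$column_means)  # un-center
  expect_equal(unname(raw[1, 1:3]), c(0, 2, 0))            # homozygote
  expect_equal(max(abs(colMeans(ad$matrix))), 0, tolerance = 1e-12)
  # imputed value equals the mean of observed dosages in that column
  l2cols <- which(ad$locus_of_column == "L2")
  obs_mean <- colMeans(raw[1:2, l2cols, drop = FALSE])
  expect_equal(unname(raw[3, l2cols]), unname(obs_mean))
  # per-locus dosages of observed individuals sum to 2
  expect_equal(unname(rowSums(raw[1:2, l2cols, drop = FALSE])), c(2, 2))
})

test_that("environmental PCA has the right rank and duplication invariance", {
  env <- data.frame(estuary = c("a", "b"), v1 = c(1, 2), v2 = c(5, 3))
  p <- env_pca(env)
  expect_equal(sum(p$percent_variance > 1e-9), 1L)  # 2 estuaries -> 1 PC
  set.seed(701)
  env2 <- data.frame(estuary = letters[1:6],
                     v1 = rnorm(6), v2 = rnorm(6), v3 = rnorm(6))
  p2 <- env_pca(env2)
  env_dup <- cbind(env2, v3b = env2$v3)
  p3 <- env_pca(env_dup)
  # duplicated variables receive identical loadings on every informative
  # component (the antisymmetric combination spans a zero-variance direction)
  informative <- p3$percent_variance > 1e-9
  expect_equal(unname(p3$loadings["v3", informative]),
               unname(p3$loadings["v3b", informative]), tolerance = 1e-10)
  expect_equal(sum(p3$percent_variance), 100, tolerance = 1e-9)
  env_const <- cbind(env2, flat = 1)
  expect_warning(env_pca(env_const), "zero-variance")
})

test_that("spatial polynomial basis is centered and orthogonal", {
  set.seed(702)
  x <- rep(c(0, 100, 400, 900), each = 5)
  m <- spatial_design(x, degree = 3, jitter_sd_km = 2)
  expect_equal(ncol(m), 3L)
  expect_equal(max(abs(colMeans(m))), 0, tolerance = 1e-12)
  cp <- crossprod(m)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-10)
  expect_error(spatial_design(rep(5, 10), degree = 2, jitter_sd_km = 0),
               "rank")
  # jitter robustness: R2 barely moves between 0 and 1 km jitter
  set.seed(703)
  Y <- scale(matrix(rnorm(20 * 6) + rep(x, 6) / 500, 20, 6), scale = FALSE)
  r <- vapply(c(1e-9, 1), function(j) {
    rda_fit(Y, spatial_design(x, 1, j), n_perm = 0)$R2
  }, 0)
  expect_lt(abs(r[1] - r[2]) / r[1], 0.05)
})

test_that("rda_fit equals the brute-force regression + eigen oracle", {
  set.seed(704)
  Y <- scale(matrix(rnorm(5 * 4), 5, 4), scale = FALSE)
  X <- matrix(rnorm(5), 5, 1)
  fit <- rda_fit(Y, X, n_perm = 0)
  oracle <- brute_rda(Y, X)
  expect_equal(fit$canonical_eigenvalues, oracle$eig, tolerance = 1e-10)
  expect_equal(fit$R2, oracle$R2, tolerance = 1e-12)
  # loadings are orthonormal right singular vectors of the fitted matrix
  expect_equal(crossprod(fit$allele_loadings),
               diag(length(fit$canonical_eigenvalues)), ignore_attr = TRUE,
               tolerance = 1e-10)
  proj <- oracle$fitted %*% fit$allele_loadings
  expect_equal(colSums(proj^2) / (nrow(Y) - 1), fit$canonical_eigenvalues,
               tolerance = 1e-10)
})

test_that("rda_fit agrees with vegan on R2, adjR2 and eigenvalues", {
  skip_if_not_installed("vegan")
  set.seed(705)
  n <- 24
  Y <- scale(matrix(rnorm(n * 10), n, 10), scale = FALSE)
  X <- matrix(rnorm(n * 3), n, 3)
  Z <- matrix(rnorm(n * 2), n, 2)
  fit <- rda_fit(Y, X, n_perm = 0)
  v <- vegan::rda(Y ~ X)
  expect_equal(fit$canonical_eigenvalues, unname(v$CCA$eig), tolerance = 1e-9)
  expect_equal(fit$R2, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-12)
  expect_equal(fit$adjR2, vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-12)
  fitp <- rda_fit(Y, X, Z = Z, n_perm = 0)
  vp <- vegan::rda(Y ~ X + Condition(Z))
  expect_equal(fitp$canonical_eigenvalues, unname(vp$CCA$eig), tolerance = 1e-9)
})

test_that("saturated constraints explain everything; noise matches m/(n-1)", {
  set.seed(706)
  n <- 12
  Y <- scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)
  Xs <- stats::model.matrix(~ factor(seq_len(n)))[, -1]
  fs <- rda_fit(Y, Xs, n_perm = 0)
  expect_equal(fs$R2, 1, tolerance = 1e-12)
  expect_equal(fs$ss_res, 0, tolerance = 1e-8)
  # independent noise constraint: E[R2] = m/(n-1), adjR2 near 0
  r2 <- replicate(300, {
    Yn <- scale(matrix(rnorm(20 * 4), 20, 4), scale = FALSE)
    rda_fit(Yn, matrix(rnorm(20), 20, 1), n_perm = 0)$R2
  })
  expect_lt(abs(mean(r2) - 1 / 19), 0.012)
  # adjusted R2 formula holds exactly for arbitrary shapes
  fit <- rda_fit(Y, Xs[, 1:3], n_perm = 0)
  expect_equal(fit$adjR2,
               1 - (1 - fit$R2) * (n - 1) / (n - 3 - 1), tolerance = 1e-12)
})

test_that("rank-(n-1) constraints reproduce the PCA of Y", {
  set.seed(707)
  n <- 10
  Y <- scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)
  Xs <- stats::model.matrix(~ factor(seq_len(n)))[, -1]
  fit <- rda_fit(Y, Xs, n_perm = 0)
  pc_eig <- prcomp(Y)$sdev^2
  pc_eig <- pc_eig[pc_eig > max(pc_eig) * 1e-9]
  expect_equal(fit$canonical_eigenvalues, pc_eig, tolerance = 1e-9)
})

test_that("forward selection keeps signal and rejects noise", {
  set.seed(708)
  n <- 60
  signal <- rnorm(n)
  Y <- scale(matrix(rnorm(n * 8) + signal %o% rnorm(8), n, 8), scale = FALSE)
  cands <- cbind(A = signal, matrix(rnorm(n * 7), n, 7))
  colnames(cands)[2:8] <- paste0("N", 1:7)
  sel <- forward_select(Y, cands, n_perm = 199)
  expect_equal(sel$selected[1], "A")
  # pure noise: empty or near-empty selection
  set.seed(709)
  n_sel <- replicate(20, {
    Yn <- scale(matrix(rnorm(30 * 5), 30, 5), scale = FALSE)
    length(forward_select(Yn, matrix(rnorm(30 * 4), 30, 4), n_perm = 99)$selected)
  })
  # first-step family-wise pick rate ~ k * alpha; deeper selections rare
  expect_lt(mean(n_sel), 0.5)
  expect_lt(mean(n_sel > 1), 0.15)
})

test_that("varpart identities hold to 1e-12 and degenerate cases behave", {
  set.seed(710)
  n <- 30
  Y <- scale(matrix(rnorm(n * 8), n, 8), scale = FALSE)
  X1 <- matrix(rnorm(n * 2), n, 2)
  X2 <- matrix(rnorm(n * 2), n, 2)
  vp <- varpart(Y, X1, X2, n_perm = 49)
  expect_equal(vp$env_unique, vp$adjR2_full - vp$adjR2_xy_total, tolerance = 1e-12)
  expect_equal(vp$xy_unique, vp$adjR2_full - vp$adjR2_env_total, tolerance = 1e-12)
  expect_equal(vp$shared, vp$adjR2_env_total + vp$adjR2_xy_total - vp$adjR2_full,
               tolerance = 1e-12)
  expect_equal(vp$residual, 1 - vp$adjR2_full, tolerance = 1e-12)
  # identical matrices: unique fractions vanish
  vp2 <- varpart(Y, X1, X1 %*% diag(2), n_perm = 0)
  expect_equal(vp2$env_unique, 0, tolerance = 1e-10)
  expect_equal(vp2$xy_unique, 0, tolerance = 1e-10)
  expect_equal(vp2$shared, vp2$adjR2_full, tolerance = 1e-10)
  # orthogonal constructed predictors: shared near zero
  q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  vp3 <- varpart(Y, q[, 1:2], q[, 3:4], n_perm = 0)
  expect_lt(abs(vp3$shared), 0.05)
})

test_that("varpart fractions agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(711)
  n <- 26
  Y <- scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)
  X1 <- matrix(rnorm(n * 2), n, 2)
  X2 <- matrix(rnorm(n), n, 1)
  mine <- varpart(Y, X1, X2, n_perm = 0)
  vv <- vegan::varpart(Y, X1, X2)
  frac <- vv$part$indfract$Adj.R.square
  expect_equal(mine$env_unique, frac[1], tolerance = 1e-10)
  expect_equal(mine$xy_unique, frac[2], tolerance = 1e-10)
  expect_equal(mine$shared, frac[3], tolerance = 1e-10)
  expect_equal(mine$residual, frac[4], tolerance = 1e-10)
})

test_that("Mahalanobis flagging: chi-square tail and planted outlier", {
  set.seed(712)
  Lm <- matrix(rnorm(4e5 * 2), ncol = 2)
  D2 <- mahalanobis(Lm, colMeans(Lm), cov(Lm))
  # expected flags at threshold 25 under chi2_2: 4e5 * 3.7e-6 ~ 1.5
  expect_lt(sum(D2 > 25), 10)
  # a planted point far out is flagged
  fake <- list(canonical_eigenvalues = c(1, 0.5),
               allele_loadings = rbind(Lm[1:500, ], c(10, -10)),
               dosage_meta = NULL)
  class(fake) <- "rda_model"
  fl <- mahalanobis_flags(fake, 25)
  expect_true(fl$table$flagged[501])
  expect_lt(mean(fl$table$flagged[1:500]), 0.02)
  expect_true(all(fl$table$mahalanobis_D2 >= 0))
})
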