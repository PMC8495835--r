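# Fixture builders and independent brute-force oracles used across tests.

# deterministic ACGT string for allele index k (width base-4 digits)
int2hap <- function(k, width = 6) {
  vapply(k, function(kk) {
    digs <- integer(width)
    for (i in seq_len(width)) { digs[i] <- kk %% 4; kk <- kk %/% 4 }
    paste(c("A", "C", "G", "T")[digs + 1], collapse = "")
  }, "")
}

# tiny hand-built genotype matrix: 2 loci x 3 individuals
toy_genotypes <- function() {
  loci <- list(mh_locus("L1", "c1", c("AA", "AC", "CC")),
               mh_locus("L2", "c2", c("AA", "AC")))
  a1 <- matrix(c(1L, 1L, 2L,
                 1L, 2L, 1L), 2, 3, byrow = TRUE)
  a2 <- matrix(c(2L, 3L, 3L,
                 2L, 2L, 1L), 2, 3, byrow = TRUE)
  mh_genotypes(c("i1", "i2", "i3"), loci, a1, a2)
}

toy_metadata <- function(ind = c("i1", "i2", "i3")) {
  data.frame(individual_id = ind,
             estuary = c("E1", "E1", "E2")[seq_along(ind)],
             basin = "gulf", life_stage = "yoy",
             coastal_distance_km = c(0, 0, 100)[seq_along(ind)],
             stringsAsFactors = FALSE)
}

# random genotypes: L loci, pops with n_ind each, allele count per locus
random_genotypes <- function(L, n_per_pop, n_alleles = 3, missing = 0) {
  P <- length(n_per_pop)
  N <- sum(n_per_pop)
  loci <- lapply(seq_len(L), function(l) {
    mh_locus(sprintf("L%03d", l), "c", int2hap(seq_len(n_alleles)))
  })
  a1 <- matrix(sample.int(n_alleles, L * N, TRUE), L, N)
  a2 <- matrix(sample.int(n_alleles, L * N, TRUE), L, N)
  if (missing > 0) {
    mi <- matrix(runif(L * N) < missing, L, N)
    a1[mi] <- NA_integer_; a2[mi] <- NA_integer_
  }
  ind <- sprintf("i%03d", seq_len(N))
  g <- mh_genotypes(ind, loci, a1, a2)
  pops <- setNames(rep(paste0("p", seq_len(P)), n_per_pop), ind)
  list(geno = g, pops = pops)
}

# genotypes built from island-model coalescent samples (diploids paired
# within demes); used by scan and recovery tests. theta is per locus; note
# within-deme tree depth scales with d_total, so keep theta ~ target_het / d.
island_genotypes <- function(L, d_total, M, n_ind_per_pop,
                             theta_range = c(0.5, 5) / d_total) {
  P <- length(n_ind_per_pop)
  copies <- 2L * n_ind_per_pop
  ss <- integer(d_total); ss[seq_len(P)] <- copies
  mig <- island_migration(d_total, M)
  N <- sum(n_ind_per_pop)
  loci <- vector("list", L)
  a1 <- a2 <- matrix(NA_integer_, L, N)
  for (l in seq_len(L)) {
    th <- exp(runif(1, log(theta_range[1]), log(theta_range[2])))
    al <- microhapgen:::sim_locus_alleles_cpp(ss, mig, 0, -1L, th, 1e7)
    loci[[l]] <- mh_locus(sprintf("L%04d", l), "c", int2hap(seq_len(max(al))))
    first <- seq(1, length(al), by = 2)
    a1[l, ] <- al[first]; a2[l, ] <- al[first + 1]
  }
  ind <- sprintf("i%03d", seq_len(N))
  g <- mh_genotypes(ind, loci, a1, a2)
  pops <- setNames(rep(paste0("p", seq_len(P)), n_ind_per_pop), ind)
  list(geno = g, pops = pops)
}

# Brute-force AMOVA oracle: explicit pairwise 0/1 distance matrices and
# direct double sums (Excoffier et al. 1992), independent of the package's
# vectorised engine.
brute_amova <- function(geno, pops, groups = NULL) {
  L <- length(geno$loci)
  sa <- sb <- sc <- saml <- swl <- 0
  for (l in seq_len(L)) {
    al <- c(geno$a1[l, ], geno$a2[l, ])
    pp <- rep(pops[geno$individuals], 2)
    ok <- !is.na(al); al <- al[ok]; pp <- pp[ok]
    n_T <- length(al)
    d2 <- outer(al, al, "!=") * 1
    ssd_t <- sum(d2[upper.tri(d2)]) / n_T
    upops <- unique(pp)
    np <- vapply(upops, function(p) sum(pp == p), 0L)
    ssd_w <- 0
    for (p in upops) {
      sel <- pp == p
      dd <- d2[sel, sel]
      ssd_w <- ssd_w + sum(dd[upper.tri(dd)]) / sum(sel)
    }
    P <- length(upops)
    if (is.null(groups)) {
      ssd_a <- ssd_t - ssd_w
      dfw <- n_T - P; dfa <- P - 1
      nc <- (n_T - sum(np^2) / n_T) / dfa
      msw <- ssd_w / dfw; msa <- ssd_a / dfa
      swl <- swl + msw
      saml <- saml + (msa - msw) / nc
    } else {
      gg <- groups[upops]
      ugr <- unique(gg)
      G <- length(ugr)
      ng <- vapply(ugr, function(g) sum(np[gg == g]), 0)
      ssd_grp <- 0
      for (g in ugr) {
        sel <- pp %in% upops[gg == g]
        dd <- d2[sel, sel]
        ssd_grp <- ssd_grp + sum(dd[upper.tri(dd)]) / sum(sel)
      }
      ssd_ag <- ssd_t - ssd_grp
      ssd_ap <- ssd_grp - ssd_w
      df_ag <- G - 1; df_ap <- P - G; df_wp <- n_T - P
      sum_np2_over_ng <- sum(vapply(ugr, function(g) {
        sum(np[gg == g]^2) / sum(np[gg == g])
      }, 0))
      n1 <- (n_T - sum_np2_over_ng) / df_ap
      n2 <- (sum_np2_over_ng - sum(np^2) / n_T) / df_ag
      n3 <- (n_T - sum(ng^2) / n_T) / df_ag
      ms_wp <- ssd_w / df_wp
      ms_ap <- ssd_ap / df_ap
      ms_ag <- ssd_ag / df_ag
      sc_l <- ms_wp
      sb_l <- (ms_ap - ms_wp) / n1
      sa_l <- (ms_ag - sc_l - n2 * sb_l) / n3
      sa <- sa + sa_l; sb <- sb + sb_l; sc <- sc + sc_l
    }
  }
  if (is.null(groups)) {
    list(sigma_among = saml, sigma_within = swl, fst = saml / (saml + swl))
  } else {
    list(sigma_a = sa, sigma_b = sb, sigma_c = sc,
         f_ct = sa / (sa + sb + sc), f_sc = sb / (sb + sc),
         f_st = (sa + sb) / (sa + sb + sc))
  }
}

# Brute-force RDA oracle: explicit regression then eigen-decomposition.
brute_rda <- function(Y, X) {
  Y <- sweep(Y, 2, colMeans(Y))
  X <- sweep(as.matrix(X), 2, colMeans(as.matrix(X)))
  B <- solve(crossprod(X), crossprod(X, Y))
  fitted <- X %*% B
  ev <- eigen(crossprod(fitted) / (nrow(Y) - 1), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-9
  list(eig = ev$values[keep], R2 = sum(fitted^2) / sum(Y^2),
       fitted = fitted)
}
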