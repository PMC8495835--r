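# Locus-by-locus AMOVA on microhaplotype alleles with gene copies as units
# and allele-identity distance (delta = 0 same allele, else 1), following the
# classical sums-of-squares partition with unequal-size coefficients
# (Excoffier, Smouse & Quattro 1992). Variance components are computed per
# locus with per-locus gene-copy counts (missing calls reduce n), summed over
# loci, and F-statistics formed from the summed components (ratio-of-sums).
# Negative components are retained, never truncated.
#
# Permutation schemes follow the standard conventions for each statistic:
# F_ST permutes individuals among populations, F_SC permutes individuals
# among populations within groups, F_CT permutes whole populations among
# groups. p = (# permuted >= observed, ties included, + 1) / (n_perm + 1).

# Long-format copy table used by the fast tabulation path.
.amova_prep <- function(geno, populations) {
  pops <- populations[geno$individuals]
  if (anyNA(pops)) stop("every genotyped individual needs a population")
  pop_levels <- unique(pops)
  pop_of_ind <- match(pops, pop_levels)
  L <- length(geno$loci)
  n_alleles <- vapply(geno$loci, function(l) length(l$alleles), 0L)
  offset <- c(0L, cumsum(n_alleles))[seq_len(L)]
  idx <- which(!is.na(geno$a1))                     # locus-major cell index
  loc <- ((idx - 1L) %% L) + 1L
  ind <- ((idx - 1L) %/% L) + 1L
  gid <- c(offset[loc] + geno$a1[idx], offset[loc] + geno$a2[idx])
  list(gid_copy = gid, ind_copy = c(ind, ind),
       locus_of_gid = rep.int(seq_len(L), n_alleles),
       n_gid = sum(n_alleles), L = L,
       pop_levels = pop_levels, pop_of_ind = pop_of_ind,
       individuals = geno$individuals,
       locus_ids = vapply(geno$loci, `[[`, "", "locus_id"))
}

# counts matrix: n_gid x P
.amova_counts <- function(prep, pop_of_ind) {
  P <- length(prep$pop_levels)
  key <- (prep$gid_copy - 1L) * P + pop_of_ind[prep$ind_copy]
  cnt <- tabulate(key, nbins = prep$n_gid * P)
  matrix(cnt, nrow = P, ncol = prep$n_gid)  # P x n_gid (pop fastest)
}

# Hierarchical components per locus. Cmat: P x n_gid counts;
# group_of_pop: length-P integer. Returns per-locus sigma_a/b/c and the
# summed SSD/df per level.
.hier_components <- function(prep, Cmat, group_of_pop) {
  L <- prep$L
  G <- max(group_of_pop)
  lg <- prep$locus_of_gid
  tC <- t(Cmat)                                   # n_gid x P
  n_lp <- rowsum(tC, lg, reorder = FALSE)         # L x P  gene copies
  s2_lp <- rowsum(tC^2, lg, reorder = FALSE)      # L x P  sum_a c^2
  Ig <- matrix(0, length(group_of_pop), G)
  Ig[cbind(seq_along(group_of_pop), group_of_pop)] <- 1
  Cg <- tC %*% Ig                                 # n_gid x G
  n_lg <- n_lp %*% Ig                             # L x G
  s2_lg <- rowsum(Cg^2, lg, reorder = FALSE)      # L x G
  cT <- rowSums(tC)                               # per gid
  s2_lT <- rowsum(cT^2, lg, reorder = FALSE)[, 1] # L
  n_lT <- rowSums(n_lp)

  ssd_wp <- rowSums(ifelse(n_lp > 0, (n_lp - s2_lp / pmax(n_lp, 1)) / 2, 0))
  ssd_g <- ifelse(n_lg > 0, (n_lg - s2_lg / pmax(n_lg, 1)) / 2, 0)
  ssd_t <- (n_lT - s2_lT / pmax(n_lT, 1)) / 2
  ssd_ap <- rowSums(ssd_g) - ssd_wp
  ssd_ag <- ssd_t - rowSums(ssd_g)

  P_l <- rowSums(n_lp > 0)
  G_l <- rowSums(n_lg > 0)
  df_wp <- n_lT - P_l
  df_ap <- P_l - G_l
  df_ag <- G_l - 1

  np2 <- n_lp^2
  sum_np2_over_ng <- rowSums(ifelse(n_lg > 0, (np2 %*% Ig) / pmax(n_lg, 1), 0))
  sum_np2_over_nT <- rowSums(np2) / pmax(n_lT, 1)
  sum_ng2_over_nT <- rowSums(n_lg^2) / pmax(n_lT, 1)
  n1 <- ifelse(df_ap > 0, (n_lT - sum_np2_over_ng) / pmax(df_ap, 1), NA_real_)
  n2 <- ifelse(df_ag > 0, (sum_np2_over_ng - sum_np2_over_nT) / pmax(df_ag, 1), NA_real_)
  n3 <- ifelse(df_ag > 0, (n_lT - sum_ng2_over_nT) / pmax(df_ag, 1), NA_real_)

  ms_wp <- ifelse(df_wp > 0, ssd_wp / pmax(df_wp, 1), NA_real_)
  ms_ap <- ifelse(df_ap > 0, ssd_ap / pmax(df_ap, 1), NA_real_)
  ms_ag <- ifelse(df_ag > 0, ssd_ag / pmax(df_ag, 1), NA_real_)

  sig_c <- ifelse(is.na(ms_wp), 0, ms_wp)
  sig_b <- ifelse(is.na(ms_ap) | is.na(ms_wp) | n1 <= 0, 0, (ms_ap - ms_wp) / n1)
  sig_a <- ifelse(is.na(ms_ag) | n3 <= 0, 0,
                  (ms_ag - sig_c - n2 * sig_b) / n3)
  list(sigma_a = sig_a, sigma_b = sig_b, sigma_c = sig_c,
       ssd = c(among_groups = sum(ssd_ag), among_pops = sum(ssd_ap),
               within_pops = sum(ssd_wp)),
       df = c(among_groups = sum(df_ag), among_pops = sum(df_ap),
              within_pops = sum(df_wp)))
}

# Single-level components per locus (populations only).
.single_components <- function(prep, Cmat) {
  lg <- prep$locus_of_gid
  tC <- t(Cmat)
  n_lp <- rowsum(tC, lg, reorder = FALSE)
  s2_lp <- rowsum(tC^2, lg, reorder = FALSE)
  cT <- rowSums(tC)
  s2_lT <- rowsum(cT^2, lg, reorder = FALSE)[, 1]
  n_lT <- rowSums(n_lp)
  ssd_wp <- rowSums(ifelse(n_lp > 0, (n_lp - s2_lp / pmax(n_lp, 1)) / 2, 0))
  ssd_t <- (n_lT - s2_lT / pmax(n_lT, 1)) / 2
  ssd_ap <- ssd_t - ssd_wp
  P_l <- rowSums(n_lp > 0)
  df_wp <- n_lT - P_l
  df_ap <- P_l - 1
  nc <- ifelse(df_ap > 0, (n_lT - rowSums(n_lp^2) / pmax(n_lT, 1)) / pmax(df_ap, 1),
               NA_real_)
  ms_wp <- ifelse(df_wp > 0, ssd_wp / pmax(df_wp, 1), NA_real_)
  ms_ap <- ifelse(df_ap > 0, ssd_ap / pmax(df_ap, 1), NA_real_)
  sig_w <- ifelse(is.na(ms_wp), 0, ms_wp)
  sig_a <- ifelse(is.na(ms_ap) | is.na(ms_wp) | nc <= 0, 0, (ms_ap - ms_wp) / nc)
  list(sigma_among = sig_a, sigma_within = sig_w,
       ssd = c(among_pops = sum(ssd_ap), within_pops = sum(ssd_wp)),
       df = c(among_pops = sum(df_ap), within_pops = sum(df_wp)))
}

.perm_pops_within <- function(pop_of_ind, group_of_pop, scheme) {
  # returns a permuted pop_of_ind
  if (scheme == "all") {
    sample(pop_of_ind)
  } else { # within groups
    out <- pop_of_ind
    gi <- group_of_pop[pop_of_ind]
    for (g in unique(gi)) {
      sel <- which(gi == g)
      out[sel] <- pop_of_ind[sel][sample(length(sel))]
    }
    out
  }
}

#' Hierarchical or single-level locus-by-locus AMOVA
#'
#' Partitions molecular variance among groups (ocean basins), among
#' populations (estuaries) within groups, and within populations, with
#' permutation tests per statistic. With `groups = NULL` a single-level
#' analysis (among/within populations) is run.
#'
#' @param geno an `mh_genotypes` object.
#' @param populations named character vector individual -> population.
#' @param groups optional named character vector population -> group.
#' @param n_perm number of permutations per statistic (0 disables tests).
#' @return an `amova_result`: per-level SSD/df/MS, summed variance
#'   components, percent variation, F-statistics, permutation p-values, a
#'   per-locus component table, and a flag for negative components.
#' @export
amova <- function(geno, populations, groups = NULL, n_perm = 10000L) {
  prep <- .amova_prep(geno, populations)
  P <- length(prep$pop_levels)
  if (P < 2) stop("need at least 2 populations")
  copies_per_pop <- tabulate(prep$pop_of_ind[prep$ind_copy], P)
  if (any(copies_per_pop == 0)) {
    stop("population(s) with zero called gene copies: ",
         paste(prep$pop_levels[copies_per_pop == 0], collapse = ", "))
  }
  Cmat <- .amova_counts(prep, prep$pop_of_ind)

  if (is.null(groups)) {
    comp <- .single_components(prep, Cmat)
    sa <- sum(comp$sigma_among); sw <- sum(comp$sigma_within)
    tot <- sa + sw
    fst <- sa / tot
    p_fst <- NA_real_
    if (n_perm > 0) {
      count <- 0L
      for (b in seq_len(n_perm)) {
        pb <- .perm_pops_within(prep$pop_of_ind, NULL, "all")
        cb <- .single_components(prep, .amova_counts(prep, pb))
        sab <- sum(cb$sigma_among); swb <- sum(cb$sigma_within)
        if (sab / (sab + swb) >= fst) count <- count + 1L
      }
      p_fst <- (count + 1) / (n_perm + 1)
    }
    return(structure(list(
      design = "single_level", populations = prep$pop_levels,
      ssd = comp$ssd, df = comp$df,
      ms = comp$ssd / pmax(comp$df, 1),
      sigma2 = c(among_pops = sa, within_pops = sw),
      percent_variation = 100 * c(among_pops = sa, within_pops = sw) / tot,
      fst = fst, p_fst = p_fst, n_perm = n_perm,
      per_locus = data.frame(locus_id = prep$locus_ids,
                             sigma_among = comp$sigma_among,
                             sigma_within = comp$sigma_within),
      negative_components = any(comp$sigma_among < 0)),
      class = "amova_result"))
  }

  gmap <- groups[prep$pop_levels]
  if (anyNA(gmap)) stop("every population needs a group")
  grp_levels <- unique(gmap)
  if (length(grp_levels) < 2) {
    # a single group carries no among-group level: collapse to single-level
    message("single group supplied; collapsing to single-level AMOVA")
    return(amova(geno, populations, groups = NULL, n_perm = n_perm))
  }
  group_of_pop <- match(gmap, grp_levels)

  comp <- .hier_components(prep, Cmat, group_of_pop)
  sa <- sum(comp$sigma_a); sb <- sum(comp$sigma_b); sc <- sum(comp$sigma_c)
  tot <- sa + sb + sc
  f_ct <- sa / tot
  f_sc <- sb / (sb + sc)
  f_st <- (sa + sb) / tot

  p <- c(f_ct = NA_real_, f_sc = NA_real_, f_st = NA_real_)
  if (n_perm > 0) {
    counts <- c(f_ct = 0L, f_sc = 0L, f_st = 0L)
    for (b in seq_len(n_perm)) {
      # F_ST: individuals among populations (across groups)
      pb <- .perm_pops_within(prep$pop_of_ind, group_of_pop, "all")
      cb <- .hier_components(prep, .amova_counts(prep, pb), group_of_pop)
      sA <- sum(cb$sigma_a); sB <- sum(cb$sigma_b); sC <- sum(cb$sigma_c)
      if ((sA + sB) / (sA + sB + sC) >= f_st) counts["f_st"] <- counts["f_st"] + 1L
      # F_SC: individuals among populations within groups
      pb <- .perm_pops_within(prep$pop_of_ind, group_of_pop, "within")
      cb <- .hier_components(prep, .amova_counts(prep, pb), group_of_pop)
      sB <- sum(cb$sigma_b); sC <- sum(cb$sigma_c)
      if (sB / (sB + sC) >= f_sc) counts["f_sc"] <- counts["f_sc"] + 1L
      # F_CT: whole populations among groups (counts unchanged)
      gb <- sample(group_of_pop)
      cb <- .hier_components(prep, Cmat, gb)
      sA <- sum(cb$sigma_a); sB <- sum(cb$sigma_b); sC <- sum(cb$sigma_c)
      if (sA / (sA + sB + sC) >= f_ct) counts["f_ct"] <- counts["f_ct"] + 1L
    }
    p <- (counts + 1) / (n_perm + 1)
  }

  structure(list(
    design = "hierarchical", populations = prep$pop_levels,
    groups = grp_levels, group_of_pop = gmap,
    ssd = comp$ssd, df = comp$df, ms = comp$ssd / pmax(comp$df, 1),
    sigma2 = c(among_groups = sa, among_pops_within = sb, within_pops = sc),
    percent_variation = 100 * c(among_groups = sa, among_pops_within = sb,
                                within_pops = sc) / tot,
    f_ct = f_ct, f_sc = f_sc, f_st = f_st,
    p_f_ct = p[["f_ct"]], p_f_sc = p[["f_sc"]], p_f_st = p[["f_st"]],
    n_perm = n_perm,
    per_locus = data.frame(locus_id = prep$locus_ids, sigma_a = comp$sigma_a,
                           sigma_b = comp$sigma_b, sigma_c = comp$sigma_c),
    negative_components = any(c(comp$sigma_a, comp$sigma_b) < 0)),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>", x$design, "\n")
  if (x$design == "hierarchical") {
    cat(sprintf("  F_CT = %.4f (p = %s)\n", x$f_ct, format(x$p_f_ct)))
    cat(sprintf("  F_SC = %.4f (p = %s)\n", x$f_sc, format(x$p_f_sc)))
    cat(sprintf("  F_ST = %.4f (p = %s)\n", x$f_st, format(x$p_f_st)))
  } else {
    cat(sprintf("  F_ST = %.4f (p = %s)\n", x$fst, format(x$p_fst)))
  }
  invisible(x)
}

#' Pairwise F_ST between populations
#'
#' Every pair is analysed as a two-population single-level AMOVA with
#' permutation of individuals between the pair; BH adjustment across all
#' pairs. Negative estimates are retained.
#'
#' @inheritParams amova
#' @return a `pairwise_fst` object: symmetric `fst`, `p_raw` and `q_bh`
#'   matrices over populations.
#' @export
pairwise_fst <- function(geno, populations, n_perm = 10000L) {
  pops <- unique(populations[geno$individuals])
  if (length(pops) < 2) stop("need at least 2 populations")
  sizes <- table(populations[geno$individuals])
  if (any(sizes < 2)) stop("each population needs >= 2 individuals")
  K <- length(pops)
  fst <- p_raw <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    keep <- names(populations)[populations %in% c(pops[i], pops[j])]
    keep <- intersect(geno$individuals, keep)
    sub <- .subset_genotypes(geno, keep)
    res <- amova(sub, populations[keep], n_perm = n_perm)
    fst[i, j] <- fst[j, i] <- res$fst
    p_raw[i, j] <- p_raw[j, i] <- res$p_fst
  }
  up <- upper.tri(fst)
  q <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  if (n_perm > 0) {
    qv <- bh_adjust(p_raw[up])
    q[up] <- qv; q <- t(q); q[up] <- qv
  }
  structure(list(groups = pops, fst = fst, p_raw = p_raw, q_bh = q,
                 n_perm = n_perm),
            class = "pairwise_fst")
}

# genotype subset by individuals (keeps all loci)
.subset_genotypes <- function(geno, individuals) {
  idx <- match(individuals, geno$individuals)
  mh_genotypes(individuals, geno$loci,
               geno$a1[, idx, drop = FALSE], geno$a2[, idx, drop = FALSE])
}

#' Single-level F_ST and within-population diversity from one count matrix
#'
#' The per-locus primitive shared by the AMOVA engine and the outlier scan:
#' variance components for one locus from a populations x alleles count
#' matrix, plus the gene-copy-weighted mean within-population unbiased gene
#' diversity.
#'
#' @param counts populations x alleles integer matrix of gene copies.
#' @return list: `fst`, `sigma_among`, `sigma_within`, `het` (NA when
#'   undefined).
#' @export
fst_from_counts <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  n_p <- rowSums(counts)
  P <- nrow(counts); n_T <- sum(n_p)
  if (P < 2) return(list(fst = NA_real_, sigma_among = NA_real_,
                         sigma_within = NA_real_, het = NA_real_))
  ssd_wp <- sum((n_p - rowSums(counts^2) / n_p) / 2)
  cT <- colSums(counts)
  ssd_t <- (n_T - sum(cT^2) / n_T) / 2
  ssd_ap <- ssd_t - ssd_wp
  df_wp <- n_T - P; df_ap <- P - 1
  nc <- (n_T - sum(n_p^2) / n_T) / df_ap
  ms_wp <- if (df_wp > 0) ssd_wp / df_wp else NA_real_
  ms_ap <- ssd_ap / df_ap
  sig_w <- ms_wp
  sig_a <- if (is.na(ms_wp) || nc <= 0) NA_real_ else (ms_ap - ms_wp) / nc
  het_p <- ifelse(n_p > 1,
                  n_p / (n_p - 1) * (1 - rowSums((counts / n_p)^2)), NA)
  het <- sum(het_p * n_p, na.rm = TRUE) / sum(n_p[!is.na(het_p)])
  fst <- if (is.na(sig_a)) NA_real_ else sig_a / (sig_a + sig_w)
  list(fst = fst, sigma_among = sig_a, sigma_within = sig_w, het = het)
}

#' Per-locus allele counts by population
#'
#' @param geno an `mh_genotypes`.
#' @param populations named vector individual -> population.
#' @return list of populations x alleles count matrices, one per locus.
#' @export
allele_counts_by_pop <- function(geno, populations) {
  pops <- populations[geno$individuals]
  levs <- unique(pops)
  lapply(seq_along(geno$loci), function(l) {
    A <- length(geno$loci[[l]]$alleles)
    m <- matrix(0L, length(levs), A,
                dimnames = list(levs, geno$loci[[l]]$alleles))
    for (k in seq_along(levs)) {
      cols <- which(pops == levs[k])
      al <- c(geno$a1[l, cols], geno$a2[l, cols])
      m[k, ] <- tabulate(al[!is.na(al)], nbins = A)
    }
    m
  })
}
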