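# Per-group, per-locus genomic diversity: Nei's unbiased gene diversity,
# hypergeometric rarefied allele counts, and E5 evenness (ratio of the
# Stoddart & Taylor and Shannon-Wiener indices), plus fixed-allele set
# analysis and the Friedman / pairwise-Wilcoxon comparison framework.

#' Nei's unbiased gene diversity
#'
#' `H = n/(n-1) * (1 - sum p_i^2)` over allele frequencies.
#'
#' @param allele_counts integer vector of gene-copy counts per allele.
#' @return H in `[0, 1]`; `NA` when fewer than 2 gene copies.
#' @export
nei_gene_diversity <- function(allele_counts) {
  n <- sum(allele_counts)
  if (n < 2) return(NA_real_)
  p <- allele_counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Rarefied allele count
#'
#' Expected number of distinct alleles in a hypergeometric draw of `g` gene
#' copies: `E[A_g] = sum_i [1 - C(N - N_i, g) / C(N, g)]`.
#'
#' @param allele_counts integer vector of gene-copy counts per allele.
#' @param g rarefaction depth in gene copies, `1 <= g <= sum(allele_counts)`.
#' @return expected allele count at depth `g`.
#' @export
rarefied_allele_count <- function(allele_counts, g) {
  N <- sum(allele_counts)
  if (g < 1 || g > N) stop("rarefaction depth g must be in [1, N]")
  ac <- allele_counts[allele_counts > 0]
  # lchoose handles C(N - Ni, g) = 0 when g > N - Ni
  sum(1 - exp(lchoose(N - ac, g) - lchoose(N, g)))
}

#' E5 evenness
#'
#' `E5 = ((1/lambda) - 1) / (exp(H') - 1)` with Simpson concentration
#' `lambda = sum p^2` and Shannon-Wiener entropy `H'` (nats). Equifrequent
#' alleles give 1; a monomorphic locus is 1 by convention (the 0/0 limit),
#' signalled via the `"monomorphic"` attribute.
#'
#' @param allele_counts counts or frequencies (scale-invariant).
#' @return E5 in `(0, 1]`.
#' @export
evenness_e5 <- function(allele_counts) {
  if (sum(allele_counts) <= 0) stop("needs at least one nonzero count")
  p <- allele_counts[allele_counts > 0] / sum(allele_counts)
  if (length(p) == 1) return(structure(1, monomorphic = TRUE))
  lambda <- sum(p^2)
  hshan <- -sum(p * log(p))
  (1 / lambda - 1) / (exp(hshan) - 1)
}

#' Per-group, per-locus diversity records
#'
#' Computes H, A_g, E5, Simpson concentration and Shannon entropy for every
#' (group, locus). The rarefaction depth defaults per locus to the smallest
#' per-group gene-copy count across the compared groups (reported in the
#' output); loci where that floor is below `min_g` are dropped.
#'
#' @param geno an `mh_genotypes`.
#' @param populations named vector individual -> group.
#' @param g fixed rarefaction depth, or `NULL` for the per-locus minimum.
#' @param min_g smallest acceptable depth when `g` is `NULL`.
#' @return long data.frame: group, locus_id, n, H, A_g, E5, lambda,
#'   H_shannon, g.
#' @export
diversity_records <- function(geno, populations, g = NULL, min_g = 2L) {
  counts <- allele_counts_by_pop(geno, populations)
  ids <- vapply(geno$loci, `[[`, "", "locus_id")
  out <- list()
  for (l in seq_along(counts)) {
    m <- counts[[l]]
    n_p <- rowSums(m)
    gl <- if (is.null(g)) min(n_p) else g
    if (gl < min_g || any(n_p < gl)) next
    for (k in seq_len(nrow(m))) {
      ac <- m[k, ]
      p <- ac[ac > 0] / n_p[k]
      e5 <- evenness_e5(ac)
      out[[length(out) + 1L]] <- data.frame(
        group = rownames(m)[k], locus_id = ids[l], n = n_p[k],
        H = nei_gene_diversity(ac),
        A_g = rarefied_allele_count(ac, gl),
        E5 = as.numeric(e5),
        lambda = sum(p^2), H_shannon = -sum(p * log(p)), g = gl,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fixed-allele sets and their exclusive intersections
#'
#' A locus is fixed in a group when a single allele is observed there. The
#' intersection table uses exclusive (UpSet) semantics: each locus is counted
#' in exactly the combination of groups where it is fixed. Each fixed locus
#' also carries its global (all individuals pooled) rarefied allele count.
#'
#' @param geno an `mh_genotypes`.
#' @param populations named vector individual -> group.
#' @param g_global rarefaction depth for global diversity of fixed loci
#'   (default: smallest per-group gene-copy count over loci and groups).
#' @return list: `fixed_sets` (group -> locus ids), `intersections`
#'   (combination, count), `global_diversity` (locus_id, A_g, H).
#' @export
fixed_allele_analysis <- function(geno, populations, g_global = NULL) {
  counts <- allele_counts_by_pop(geno, populations)
  ids <- vapply(geno$loci, `[[`, "", "locus_id")
  groups <- rownames(counts[[1]])
  fixed <- matrix(FALSE, length(ids), length(groups),
                  dimnames = list(ids, groups))
  for (l in seq_along(counts)) {
    m <- counts[[l]]
    fixed[l, ] <- rowSums(m > 0) == 1 & rowSums(m) > 0
  }
  fixed_sets <- lapply(seq_along(groups), function(k) ids[fixed[, k]])
  names(fixed_sets) <- groups
  any_fixed <- rowSums(fixed) > 0
  combo <- apply(fixed[any_fixed, , drop = FALSE], 1, function(r) {
    paste(groups[r], collapse = "+")
  })
  inter <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(inter) <- c("combination", "count")

  fixed_ids <- ids[any_fixed]
  gd <- NULL
  if (length(fixed_ids)) {
    pooled <- lapply(counts[match(fixed_ids, ids)], colSums)
    if (is.null(g_global)) {
      g_global <- min(unlist(lapply(counts, rowSums)))
    }
    gd <- data.frame(
      locus_id = fixed_ids,
      A_g = vapply(pooled, function(ac) {
        rarefied_allele_count(ac, min(g_global, sum(ac)))
      }, 0),
      H = vapply(pooled, nei_gene_diversity, 0),
      stringsAsFactors = FALSE)
  }
  list(fixed_sets = fixed_sets, intersections = inter, global_diversity = gd)
}

#' Friedman + pairwise Wilcoxon comparison of diversity across groups
#'
#' Loci are blocks, groups are treatments. Only complete blocks (loci with a
#' record in every group) enter; incomplete loci are dropped and counted.
#' Pairwise post hoc tests are Wilcoxon signed-rank on per-locus paired
#' differences, BH-adjusted across pairs.
#'
#' @param records long data.frame from [diversity_records()].
#' @param metric one of `"H"`, `"A_g"`, `"E5"`.
#' @return list: `friedman` (Q, df, p), `pairwise` (group pair, p, q_bh),
#'   `n_blocks`, `n_dropped`.
#' @export
compare_diversity <- function(records, metric = c("H", "A_g", "E5")) {
  metric <- match.arg(metric)
  groups <- unique(records$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  wide <- tapply(records[[metric]], list(records$locus_id, records$group),
                 identity)
  wide <- wide[, groups, drop = FALSE]
  complete <- complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2) stop("fewer than 2 complete blocks")
  storage.mode(wide) <- "double"
  fr <- friedman.test(wide)
  out <- list()
  for (i in seq_len(length(groups) - 1)) for (j in seq(i + 1, length(groups))) {
    d <- wide[, i] - wide[, j]
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(wilcox.test(wide[, i], wide[, j], paired = TRUE,
                                   exact = FALSE)$p.value)
    }
    out[[length(out) + 1L]] <- data.frame(
      group_a = groups[i], group_b = groups[j], p = p, stringsAsFactors = FALSE)
  }
  pw <- do.call(rbind, out)
  pw$q_bh <- bh_adjust(pw$p)
  list(friedman = list(Q = unname(fr$statistic), df = unname(fr$parameter),
                       p = fr$p.value),
       pairwise = pw, n_blocks = nrow(wide), n_dropped = n_dropped,
       metric = metric)
}
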