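# Per-locus sequence statistics (S, k_hat, Watterson's and pairwise theta,
# Tajima's D), the beta-approximation per-locus test, genome-wide tests
# against fixed-S coalescent null distributions, and rank-based theta
# comparisons between groups.

#' Tajima (1989) constants
#'
#' @param n number of gene copies (>= 4; the variance terms degenerate below).
#' @return list with `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima constants require n >= 4")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-locus neutrality statistics from aligned haplotypes
#'
#' Computes the number of segregating sites S, the mean pairwise difference
#' k_hat, Watterson's theta (S / a1) and pairwise theta (k_hat), each both
#' per locus and per site, and Tajima's D with its two-sided beta p-value.
#' D is undefined (NA) for monomorphic loci and left untested when `n < 4`.
#'
#' @param haplotypes character vector of aligned allele strings (one per
#'   distinct haplotype, or one per copy with `counts = NULL`).
#' @param counts optional multiplicities matching `haplotypes`.
#' @param locus_id identifier carried into the result.
#' @param length_bp sites used for the per-site variants (defaults to the
#'   string length).
#' @return list of class `locus_neutrality`: `locus_id`, `n`, `S`, `k_hat`,
#'   `theta_W`, `theta_T`, `theta_W_site`, `theta_T_site`, `D`, `p_beta`,
#'   `sign`.
#' @export
locus_stats <- function(haplotypes, counts = NULL, locus_id = NA_character_,
                        length_bp = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(haplotypes))
  stopifnot(length(counts) == length(haplotypes), all(counts >= 0))
  keep <- counts > 0
  haplotypes <- haplotypes[keep]; counts <- counts[keep]
  n <- sum(counts)
  if (n < 2) stop("locus_stats needs at least 2 gene copies")
  if (length(unique(nchar(haplotypes))) != 1) stop("haplotypes differ in length")
  if (is.null(length_bp)) length_bp <- nchar(haplotypes[1])

  chars <- do.call(rbind, strsplit(haplotypes, "", fixed = TRUE))
  pairs <- n * (n - 1) / 2
  # per site: mismatching pairs = C(n,2) - sum_a C(c_a,2)
  mism <- apply(chars, 2, function(col) {
    cs <- rowsum(counts, col)[, 1]
    pairs - sum(cs * (cs - 1) / 2)
  })
  S <- sum(mism > 0)
  k_hat <- sum(mism) / pairs
  a1 <- sum(1 / seq_len(n - 1))
  theta_W <- S / a1
  D <- NA_real_; p_beta <- NA_real_
  if (S > 0 && n >= 4) {
    tc <- tajima_constants(n)
    D <- (k_hat - S / a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
    p_beta <- tajima_test_beta(D, n)
  }
  sign <- if (is.na(D)) "undefined" else if (D >= 0) "positive" else "negative"
  structure(list(locus_id = locus_id, n = n, S = S, k_hat = k_hat,
                 theta_W = theta_W, theta_T = k_hat,
                 theta_W_site = theta_W / length_bp,
                 theta_T_site = k_hat / length_bp,
                 D = D, p_beta = p_beta, sign = sign),
            class = "locus_neutrality")
}

#' Per-locus statistics from a binary site matrix
#'
#' Same statistics as [locus_stats()], computed from a derived-allele matrix
#' (the coalescent simulator's native output); equivalent to the haplotype
#' route by construction.
#'
#' @param site_matrix samples x sites 0/1 matrix.
#' @param locus_id,length_bp as in [locus_stats()].
#' @return a `locus_neutrality` list.
#' @export
locus_stats_sites <- function(site_matrix, locus_id = NA_character_,
                              length_bp = NULL) {
  n <- nrow(site_matrix)
  if (n < 2) stop("needs at least 2 gene copies")
  if (is.null(length_bp)) length_bp <- max(1L, ncol(site_matrix))
  if (ncol(site_matrix) == 0) {
    return(locus_stats("A", 1L * n, locus_id = locus_id, length_bp = length_bp))
  }
  haps <- apply(site_matrix, 1, paste, collapse = "")
  tab <- table(haps)
  strings <- chartr("01", "AC", names(tab))
  locus_stats(strings, as.integer(tab), locus_id = locus_id, length_bp = length_bp)
}

#' Two-sided beta-approximation test for Tajima's D
#'
#' Tajima's (1989) confidence-limit construction: D is assumed to follow a
#' scaled beta distribution on `[Dmin, Dmax]` with mean 0 and variance 1,
#' where `Dmin = (2/n - 1/a1)/sqrt(e2)` and
#' `Dmax = ((n+1)/(2n) - 1/a1)/sqrt(e2)`. The two-sided p doubles the smaller
#' tail. D outside the support (beyond numerical tolerance) is clamped with
#' a warning.
#'
#' @param D observed Tajima's D.
#' @param n gene copies (>= 4).
#' @return two-sided p-value.
#' @export
tajima_test_beta <- function(D, n) {
  if (is.na(D)) stop("D is undefined")
  tc <- tajima_constants(n)
  Dmin <- (2 / n - 1 / tc$a1) / sqrt(tc$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / tc$a1) / sqrt(tc$e2)
  if (D < Dmin || D > Dmax) {
    if (D < Dmin - 1e-8 || D > Dmax + 1e-8) {
      warning("D = ", signif(D, 4), " outside beta support [", signif(Dmin, 4),
              ", ", signif(Dmax, 4), "]; clamped")
    }
    D <- min(max(D, Dmin), Dmax)
  }
  # shape parameters so that the rescaled variate has mean 0, variance 1
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  p <- pbeta((D - Dmin) / (Dmax - Dmin), beta, alpha)
  min(1, 2 * min(p, 1 - p))
}

#' Density of Tajima's beta-approximated null for D
#'
#' Exposed so the distribution itself can be validated by quadrature.
#'
#' @param x evaluation points.
#' @param n gene copies.
#' @return density values.
#' @export
tajima_beta_density <- function(x, n) {
  tc <- tajima_constants(n)
  Dmin <- (2 / n - 1 / tc$a1) / sqrt(tc$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / tc$a1) / sqrt(tc$e2)
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  ifelse(x <= Dmin | x >= Dmax, 0,
         gamma(alpha + beta) * (Dmax - x)^(alpha - 1) * (x - Dmin)^(beta - 1) /
           (gamma(alpha) * gamma(beta) * (Dmax - Dmin)^(alpha + beta - 1)))
}

#' Per-estuary locus statistics for a dataset
#'
#' Applies [locus_stats()] to every locus within each group (individuals
#' pooled as 2n gene copies; missing calls reduce n per locus). Loci with
#' fewer than 4 gene copies in a group are skipped for that group.
#'
#' @param ds an `mh_dataset`.
#' @param level grouping level, `"estuary"` or `"basin"`.
#' @return `data.frame` with one row per (group, locus): n, S, k_hat,
#'   theta_W, theta_T (per locus and per site), D, p_beta and the BH-adjusted
#'   q within each group.
#' @export
dataset_neutrality <- function(ds, level = "estuary") {
  grp <- assignment(ds, level)
  g <- ds$genotypes
  ids <- vapply(g$loci, `[[`, "", "locus_id")
  out <- list()
  for (gname in unique(grp)) {
    ind <- names(grp)[grp == gname]
    cols <- match(ind, g$individuals)
    for (l in seq_along(g$loci)) {
      al <- c(g$a1[l, cols], g$a2[l, cols])
      al <- al[!is.na(al)]
      if (length(al) < 4) next
      cnt <- tabulate(al, nbins = length(g$loci[[l]]$alleles))
      st <- locus_stats(g$loci[[l]]$alleles, cnt, locus_id = ids[l],
                        length_bp = g$loci[[l]]$length_bp)
      out[[length(out) + 1L]] <- data.frame(
        group = gname, locus_id = ids[l], n = st$n, S = st$S, k_hat = st$k_hat,
        theta_W = st$theta_W, theta_T = st$theta_T,
        theta_W_site = st$theta_W_site, theta_T_site = st$theta_T_site,
        D = st$D, p_beta = st$p_beta, sign = st$sign,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q_beta <- NA_real_
  for (gname in unique(res$group)) {
    sel <- res$group == gname & !is.na(res$p_beta)
    res$q_beta[sel] <- bh_adjust(res$p_beta[sel])
  }
  res
}

#' Genome-wide test of Tajima's D against fixed-S coalescent nulls
#'
#' For each of `R` replicates, every observed polymorphic locus is matched by
#' one constant-size neutral coalescent locus with the same gene-copy count
#' and exactly the same number of segregating sites; replicate means and
#' medians of D form the null distributions. `p_mean_lower` is the proportion
#' of replicates whose simulated mean is `<=` the observed mean (with the
#' three analogues); `add_one = TRUE` switches to `(1 + count)/(R + 1)`.
#' Monomorphic loci carry no D and are excluded (counted in the result).
#'
#' @param stats data.frame with columns `n`, `S`, `D` (one row per locus in
#'   one group), or a list of `locus_neutrality` objects.
#' @param R number of genome-wide null replicates.
#' @param add_one use the (1+count)/(R+1) estimator instead of the plain
#'   empirical proportion.
#' @return list of class `genome_wide_D_test`: observed mean/median,
#'   replicate means/medians, the four p-values, loci used/excluded.
#' @export
genome_wide_null_test <- function(stats, R = 1000L, add_one = FALSE) {
  if (R < 1) stop("R must be >= 1")
  if (!is.data.frame(stats)) {
    stats <- data.frame(n = vapply(stats, `[[`, 0, "n"),
                        S = vapply(stats, `[[`, 0L, "S"),
                        D = vapply(stats, `[[`, 0, "D"))
  }
  use <- stats$S > 0 & stats$n >= 4 & !is.na(stats$D)
  n_excluded <- sum(!use)
  st <- stats[use, , drop = FALSE]
  if (!nrow(st)) stop("no polymorphic loci with defined D")
  Dm <- null_tajima_D_cpp(as.integer(st$n), as.integer(st$S), as.integer(R),
                          .event_cap)
  rep_means <- rowMeans(Dm)
  rep_medians <- apply(Dm, 1, median)
  obs_mean <- mean(st$D); obs_median <- median(st$D)
  prop <- function(count) if (add_one) (1 + count) / (R + 1) else count / R
  structure(list(
    observed_mean = obs_mean, observed_median = obs_median,
    replicate_means = rep_means, replicate_medians = rep_medians,
    p_mean_lower = prop(sum(rep_means <= obs_mean)),
    p_mean_upper = prop(sum(rep_means >= obs_mean)),
    p_median_lower = prop(sum(rep_medians <= obs_median)),
    p_median_upper = prop(sum(rep_medians >= obs_median)),
    R = R, n_loci = nrow(st), n_excluded = n_excluded),
    class = "genome_wide_D_test")
}

#' Pairwise Mann-Whitney comparisons of per-locus theta between groups
#'
#' Two-sided rank-sum tests on per-locus theta values for every pair of
#' groups, run separately for the Watterson and pairwise estimators, with BH
#' adjustment across the comparison family. Per-locus theta is the default;
#' `per_site = TRUE` switches to the per-site variants.
#'
#' @param stats a `data.frame` from [dataset_neutrality()] (columns `group`,
#'   `theta_W`, `theta_T`, `theta_W_site`, `theta_T_site`).
#' @param per_site compare per-site theta instead of per-locus.
#' @return data.frame: group pair, estimator, p, q_bh.
#' @export
compare_theta <- function(stats, per_site = FALSE) {
  groups <- unique(stats$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  cols <- if (per_site) c(theta_W = "theta_W_site", theta_T = "theta_T_site")
          else c(theta_W = "theta_W", theta_T = "theta_T")
  out <- list()
  for (est in names(cols)) {
    v <- cols[[est]]
    for (i in seq_len(length(groups) - 1)) for (j in seq(i + 1, length(groups))) {
      x <- stats[stats$group == groups[i], v]
      y <- stats[stats$group == groups[j], v]
      if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 loci")
      p <- if (length(unique(c(x, y))) == 1) {
        warning("all theta values tied; p = 1"); 1
      } else {
        suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      }
      out[[length(out) + 1L]] <- data.frame(
        group_a = groups[i], group_b = groups[j], estimator = est, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q_bh <- NA_real_
  for (est in unique(res$estimator)) {
    sel <- res$estimator == est
    res$q_bh[sel] <- bh_adjust(res$p[sel])
  }
  res
}

#' Summarise per-locus neutrality outcomes across estuaries
#'
#' Counts loci significantly positive, negative, or both (in at least one
#' estuary), before and after the per-estuary BH adjustment.
#'
#' @param stats output of [dataset_neutrality()].
#' @param alpha significance threshold.
#' @return list with raw and BH-adjusted cross-estuary counts.
#' @export
summarize_neutrality <- function(stats, alpha = 0.05) {
  count_sets <- function(pcol) {
    sig <- !is.na(stats[[pcol]]) & stats[[pcol]] < alpha
    pos <- unique(stats$locus_id[sig & stats$D > 0])
    neg <- unique(stats$locus_id[sig & stats$D < 0])
    list(n_any = length(union(pos, neg)),
         n_positive = length(setdiff(pos, neg)),
         n_negative = length(setdiff(neg, pos)),
         n_both = length(intersect(pos, neg)))
  }
  list(raw = count_sets("p_beta"), bh = count_sets("q_beta"))
}
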