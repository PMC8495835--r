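# Redundancy analysis from first principles: allele dosage coding,
# environmental PCA, spatial polynomial bases, constrained ordination with
# permutation tests, forward selection with the double stopping rule,
# variance partitioning by inclusion-exclusion on adjusted R2, and
# Mahalanobis flagging of environment-associated alleles.

#' Allele dosage matrix for ordination
#'
#' One column per (locus, allele); entries are diploid dosages 0/1/2.
#' Missing genotypes are imputed with the across-included-individuals mean
#' dosage of the column, then columns are centered. Loci with zero observed
#' copies in the subset are dropped.
#'
#' @param geno an `mh_genotypes`.
#' @param individuals subset of individual ids (default: all).
#' @param min_freq minimum allele frequency for a column to be kept
#'   (columns with frequency outside `[min_freq, 1 - min_freq]` are
#'   dropped). 0 keeps every observed allele; rare-allele columns make
#'   ordination loadings heavy-tailed, so distance-threshold flagging is
#'   only chi-square-calibrated after filtering (see the methods vignette).
#' @return list of class `allele_dosage`: centered `matrix`
#'   (individuals x columns), `column_means`, `locus_of_column`,
#'   `allele_of_column`, `dropped_loci`.
#' @export
code_alleles <- function(geno, individuals = NULL, min_freq = 0) {
  if (is.null(individuals)) individuals <- geno$individuals
  if (length(individuals) < 2) stop("need at least 2 individuals")
  idx <- match(individuals, geno$individuals)
  if (anyNA(idx)) stop("unknown individuals")
  L <- length(geno$loci)
  ids <- vapply(geno$loci, `[[`, "", "locus_id")
  n_alleles <- vapply(geno$loci, function(l) length(l$alleles), 0L)
  blocks <- vector("list", L)
  dropped <- character()
  for (l in seq_len(L)) {
    a1 <- geno$a1[l, idx]; a2 <- geno$a2[l, idx]
    if (all(is.na(a1))) { dropped <- c(dropped, ids[l]); next }
    A <- n_alleles[l]
    m <- matrix(0, length(idx), A)
    ok <- !is.na(a1)
    m[cbind(which(ok), a1[ok])] <- m[cbind(which(ok), a1[ok])] + 1
    m[cbind(which(ok), a2[ok])] <- m[cbind(which(ok), a2[ok])] + 1
    if (any(!ok)) {
      mu <- colSums(m[ok, , drop = FALSE]) / sum(ok)
      m[!ok, ] <- matrix(mu, sum(!ok), A, byrow = TRUE)
    }
    colnames(m) <- paste0(ids[l], ".", seq_len(A))
    blocks[[l]] <- m
  }
  Y <- do.call(cbind, blocks[!vapply(blocks, is.null, TRUE)])
  mu <- colMeans(Y)
  locus_of_column <- rep(ids[!(ids %in% dropped)],
                         n_alleles[!(ids %in% dropped)])
  allele_of_column <- unlist(lapply(which(!(ids %in% dropped)),
                                    function(l) seq_len(n_alleles[l])))
  if (min_freq > 0) {
    keep <- mu / 2 >= min_freq & mu / 2 <= 1 - min_freq
    Y <- Y[, keep, drop = FALSE]
    mu <- mu[keep]
    locus_of_column <- locus_of_column[keep]
    allele_of_column <- allele_of_column[keep]
  }
  structure(list(matrix = sweep(Y, 2, mu), column_means = mu,
                 individuals = individuals,
                 locus_of_column = locus_of_column,
                 allele_of_column = allele_of_column,
                 dropped_loci = dropped),
            class = "allele_dosage")
}

#' PCA of the environmental table
#'
#' Variables are centered and unit-scaled across estuaries (zero-variance
#' variables dropped with a warning) and eigen-decomposed; scores per estuary
#' and percent variance per component are returned.
#'
#' @param env data.frame: `estuary` plus numeric variable columns.
#' @return list of class `env_pca`: `scores` (estuaries x PCs), `loadings`,
#'   `percent_variance`, `dropped`.
#' @export
env_pca <- function(env) {
  if (!"estuary" %in% names(env)) stop("env table needs an 'estuary' column")
  X <- as.matrix(env[, setdiff(names(env), "estuary"), drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 estuaries")
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance variable(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  rownames(scores) <- env$estuary
  structure(list(scores = scores, loadings = pc$rotation,
                 percent_variance = pct, dropped = dropped),
            class = "env_pca")
}

#' Spatial polynomial design from coastal distances
#'
#' Per-individual coastal distance with Gaussian jitter (estuary-mates would
#' otherwise be exact ties), expanded into a centered orthogonal polynomial
#' basis of the given degree.
#'
#' @param coastal_distance_km numeric vector, one entry per individual.
#' @param degree polynomial degree (>= 1).
#' @param jitter_sd_km jitter standard deviation in km.
#' @return matrix (individuals x degree) with orthogonal centered columns.
#' @export
spatial_design <- function(coastal_distance_km, degree = 3L, jitter_sd_km = 2) {
  if (degree < 1) stop("degree must be >= 1")
  x <- coastal_distance_km + rnorm(length(coastal_distance_km), 0, jitter_sd_km)
  if (length(unique(x)) <= degree) {
    stop("distances are rank-deficient for the requested degree; add jitter")
  }
  m <- poly(x, degree = degree)
  m <- sweep(m, 2, colMeans(m))
  colnames(m) <- paste0("dist_poly", seq_len(degree))
  unclass(m)
}

# rank-revealing column pruning via QR
.prune_collinear <- function(X, tol = 1e-9) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  qr_x <- qr(X, tol = tol)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping ", ncol(X) - qr_x$rank, " collinear constraint column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# residuals of Y on (centered) X via least squares
.residualize <- function(Y, X) {
  Q <- qr.Q(qr(cbind(1, X)))
  Y - Q %*% crossprod(Q, Y)
}

#' Redundancy analysis (constrained ordination)
#'
#' Regresses the centered response matrix on the constraints (optionally
#' after partialling out a conditioning matrix from both sides), then
#' eigen-decomposes the fitted values. R2 and adjusted R2 are reported
#' against the total (unconditioned) response variance so that variance
#' fractions from different models are commensurable; the pseudo-F and its
#' permutation test use the conditioned residual space.
#'
#' @param Y an `allele_dosage` object or centered numeric matrix.
#' @param X constraint matrix (individuals x variables).
#' @param Z optional conditioning matrix.
#' @param n_perm permutations for the pseudo-F test (0 disables).
#' @return an `rda_model`: eigenvalues, `R2`, `adjR2`,
#'   `axis_percent_constrained`, `site_scores`, `allele_loadings` (right
#'   singular vectors), `pseudo_F`, `p_perm`, ranks and df.
#' @export
rda_fit <- function(Y, X, Z = NULL, n_perm = 1000L) {
  dosage <- NULL
  if (inherits(Y, "allele_dosage")) { dosage <- Y; Y <- Y$matrix }
  n <- nrow(Y)
  X <- as.matrix(X)
  X <- .prune_collinear(sweep(X, 2, colMeans(X)))  # center, keep full rank
  m <- ncol(X)
  p_cond <- 0L
  ss_total <- sum(Y^2)
  Ywork <- Y; Xwork <- X
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    Z <- .prune_collinear(sweep(Z, 2, colMeans(Z)))
    p_cond <- ncol(Z)
    Ywork <- .residualize(Y, Z)
    Xwork <- .prune_collinear(.residualize(X, Z))
    m <- ncol(Xwork)
  }
  df_res <- n - m - p_cond - 1
  if (df_res < 0) stop("too few individuals for the requested model")
  Qx <- qr.Q(qr(Xwork))[, seq_len(m), drop = FALSE]
  # all statistics live in the m-dimensional constraint space: decompose the
  # reduced m x c matrix instead of the n x c fitted values
  B <- crossprod(Qx, Ywork)
  sv <- svd(B)
  pos <- sv$d > max(sv$d) * 1e-9
  eig <- (sv$d[pos]^2) / (n - 1)
  ss_fit <- sum(B^2)
  ss_work <- sum(Ywork^2)
  ss_res <- ss_work - ss_fit
  R2 <- ss_fit / ss_total
  # saturated models (df_res = 0) leave no residual df for adjustment/testing
  adjR2 <- if (df_res > 0) 1 - (1 - R2) * (n - 1) / df_res else NA_real_
  pseudo_F <- if (df_res > 0) (ss_fit / m) / (ss_res / df_res) else NA_real_
  p_perm <- NA_real_
  if (n_perm > 0 && df_res > 0) {
    # permute rows of the (residualised) response; since Qx and the
    # conditioning basis Qz are orthogonal, the permuted-response statistics
    # reduce to crossprods with row-permuted Q factors (no response copies)
    Qz <- if (p_cond > 0) qr.Q(qr(Z)) else NULL  # Z centered above
    count <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample(n)
      ssf <- sum(crossprod(Qx[pi, , drop = FALSE], Ywork)^2)
      ssz <- if (p_cond > 0) {
        sum(crossprod(Qz[pi, , drop = FALSE], Ywork)^2)
      } else 0
      ssr <- ss_work - ssz - ssf
      Fb <- (ssf / m) / (ssr / df_res)
      if (Fb >= pseudo_F) count <- count + 1L
    }
    p_perm <- (count + 1) / (n_perm + 1)
  }
  V <- sv$v[, pos, drop = FALSE]
  rownames(V) <- colnames(Y)
  site <- Ywork %*% V
  structure(list(
    n = n, m = m, p_cond = p_cond,
    canonical_eigenvalues = eig, R2 = R2, adjR2 = adjR2,
    axis_percent_constrained = 100 * eig / sum(eig),
    site_scores = site, allele_loadings = V,
    pseudo_F = pseudo_F, p_perm = p_perm, n_perm = n_perm,
    ss_total = ss_total, ss_fit = ss_fit, ss_res = ss_res,
    dosage_meta = if (!is.null(dosage)) {
      list(locus_of_column = dosage$locus_of_column,
           allele_of_column = dosage$allele_of_column)
    }),
    class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("<rda_model> n = %d, m = %d, cond = %d | R2 = %.4g, adjR2 = %.4g, F = %.3g, p = %s\n",
              x$n, x$m, x$p_cond, x$R2, x$adjR2, x$pseudo_F, format(x$p_perm)))
  invisible(x)
}

#' Forward selection of constraint columns
#'
#' Iteratively adds the candidate that most increases adjusted R2, subject to
#' a permutation test on the added column (conditional on the current
#' selection) at level `alpha` and to the cumulative adjusted R2 not
#' exceeding that of the full-candidate model (the double stopping rule).
#'
#' @param Y response (`allele_dosage` or centered matrix).
#' @param candidates named matrix of candidate columns.
#' @param alpha permutation significance threshold for adding a column.
#' @param n_perm permutations per candidate test.
#' @return list: `selected` (column names in order), `trace` data.frame
#'   (step, column, adjR2_cum, p), `adjR2_full`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 1000L) {
  if (inherits(Y, "allele_dosage")) Y <- Y$matrix
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates))) {
    colnames(candidates) <- paste0("cand", seq_len(ncol(candidates)))
  }
  full <- rda_fit(Y, candidates, n_perm = 0)
  adjR2_full <- full$adjR2
  selected <- character()
  trace <- list()
  remaining <- colnames(candidates)
  current_adj <- 0
  repeat {
    if (!length(remaining)) break
    best <- NULL
    for (cand in remaining) {
      Xtry <- candidates[, c(selected, cand), drop = FALSE]
      fit <- rda_fit(Y, Xtry, n_perm = 0)
      if (is.null(best) || fit$adjR2 > best$adjR2) {
        best <- list(cand = cand, adjR2 = fit$adjR2)
      }
    }
    # adjusted-R2 cap: guards against over-selection; applied from the second
    # addition on (a lone strong candidate can exceed the full-candidate
    # model's adjR2 by pure degrees-of-freedom accounting)
    if (length(selected) >= 1 && best$adjR2 > adjR2_full + 1e-12) break
    # test the added column conditional on the current selection
    Z <- if (length(selected)) candidates[, selected, drop = FALSE] else NULL
    fit_test <- rda_fit(Y, candidates[, best$cand, drop = FALSE], Z = Z,
                        n_perm = n_perm)
    if (fit_test$p_perm > alpha) break
    selected <- c(selected, best$cand)
    remaining <- setdiff(remaining, best$cand)
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), column = best$cand, adjR2_cum = best$adjR2,
      p = fit_test$p_perm, stringsAsFactors = FALSE)
    current_adj <- best$adjR2
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), column = character(),
                    adjR2_cum = numeric(), p = numeric()),
       adjR2_full = adjR2_full)
}

#' Variance partitioning between environment and space
#'
#' Adjusted R2 of the env-only (`[a+b]`), space-only (`[b+c]`) and combined
#' (`[a+b+c]`) models; unique and shared fractions by inclusion-exclusion:
#' `[a] = [a+b+c] - [b+c]`, `[c] = [a+b+c] - [a+b]`,
#' `[b] = [a+b] + [b+c] - [a+b+c]`, residual `= 1 - [a+b+c]` (components may
#' be negative on the adjusted scale). Permutation tests cover `[a+b]`,
#' `[b+c]`, and the unique fractions via the corresponding partial models.
#'
#' @param Y response (`allele_dosage` or centered matrix).
#' @param X_env environmental constraint matrix.
#' @param X_xy spatial constraint matrix.
#' @param n_perm permutations per test.
#' @return a `varpart_result` list.
#' @export
varpart <- function(Y, X_env, X_xy, n_perm = 1000L) {
  if (inherits(Y, "allele_dosage")) Y <- Y$matrix
  m_env <- rda_fit(Y, X_env, n_perm = n_perm)
  m_xy <- rda_fit(Y, X_xy, n_perm = n_perm)
  m_full <- rda_fit(Y, cbind(X_env, X_xy), n_perm = n_perm)
  m_env_unique <- rda_fit(Y, X_env, Z = X_xy, n_perm = n_perm)
  m_xy_unique <- rda_fit(Y, X_xy, Z = X_env, n_perm = n_perm)
  ab <- m_env$adjR2; bc <- m_xy$adjR2; abc <- m_full$adjR2
  structure(list(
    adjR2_env_total = ab, adjR2_xy_total = bc, adjR2_full = abc,
    env_unique = abc - bc, xy_unique = abc - ab, shared = ab + bc - abc,
    residual = 1 - abc,
    p_env_total = m_env$p_perm, p_xy_total = m_xy$p_perm,
    p_full = m_full$p_perm,
    p_env_unique = m_env_unique$p_perm, p_xy_unique = m_xy_unique$p_perm,
    models = list(env = m_env, xy = m_xy, full = m_full)),
    class = "varpart_result")
}

#' Variance-partition fractions from marginal adjusted R2 values
#'
#' The inclusion-exclusion identity used throughout: given `[a+b]`, `[b+c]`
#' and either `[a+b+c]` or `[b]`, reconstruct all fractions.
#'
#' @param adjR2_env_total adjusted R2 of the env-only model (`[a+b]`).
#' @param adjR2_xy_total adjusted R2 of the space-only model (`[b+c]`).
#' @param adjR2_full combined-model adjusted R2 (`[a+b+c]`), or `NULL` if
#'   `shared` is given.
#' @param shared shared fraction `[b]`, or `NULL` if `adjR2_full` is given.
#' @return list with all seven fractions.
#' @export
varpart_fractions <- function(adjR2_env_total, adjR2_xy_total,
                              adjR2_full = NULL, shared = NULL) {
  if (is.null(adjR2_full) + is.null(shared) != 1) {
    stop("give exactly one of adjR2_full or shared")
  }
  if (is.null(adjR2_full)) adjR2_full <- adjR2_env_total + adjR2_xy_total - shared
  list(adjR2_env_total = adjR2_env_total, adjR2_xy_total = adjR2_xy_total,
       adjR2_full = adjR2_full,
       shared = adjR2_env_total + adjR2_xy_total - adjR2_full,
       env_unique = adjR2_full - adjR2_xy_total,
       xy_unique = adjR2_full - adjR2_env_total,
       residual = 1 - adjR2_full)
}

#' Mahalanobis flagging of environment-associated alleles
#'
#' Squared Mahalanobis distance of each allele's loadings on the first two
#' canonical axes from the empirical centroid and covariance of all
#' loadings; alleles with `D^2 > threshold` are flagged, a locus is flagged
#' when any of its alleles is, and flagged loci are annotated with linkage
#' groups when a map is given.
#'
#' @param model an `rda_model` fitted on an `allele_dosage` response.
#' @param threshold flagging threshold on `D^2`.
#' @param map optional linkage map data.frame (`locus_id`, `linkage_group`).
#' @return a `gea_flags` list: per-allele table, flagged locus ids,
#'   per-linkage-group counts (when mapped).
#' @export
mahalanobis_flags <- function(model, threshold = 25, map = NULL) {
  if (length(model$canonical_eigenvalues) < 2) {
    stop("model has fewer than 2 canonical axes")
  }
  L <- model$allele_loadings[, 1:2, drop = FALSE]
  if (nrow(L) < 3) stop("need at least 3 allele columns for a covariance")
  D2 <- mahalanobis(L, colMeans(L), cov(L))
  flagged <- D2 > threshold
  ids <- model$dosage_meta$locus_of_column %||% rownames(L) %||%
    paste0("col", seq_len(nrow(L)))
  tab <- data.frame(
    locus_id = ids,
    allele = model$dosage_meta$allele_of_column %||% seq_len(nrow(L)),
    loading1 = L[, 1], loading2 = L[, 2], mahalanobis_D2 = D2,
    flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
  flagged_loci <- unique(tab$locus_id[tab$flagged])
  lg_counts <- NULL
  if (!is.null(map) && length(flagged_loci)) {
    mm <- map[map$locus_id %in% flagged_loci, , drop = FALSE]
    if (nrow(mm)) {
      lg_counts <- as.data.frame(table(linkage_group = mm$linkage_group),
                                 stringsAsFactors = FALSE)
      names(lg_counts) <- c("linkage_group", "n_flagged")
    }
  }
  structure(list(table = tab, flagged_loci = flagged_loci,
                 linkage_group_counts = lg_counts, threshold = threshold),
            class = "gea_flags")
}
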