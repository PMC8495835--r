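#' @useDynLib microhapgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats p.adjust pbeta integrate prcomp poly rnorm runif rpois
#'   friedman.test wilcox.test ks.test mahalanobis pchisq median sd var cov
#'   complete.cases quantile setNames
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1, returned in the
#' input order. Applied within one analysis family at a time (a pairwise
#' F_ST matrix, an outlier scan, per-locus neutrality tests within an
#' estuary), never pooled across families.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (anyNA(p)) stop("p-values must not contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stage seeds derived from one master seed
#'
#' Every stochastic stage draws its seed from a single master seed through a
#' fixed named map, so whole-pipeline runs are reproducible from one integer
#' and stages stay independent. Offsets keep seeds below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  offsets <- c(simulate = 101L, diversity = 211L, amova = 307L,
               pairwise_fst = 401L, outliers = 503L, neutrality = 601L,
               rda = 701L, varpart = 809L, gea = 907L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master_seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Default analysis configuration
#'
#' Permutation/simulation sizes and thresholds used by the analysis drivers:
#' 10,000 AMOVA permutations, 20,000 outlier-scan simulations, 1,000
#' genome-wide null replicates, 1,000 ordination permutations, a minimum
#' group size of 18 individuals, a Mahalanobis flagging threshold of 25 and a
#' BH q threshold of 0.05.
#'
#' @return named list of stage parameters.
#' @export
default_run_config <- function() {
  list(n_perm_amova = 10000L, n_sims_outlier = 20000L, n_null_reps = 1000L,
       n_perm_rda = 1000L, min_group_n = 18L, mahalanobis_threshold = 25,
       q_threshold = 0.05, d_sim = 100L, het_bins = 20L)
}
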