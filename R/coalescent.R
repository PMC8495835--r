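# Hudson-style coalescent simulation. Time is measured in units of 2N
# generations: the pairwise within-deme coalescence rate is 1, a scaled
# migration rate M = 4Nm gives a per-lineage migration rate of M/2, and in
# theta mode the number of mutations is Poisson(theta * T_total / 2), so
# E[S] = theta * a1 with a1 = sum_{k=1}^{n-1} 1/k. Exponential growth at rate
# alpha (in 2N units) shrinks all demes backwards in time, handled exactly by
# integrating the time-inhomogeneous coalescence hazard.

.event_cap <- 1e7

#' Island-model migration rate matrix
#'
#' Strict island model: each lineage leaves its deme at total rate `M / 2`
#' and moves to a uniformly chosen other deme.
#'
#' @param d number of demes.
#' @param M scaled migration rate 4Nm (total per-lineage rate `M/2`).
#' @return `d x d` backwards migration rate matrix.
#' @export
island_migration <- function(d, M) {
  if (d < 1) stop("d must be >= 1")
  if (M < 0) stop("M must be non-negative")
  m <- matrix(if (d > 1) M / 2 / (d - 1) else 0, d, d)
  diag(m) <- 0
  m
}

#' Simulate a coalescent genealogy
#'
#' @param sample_sizes integer vector of gene copies sampled per deme (length
#'   1 for a single panmictic deme).
#' @param migration either a `d x d` backwards rate matrix or a scalar `M`
#'   interpreted through [island_migration()].
#' @param alpha exponential growth rate in 2N units (0 = constant size).
#' @return a `coal_genealogy`: 1-based `parent` pointers (0 marks the root),
#'   `node_time`, per-node `tip_count`, `deme_of_sample`,
#'   `total_branch_length` and the migration-event count.
#' @export
sim_genealogy <- function(sample_sizes, migration = 0, alpha = 0) {
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 0) || sum(sample_sizes) < 2) {
    stop("need at least 2 gene copies in total")
  }
  d <- length(sample_sizes)
  mig <- if (is.matrix(migration)) {
    if (!all(dim(migration) == c(d, d))) stop("migration matrix must be d x d")
    migration
  } else {
    island_migration(d, migration)
  }
  g <- coal_genealogy_cpp(sample_sizes, mig, alpha, .event_cap)
  class(g) <- "coal_genealogy"
  g
}

#' Drop mutations on a genealogy
#'
#' Places mutations uniformly on total branch length under infinite sites:
#' `fixed_S` mode places exactly `S` mutations (conditioning only on S, not
#' on tree shape); `theta` mode first draws `S ~ Poisson(theta * T_total / 2)`.
#'
#' @param genealogy a `coal_genealogy`.
#' @param S exact number of segregating sites (fixed-S mode), or `NULL`.
#' @param theta per-locus scaled mutation rate (theta mode), or `NULL`.
#' @return a `sim_locus`: binary `site_matrix` (samples x S, derived = 1),
#'   `deme_of_sample`, `total_branch_length`, `S`.
#' @export
drop_mutations <- function(genealogy, S = NULL, theta = NULL) {
  if (is.null(S) == is.null(theta)) stop("give exactly one of S or theta")
  if (genealogy$n_tips < 2) stop("mutation dropping needs n >= 2")
  if (is.null(S)) {
    if (theta <= 0) stop("theta must be positive")
    S <- rpois(1L, theta * genealogy$total_branch_length / 2)
  }
  if (S < 0) stop("S must be non-negative")
  sm <- drop_mutations_cpp(genealogy$parent, genealogy$node_time,
                           genealogy$n_tips, as.integer(S))
  structure(list(site_matrix = sm, deme_of_sample = genealogy$deme_of_sample,
                 total_branch_length = genealogy$total_branch_length,
                 S = as.integer(S)),
            class = "sim_locus")
}

#' Simulate one island-model locus
#'
#' Convenience composition of [sim_genealogy()] and [drop_mutations()] for
#' the finite island model. Zero migration with samples spread over several
#' demes is caught by the event guard and raised as an error.
#'
#' @inheritParams sim_genealogy
#' @inheritParams drop_mutations
#' @return a `sim_locus`.
#' @export
sim_island_locus <- function(sample_sizes, M, S = NULL, theta = NULL, alpha = 0) {
  if (sum(sample_sizes > 0) > 1 && M <= 0) {
    stop("M = 0 with samples in more than one deme never coalesces")
  }
  drop_mutations(sim_genealogy(sample_sizes, M, alpha), S = S, theta = theta)
}

#' Haplotype strings from a simulated locus
#'
#' Concatenates per-site states into allele strings (ancestral `A`, derived
#' `C`); a locus with `S = 0` yields the single-character monomorphic
#' haplotype.
#'
#' @param locus a `sim_locus`.
#' @return character vector, one haplotype per sampled gene copy.
#' @export
sim_haplotypes <- function(locus) {
  sm <- locus$site_matrix
  n <- nrow(sm)
  if (ncol(sm) == 0) return(rep("A", n))
  chars <- matrix(c("A", "C")[sm + 1L], nrow = n)
  apply(chars, 1, paste, collapse = "")
}
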