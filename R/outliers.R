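# fdist-style F_ST outlier scan: simulate a neutral strict-island-model
# F_ST ~ heterozygosity joint distribution at a migration rate calibrated to
# the observed global F_ST, then test each observed locus against simulated
# loci in its heterozygosity stratum (high tail only; marine background F_ST
# is low and a balancing-selection tail is not assessed). Multiallelic
# microhaplotypes are emulated by collapsing infinite-sites haplotypes to
# allele identities, exactly how the observed F_ST treats alleles.

#' Calibrate the island-model migration rate to a target F_ST
#'
#' Starts from the finite-island closed form
#' `M = (1/F - 1) * ((d-1)/d)^2` and refines by bisection on the mean
#' simulated F_ST (ratio-of-sums over a pilot batch of loci, common random
#' numbers across candidate M values) until within `tol` of the target.
#'
#' @param target_fst target mean F_ST in (0, 1).
#' @param d_sim number of demes simulated.
#' @param sample_sizes gene copies per sampled deme (demes beyond
#'   `length(sample_sizes)` are unsampled).
#' @param n_pilot pilot loci per evaluation.
#' @param theta_range per-locus theta drawn log-uniformly over this range
#'   (default scales with `1/d_sim` because within-deme tree depth grows
#'   with the deme count).
#' @param tol absolute tolerance on the recovered mean F_ST.
#' @param max_steps bisection step cap.
#' @return list: `M`, `mean_fst`, `steps`, `target_fst`.
#' @export
calibrate_migration <- function(target_fst, d_sim, sample_sizes,
                                n_pilot = 2000L,
                                theta_range = c(0.5, 5) / d_sim,
                                tol = 0.005, max_steps = 30L) {
  if (target_fst <= 0 || target_fst >= 1) stop("target_fst must be in (0, 1)")
  M0 <- (1 / target_fst - 1) * ((d_sim - 1) / d_sim)^2
  if (M0 > 1e4) stop("target F_ST too small: required M exceeds cap")
  batch_seed <- sample.int(2147483646L, 1)
  eval_mean <- function(M) {
    # common random numbers: same seed for every candidate M
    set.seed(batch_seed)
    sims <- simulate_island_batch(n_pilot, d_sim, M, sample_sizes, theta_range)
    sum(sims$sigma_among, na.rm = TRUE) /
      sum(sims$sigma_among + sims$sigma_within, na.rm = TRUE)
  }
  # mean F_ST decreases in M; bracket the target
  lo <- M0 / 8; hi <- M0 * 8
  f_lo <- eval_mean(lo); f_hi <- eval_mean(hi)
  if (!(f_lo > target_fst && f_hi < target_fst)) {
    stop("calibration bracket failed: F(", signif(lo, 3), ") = ", signif(f_lo, 3),
         ", F(", signif(hi, 3), ") = ", signif(f_hi, 3))
  }
  M <- M0; fmid <- eval_mean(M); steps <- 1L
  while (abs(fmid - target_fst) > tol && steps < max_steps) {
    if (fmid > target_fst) lo <- M else hi <- M
    M <- sqrt(lo * hi)  # bisection on log scale (F_ST ~ 1/(1+cM))
    fmid <- eval_mean(M)
    steps <- steps + 1L
  }
  if (abs(fmid - target_fst) > tol) {
    stop("migration calibration did not converge in ", max_steps,
         " steps (last mean F_ST = ", signif(fmid, 4), ")")
  }
  list(M = M, mean_fst = fmid, steps = steps, target_fst = target_fst)
}

#' Simulate a batch of island-model loci
#'
#' @param n_loci number of loci.
#' @param d_sim total demes; samples occupy the first `length(sample_sizes)`.
#' @param M scaled migration rate.
#' @param sample_sizes gene copies per sampled deme.
#' @param theta_range log-uniform range for the per-locus theta.
#' @return data.frame: per-locus `fst`, `sigma_among`, `sigma_within`,
#'   `het`, `n_alleles`.
#' @export
simulate_island_batch <- function(n_loci, d_sim, M, sample_sizes,
                                  theta_range = c(0.2, 2)) {
  ss <- integer(d_sim)
  ss[seq_along(sample_sizes)] <- sample_sizes
  P <- length(sample_sizes)
  deme <- rep.int(seq_len(P), sample_sizes)
  mig <- island_migration(d_sim, M)
  theta <- exp(runif(n_loci, log(theta_range[1]), log(theta_range[2])))
  out <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    al <- sim_locus_alleles_cpp(ss, mig, 0, -1L, theta[i], .event_cap)
    cnts <- matrix(0L, P, max(al))
    for (p in seq_len(P)) cnts[p, ] <- tabulate(al[deme == p], nbins = max(al))
    st <- fst_from_counts(cnts)
    out[[i]] <- c(fst = st$fst, sigma_among = st$sigma_among,
                  sigma_within = st$sigma_within, het = st$het,
                  n_alleles = max(al))
  }
  as.data.frame(do.call(rbind, out))
}

#' fdist-style F_ST outlier scan
#'
#' Observed per-locus F_ST and within-population gene diversity are computed
#' by the shared AMOVA primitive; the migration rate is calibrated to the
#' observed global F_ST; `n_sims` island-model loci are simulated with
#' matched per-population gene-copy counts; each observed locus gets
#' `p_high = P(F_sim >= F_obs)` among simulated loci in its heterozygosity
#' stratum (equal-count bins, widened below `min_per_bin`), then BH across
#' loci. Only the high tail is tested.
#'
#' @param geno an `mh_genotypes`.
#' @param populations named vector individual -> population.
#' @param n_sims simulated loci.
#' @param d_sim demes in the simulated island model.
#' @param n_bins heterozygosity strata (equal-count).
#' @param min_per_bin minimum simulated loci per stratum.
#' @param q_threshold BH threshold for flagging.
#' @param theta_range log-uniform per-locus theta range (default spans the
#'   observed heterozygosities).
#' @return an `outlier_scan`: per-locus table (locus_id, fst_obs, het_obs,
#'   p_high, q_bh, flagged) plus scan metadata.
#' @export
fdist_scan <- function(geno, populations, n_sims = 20000L, d_sim = 100L,
                       n_bins = 20L, min_per_bin = 100L, q_threshold = 0.05,
                       theta_range = NULL) {
  counts <- allele_counts_by_pop(geno, populations)
  obs <- lapply(counts, fst_from_counts)
  fst_obs <- vapply(obs, `[[`, 0, "fst")
  het_obs <- vapply(obs, `[[`, 0, "het")
  ids <- vapply(geno$loci, `[[`, "", "locus_id")
  usable <- !is.na(fst_obs)
  global_fst <- sum(vapply(obs[usable], `[[`, 0, "sigma_among")) /
    sum(vapply(obs[usable], function(x) x$sigma_among + x$sigma_within, 0))
  if (global_fst <= 0) {
    # no differentiation to calibrate against: use a nominal low target
    global_fst <- 0.001
  }
  # matched per-population gene-copy counts: the full-data (maximal) counts
  full_sizes <- apply(vapply(counts, rowSums, numeric(nrow(counts[[1]]))), 1, max)
  if (is.null(theta_range)) {
    # theta giving expected within-deme diversity h: h/(1-h) is the effective
    # pairwise theta, and within-deme coalescence times in a d-deme island
    # model are inflated by d, so the per-locus simulation theta is
    # h/(1-h)/d_sim (spanning the observed heterozygosities)
    h <- het_obs[usable & het_obs > 0 & het_obs < 1]
    if (!length(h)) h <- 0.5
    qs <- quantile(h, c(0.05, 0.95))
    theta_range <- pmax(qs / (1 - qs) / d_sim, 1e-3)
    if (theta_range[1] >= theta_range[2]) theta_range <- theta_range[1] * c(0.5, 2)
    theta_range <- unname(theta_range)
  }
  cal <- calibrate_migration(global_fst, d_sim, full_sizes,
                             theta_range = theta_range)
  sims <- simulate_island_batch(n_sims, d_sim, cal$M, full_sizes, theta_range)
  sims <- sims[!is.na(sims$fst) & !is.na(sims$het), , drop = FALSE]

  # equal-count heterozygosity strata over the simulated loci
  p_high <- rep(NA_real_, length(fst_obs))
  eligible <- usable & !is.na(het_obs)
  bins <- n_bins
  repeat {
    brks <- unique(quantile(sims$het, probs = seq(0, 1, length.out = bins + 1)))
    stratum <- cut(sims$het, brks, include.lowest = TRUE)
    if (min(table(stratum)) >= min_per_bin || bins == 1) break
    bins <- bins - 1L
  }
  if (bins < n_bins) {
    warning("heterozygosity strata widened to ", bins,
            " bins to keep >= ", min_per_bin, " simulated loci per bin")
  }
  obs_stratum <- cut(pmin(pmax(het_obs, min(sims$het)), max(sims$het)),
                     brks, include.lowest = TRUE)
  for (b in levels(stratum)) {
    in_b <- which(eligible & obs_stratum == b)
    if (!length(in_b)) next
    fs <- sims$fst[stratum == b]
    p_high[in_b] <- vapply(fst_obs[in_b],
                           function(f) mean(fs >= f), 0)
  }
  q_bh <- rep(NA_real_, length(p_high))
  ok <- !is.na(p_high)
  q_bh[ok] <- bh_adjust(p_high[ok])
  flagged <- !is.na(q_bh) & q_bh < q_threshold
  structure(list(
    table = data.frame(locus_id = ids, fst_obs = fst_obs, het_obs = het_obs,
                       p_high = p_high, q_bh = q_bh, flagged = flagged,
                       stringsAsFactors = FALSE),
    meta = list(global_fst = global_fst, M = cal$M, mean_sim_fst = cal$mean_fst,
                d_sim = d_sim, n_sims = n_sims, bins = bins,
                theta_range = theta_range, q_threshold = q_threshold)),
    class = "outlier_scan")
}

#' Consensus partition of loci into outlier and neutral sets
#'
#' The outlier set is the intersection of this package's scan flags with an
#' externally supplied second flag list (the study's consensus rule across
#' two detection methods); everything else is neutral. An empty second list
#' (the default) yields a conservative, all-neutral partition.
#'
#' @param scan_flags character vector of flagged locus ids (or an
#'   `outlier_scan` object).
#' @param external_flags character vector of locus ids from a second method
#'   (or a path to a one-id-per-line file).
#' @param all_loci character vector of all analysed locus ids.
#' @return list of class `locus_partition`: `outlier_set`, `neutral_set`.
#' @export
partition_loci <- function(scan_flags, external_flags = character(), all_loci) {
  if (inherits(scan_flags, "outlier_scan")) {
    scan_flags <- scan_flags$table$locus_id[scan_flags$table$flagged]
  }
  if (length(external_flags) == 1 && file.exists(external_flags)) {
    external_flags <- readLines(external_flags)
    external_flags <- external_flags[nzchar(external_flags)]
  }
  if (!all(scan_flags %in% all_loci) || !all(external_flags %in% all_loci)) {
    stop("flag lists must be subsets of the analysed loci")
  }
  outlier <- intersect(scan_flags, external_flags)
  structure(list(outlier_set = outlier,
                 neutral_set = setdiff(all_loci, outlier)),
            class = "locus_partition")
}
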