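# Scenario generator with planted truth. Estuaries are demes of a structured
# coalescent: stepping-stone migration between coastal neighbours within each
# basin, a single migration edge linking the basins (the coastline around the
# biogeographic break), exponential growth in every deme (post-glacial
# expansion signal, genome-wide negative Tajima's D), and a minority of loci
# whose allele frequencies are pushed along a latent environmental axis by
# weighted resampling of gene copies (a selection surrogate that changes
# frequencies without inventing new alleles).

#' Scenario configuration
#'
#' @param estuaries data.frame: `estuary`, `basin`, `coastal_km`, `n_ind`.
#' @param n_loci number of microhaplotype loci.
#' @param length_bp nominal fragment length (bp).
#' @param theta_range per-locus scaled mutation rate drawn log-uniformly.
#' @param M_within scaled migration rate (4Nm) on each within-basin
#'   stepping-stone edge.
#' @param M_between scaled migration rate on the single between-basin edge.
#' @param alpha exponential growth rate (2N units) in every deme.
#' @param n_env_vars observable environmental variables.
#' @param n_signal_axes latent environmental axes (signal-bearing).
#' @param frac_env_loci fraction of loci with an environmental association.
#' @param beta_env selection-surrogate effect size per unit of the latent
#'   axis.
#' @param env_noise_sd observation noise when rotating latent axes into the
#'   observables.
#' @param missing_rate per-call missing probability.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(estuaries, n_loci = 500L, length_bp = 120L,
                            theta_range = c(0.2, 2.5), M_within = 900,
                            M_between = 23, alpha = 5, n_env_vars = 39L,
                            n_signal_axes = 2L, frac_env_loci = 0.05,
                            beta_env = 1, env_noise_sd = 0.3,
                            missing_rate = 0.02) {
  stopifnot(all(c("estuary", "basin", "coastal_km", "n_ind") %in% names(estuaries)),
            n_loci >= 1, frac_env_loci >= 0, frac_env_loci <= 1,
            all(estuaries$n_ind >= 1))
  structure(list(estuaries = estuaries, n_loci = as.integer(n_loci),
                 length_bp = as.integer(length_bp), theta_range = theta_range,
                 M_within = M_within, M_between = M_between, alpha = alpha,
                 n_env_vars = as.integer(n_env_vars),
                 n_signal_axes = as.integer(n_signal_axes),
                 frac_env_loci = frac_env_loci, beta_env = beta_env,
                 env_noise_sd = env_noise_sd, missing_rate = missing_rate),
            class = "scenario_config")
}

#' Study-like default configuration
#'
#' Two ocean basins with 9 + 6 estuaries at coastline-like spacings and the
#' per-estuary sample sizes of the study's sampling design (304 individuals
#' in total), 4,000 loci, migration rates tuned so neutral-locus divergence
#' sits near F_CT ~ 0.04 between basins and F_SC ~ 0.002 within them,
#' exponential growth in all demes, 39 environmental variables carrying two
#' latent signal axes, and 5% environment-associated loci.
#'
#' @param n_loci override the locus count (computation scales linearly).
#' @return a `scenario_config`.
#' @export
default_paperlike_config <- function(n_loci = 4000L) {
  est <- data.frame(
    estuary = c("SA", "MAT", "GB", "SL", "BB", "WMS", "EMS", "MB", "AP",
                "SJR", "SHS", "Stono", "CH", "SR", "WB"),
    basin = c(rep("gulf", 9), rep("atlantic", 6)),
    coastal_km = c(0, 90, 260, 350, 610, 730, 780, 830, 1120,
                   1650, 1890, 1930, 1950, 1990, 2040),
    n_ind = c(23L, 3L, 2L, 24L, 39L, 34L, 5L, 62L, 44L,
              20L, 4L, 4L, 18L, 4L, 18L),
    stringsAsFactors = FALSE)
  scenario_config(est, n_loci = n_loci)
}

# stepping-stone + single basin link migration matrix
.scenario_migration <- function(est, M_within, M_between) {
  d <- nrow(est)
  m <- matrix(0, d, d)
  for (b in unique(est$basin)) {
    idx <- which(est$basin == b)
    idx <- idx[order(est$coastal_km[idx])]
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        i <- idx[k]; j <- idx[k + 1]
        m[i, j] <- m[i, j] + M_within / 2
        m[j, i] <- m[j, i] + M_within / 2
      }
    }
  }
  basins <- unique(est$basin)
  if (length(basins) == 2) {
    i1 <- which(est$basin == basins[1])
    i2 <- which(est$basin == basins[2])
    # link the geographically closest pair across basins
    dm <- abs(outer(est$coastal_km[i1], est$coastal_km[i2], "-"))
    k <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    i <- i1[k[1]]; j <- i2[k[2]]
    m[i, j] <- m[i, j] + M_between / 2
    m[j, i] <- m[j, i] + M_between / 2
  }
  m
}

#' Generate a synthetic microhaplotype dataset with known truth
#'
#' @param config a [scenario_config()].
#' @return list: `dataset` (an `mh_dataset` with env table and linkage map)
#'   and `truth` (per-locus flags, target axis, per-estuary allele
#'   frequencies, realized neutral-locus F_CT/F_SC, latent env axes).
#' @export
generate_scenario <- function(config) {
  est <- config$estuaries
  d <- nrow(est)
  copies <- 2L * est$n_ind
  mig <- .scenario_migration(est, config$M_within, config$M_between)
  deme_of_copy <- rep.int(seq_len(d), copies)

  # latent environmental axes and rotated observables
  A <- matrix(rnorm(d * config$n_signal_axes), d, config$n_signal_axes)
  A <- scale(A)
  W <- matrix(rnorm(config$n_signal_axes * config$n_env_vars), config$n_signal_axes)
  obs <- A %*% W + matrix(rnorm(d * config$n_env_vars, 0, config$env_noise_sd),
                          d, config$n_env_vars)
  env <- data.frame(estuary = est$estuary, obs, stringsAsFactors = FALSE)
  names(env)[-1] <- sprintf("env_%02d", seq_len(config$n_env_vars))

  n_env_loci <- round(config$frac_env_loci * config$n_loci)
  is_env <- c(rep(TRUE, n_env_loci), rep(FALSE, config$n_loci - n_env_loci))
  axis_of_locus <- ifelse(is_env, sample.int(config$n_signal_axes,
                                             config$n_loci, replace = TRUE),
                          NA_integer_)
  theta <- exp(runif(config$n_loci, log(config$theta_range[1]),
                     log(config$theta_range[2])))

  loci <- vector("list", config$n_loci)
  a1 <- matrix(NA_integer_, config$n_loci, sum(est$n_ind))
  a2 <- matrix(NA_integer_, config$n_loci, sum(est$n_ind))
  freq_list <- vector("list", config$n_loci)
  ind_deme <- rep.int(seq_len(d), est$n_ind)

  for (l in seq_len(config$n_loci)) {
    haps <- NULL
    for (attempt in 1:50) {
      sim <- drop_mutations(sim_genealogy(copies, mig, config$alpha),
                            theta = theta[l])
      if (sim$S > 0 || !is_env[l]) { haps <- sim; break }
    }
    if (is.null(haps)) haps <- sim
    sm <- haps$site_matrix
    strings <- if (ncol(sm) == 0) rep("A", nrow(sm)) else
      apply(matrix(c("A", "C")[sm + 1L], nrow = nrow(sm)), 1, paste, collapse = "")

    if (is_env[l] && ncol(sm) > 0) {
      # tag site: closest to global frequency 0.5
      fr <- colMeans(sm)
      tag <- which.min(abs(fr - 0.5))
      axis_vals <- A[, axis_of_locus[l]]
      for (dd in seq_len(d)) {
        sel <- which(deme_of_copy == dd)
        w <- exp(config$beta_env * axis_vals[dd] * sm[sel, tag])
        if (all(w == 0)) w <- rep(1, length(sel))
        strings[sel] <- sample(strings[sel], length(sel), replace = TRUE,
                               prob = w)
      }
    }

    catalog <- sort(unique(strings))
    idx_allele <- match(strings, catalog)
    # pair consecutive copies within demes into diploids
    first <- seq(1, length(idx_allele), by = 2)
    a1[l, ] <- idx_allele[first]
    a2[l, ] <- idx_allele[first + 1L]
    loci[[l]] <- mh_locus(sprintf("L%05d", l), sprintf("contig_%05d", l),
                          catalog, length_bp = max(config$length_bp, nchar(catalog[1])))
    freq_list[[l]] <- vapply(seq_len(d), function(dd) {
      f <- tabulate(idx_allele[deme_of_copy == dd], nbins = length(catalog))
      f / sum(f)
    }, numeric(length(catalog)))
  }

  individuals <- sprintf("ind_%03d", seq_len(sum(est$n_ind)))
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(a1)) < config$missing_rate, nrow(a1))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  geno <- mh_genotypes(individuals, loci, a1, a2)
  metadata <- data.frame(
    individual_id = individuals,
    estuary = est$estuary[ind_deme],
    basin = est$basin[ind_deme],
    life_stage = sample(c("yoy", "juvenile", "adult"), length(individuals),
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    coastal_distance_km = est$coastal_km[ind_deme],
    stringsAsFactors = FALSE)
  map <- data.frame(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    linkage_group = sample.int(24L, config$n_loci, replace = TRUE),
    position_cM = round(runif(config$n_loci, 0, 100), 2),
    stringsAsFactors = FALSE)
  ds <- mh_dataset(geno, metadata, env = env, map = map)

  # realized divergence of the neutral (non-planted) loci
  realized <- NULL
  if (sum(!is_env) >= 2 && d >= 2 && length(unique(est$basin)) >= 2) {
    sub <- geno
    keep <- which(!is_env)
    sub <- mh_genotypes(individuals, loci[keep],
                        a1[keep, , drop = FALSE], a2[keep, , drop = FALSE])
    am <- amova(sub, assignment(ds, "estuary"),
                groups = setNames(est$basin, est$estuary), n_perm = 0)
    realized <- list(F_CT = am$f_ct, F_SC = am$f_sc, F_ST = am$f_st)
  }
  truth <- list(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    is_env_associated = is_env,
    env_axis = axis_of_locus,
    estuary_allele_freqs = freq_list,
    latent_axes = A,
    realized = realized)
  list(dataset = ds, truth = truth)
}

#' Write a scenario to disk in the package's file dialects
#'
#' Emits the haplotype table, metadata/env/map CSVs and a per-locus truth
#' TSV under `dir`.
#'
#' @param scenario output of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- scenario$dataset
  paths <- list(
    genotypes = file.path(dir, "haplotypes.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    env = file.path(dir, "environment.csv"),
    map = file.path(dir, "linkage_map.csv"),
    truth = file.path(dir, "truth.tsv"))
  write_haplotype_table(ds$genotypes, paths$genotypes)
  write.table(ds$metadata, paths$metadata, sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(ds$env, paths$env, sep = ",", quote = FALSE, row.names = FALSE)
  write.table(ds$map, paths$map, sep = ",", quote = FALSE, row.names = FALSE)
  tr <- data.frame(locus_id = scenario$truth$locus_id,
                   is_env_associated = scenario$truth$is_env_associated,
                   env_axis = scenario$truth$env_axis)
  write.table(tr, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
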