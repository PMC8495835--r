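# Readers and writers for the package's external formats.
#
# Haplotype table dialect (tab-separated):
#   header:  locus_id  contig  alleles  <ind1>  <ind2> ...
#   row:     L0001  dDocent_Contig_12  ACGT,ACGA,GCGT  1/2  ./.  2/2 ...
# Allele catalogues are comma-separated haplotype strings; calls are 1-based
# "i/j" index pairs into the catalogue, "./." for missing.

#' Write a genotype matrix as a haplotype table
#'
#' @param geno an `mh_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(geno, path) {
  L <- length(geno$loci)
  calls <- matrix("./.", L, length(geno$individuals))
  ok <- !is.na(geno$a1)
  calls[ok] <- paste0(geno$a1[ok], "/", geno$a2[ok])
  df <- data.frame(
    locus_id = vapply(geno$loci, `[[`, "", "locus_id"),
    contig = vapply(geno$loci, `[[`, "", "contig"),
    alleles = vapply(geno$loci, function(l) paste(l$alleles, collapse = ","), ""),
    calls, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- geno$individuals
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype table
#'
#' @param path path to a tab-separated haplotype table.
#' @return an `mh_genotypes` object.
#' @export
read_haplotype_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 4) stop("haplotype table needs locus_id, contig, alleles and at least one individual")
  if (!all(names(df)[1:3] == c("locus_id", "contig", "alleles"))) {
    stop("haplotype table header must start with locus_id, contig, alleles")
  }
  if (anyDuplicated(df$locus_id)) stop("duplicated locus_id in haplotype table")
  individuals <- names(df)[-(1:3)]
  loci <- lapply(seq_len(nrow(df)), function(i) {
    mh_locus(df$locus_id[i], df$contig[i], strsplit(df$alleles[i], ",", fixed = TRUE)[[1]])
  })
  L <- nrow(df); N <- length(individuals)
  cm <- as.matrix(df[, -(1:3), drop = FALSE])
  a1 <- a2 <- matrix(NA_integer_, L, N)
  ok <- cm != "./."
  if (any(ok)) {
    parts <- strsplit(cm[ok], "/", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("malformed genotype call; expected 'i/j' or './.'")
    a1[ok] <- as.integer(vapply(parts, `[[`, "", 1L))
    a2[ok] <- as.integer(vapply(parts, `[[`, "", 2L))
    if (anyNA(a1[ok]) || anyNA(a2[ok])) stop("non-integer allele index in genotype call")
  }
  mh_genotypes(individuals, loci, a1, a2)
}

#' Load a full dataset from files
#'
#' Reads the haplotype table plus metadata and optional environment and
#' linkage-map CSVs, cross-references individual and locus ids (mismatches
#' are errors, not silent drops) and returns an [mh_dataset()].
#'
#' @param genotype_path haplotype table path.
#' @param metadata_path metadata CSV (`individual_id`, `estuary`, `basin`,
#'   `life_stage`, `coastal_distance_km`).
#' @param env_path optional environment CSV (`estuary` + variables).
#' @param map_path optional linkage-map CSV (`locus_id`, `linkage_group`,
#'   `position_cM`).
#' @return an `mh_dataset`.
#' @export
load_dataset <- function(genotype_path, metadata_path, env_path = NULL,
                         map_path = NULL) {
  geno <- read_haplotype_table(genotype_path)
  metadata <- read.table(metadata_path, sep = ",", header = TRUE,
                         stringsAsFactors = FALSE)
  env <- if (!is.null(env_path)) {
    read.table(env_path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  }
  map <- if (!is.null(map_path)) {
    read.table(map_path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  }
  if (!is.null(map)) {
    unknown <- setdiff(map$locus_id, vapply(geno$loci, `[[`, "", "locus_id"))
    if (length(unknown)) {
      stop("linkage map references unknown loci: ", paste(head(unknown, 5), collapse = ", "))
    }
  }
  mh_dataset(geno, metadata, env = env, map = map)
}

#' Export genotypes in genepop format
#'
#' One section per population; alleles coded as 3-digit ranks in catalogue
#' order, missing as `000000`.
#'
#' @param geno an `mh_genotypes` object.
#' @param populations named character vector (individual -> population).
#' @param path output path.
#' @param title first-line title.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, populations, path, title = "microhapgen export") {
  if (any(vapply(geno$loci, function(l) length(l$alleles), 0L) > 999)) {
    stop("genepop 3-digit codes support at most 999 alleles per locus")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(vapply(geno$loci, `[[`, "", "locus_id"), con)
  pops <- populations[geno$individuals]
  for (p in unique(pops)) {
    writeLines("Pop", con)
    for (ind in geno$individuals[pops == p]) {
      a1 <- geno$a1[, ind]; a2 <- geno$a2[, ind]
      code <- ifelse(is.na(a1), "000000", sprintf("%03d%03d", a1, a2))
      writeLines(paste0(ind, " , ", paste(code, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Filter a dataset by group size and locus missingness
#'
#' Removes estuaries with fewer than `min_group_n` individuals (the study's
#' population-structure analyses used a floor of 18), then loci whose missing
#' call fraction among the retained individuals exceeds `max_locus_missing`.
#' The input is untouched; the operation is idempotent.
#'
#' @param ds an `mh_dataset`.
#' @param min_group_n minimum individuals per estuary (>= 1).
#' @param max_locus_missing maximum tolerated missing-call fraction per locus.
#' @return a filtered `mh_dataset`.
#' @export
filter_dataset <- function(ds, min_group_n = 18L, max_locus_missing = 1) {
  if (min_group_n < 1) stop("min_group_n must be >= 1")
  tab <- table(ds$metadata$estuary)
  keep_est <- names(tab)[tab >= min_group_n]
  if (!length(keep_est)) stop("filtering removed every estuary (min_group_n = ", min_group_n, ")")
  keep_ind <- ds$metadata$individual_id[ds$metadata$estuary %in% keep_est]
  g <- ds$genotypes
  idx <- match(keep_ind, g$individuals)
  a1 <- g$a1[, idx, drop = FALSE]; a2 <- g$a2[, idx, drop = FALSE]
  miss_frac <- rowMeans(is.na(a1))
  keep_loc <- miss_frac <= max_locus_missing
  if (!any(keep_loc)) stop("filtering removed every locus (max_locus_missing = ", max_locus_missing, ")")
  geno <- mh_genotypes(keep_ind, g$loci[keep_loc],
                       a1[keep_loc, , drop = FALSE], a2[keep_loc, , drop = FALSE])
  md <- ds$metadata[ds$metadata$individual_id %in% keep_ind, , drop = FALSE]
  env <- ds$env
  if (!is.null(env)) env <- env[env$estuary %in% unique(md$estuary), , drop = FALSE]
  map <- ds$map
  if (!is.null(map)) {
    ids <- vapply(geno$loci, `[[`, "", "locus_id")
    map <- map[map$locus_id %in% ids, , drop = FALSE]
  }
  mh_dataset(geno, md, env = env, map = map)
}
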