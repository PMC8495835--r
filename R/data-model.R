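# Domain data model: microhaplotype loci, diploid genotype matrices, sample
# metadata, environmental tables and linkage maps, bundled into a dataset.
#
# A genotype matrix stores, for each locus x individual, an unordered pair of
# allele indices into the locus catalogue (both NA when missing). Per-locus
# gene-copy counts are always recomputed from the calls, never cached, so
# filtering cannot desynchronise bookkeeping.

#' Construct a microhaplotype locus
#'
#' @param locus_id locus identifier.
#' @param contig source contig name.
#' @param alleles character vector of haplotype strings over A/C/G/T, all the
#'   same length, unique, at least one.
#' @param length_bp fragment length in bp (defaults to the allele length).
#' @param linkage_group optional integer linkage group.
#' @param position_cM optional map position (cM).
#' @return an object of class `mh_locus`.
#' @export
mh_locus <- function(locus_id, contig, alleles, length_bp = NULL,
                     linkage_group = NA_integer_, position_cM = NA_real_) {
  if (length(alleles) < 1) stop("locus ", locus_id, ": needs at least one allele")
  if (anyDuplicated(alleles)) stop("locus ", locus_id, ": duplicated alleles")
  if (any(grepl("[^ACGT]", alleles))) {
    stop("locus ", locus_id, ": malformed allele string (non-ACGT)")
  }
  alen <- unique(nchar(alleles))
  if (length(alen) != 1) stop("locus ", locus_id, ": alleles differ in length")
  if (is.null(length_bp)) length_bp <- alen
  if (length_bp < alen) stop("locus ", locus_id, ": length_bp shorter than alleles")
  structure(list(locus_id = as.character(locus_id), contig = as.character(contig),
                 length_bp = as.integer(length_bp), alleles = alleles,
                 linkage_group = as.integer(linkage_group),
                 position_cM = as.numeric(position_cM)),
            class = "mh_locus")
}

#' Construct a genotype matrix
#'
#' @param individuals character vector of individual ids.
#' @param loci list of [mh_locus()] objects.
#' @param a1,a2 integer matrices (loci x individuals) of allele indices, both
#'   `NA` where the call is missing. Pairs are unordered; they are stored with
#'   `a1 <= a2`.
#' @return an object of class `mh_genotypes`.
#' @export
mh_genotypes <- function(individuals, loci, a1, a2) {
  L <- length(loci); N <- length(individuals)
  ids <- vapply(loci, `[[`, "", "locus_id")
  if (anyDuplicated(ids)) stop("duplicated locus_id")
  if (anyDuplicated(individuals)) stop("duplicated individual id")
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == c(L, N)),
            all(dim(a2) == c(L, N)))
  if (!identical(is.na(a1), is.na(a2))) {
    stop("half-missing calls are not allowed: both allele indices or neither")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  n_alleles <- vapply(loci, function(l) length(l$alleles), 0L)
  bad <- !is.na(a1) & (a1 < 1L | a2 > n_alleles[row(a1)])
  if (any(bad)) stop("allele index out of range for its locus catalogue")
  dimnames(a1) <- dimnames(a2) <- list(ids, individuals)
  structure(list(individuals = as.character(individuals), loci = loci,
                 a1 = a1, a2 = a2),
            class = "mh_genotypes")
}

#' Per-locus gene-copy counts
#'
#' Number of gene copies with non-missing calls at each locus, `2 x` the
#' count of called individuals. Optionally restricted to a subset of
#' individuals.
#'
#' @param geno an `mh_genotypes` object.
#' @param individuals optional character vector of individual ids.
#' @return named integer vector, one entry per locus.
#' @export
gene_copies <- function(geno, individuals = NULL) {
  a1 <- geno$a1
  if (!is.null(individuals)) a1 <- a1[, individuals, drop = FALSE]
  2L * rowSums(!is.na(a1))
}

#' Bundle genotypes, metadata and optional tables into a dataset
#'
#' @param genotypes an `mh_genotypes` object.
#' @param metadata data.frame with columns `individual_id`, `estuary`,
#'   `basin`, `life_stage`, `coastal_distance_km`.
#' @param env optional data.frame: `estuary` plus numeric variable columns.
#' @param map optional data.frame: `locus_id`, `linkage_group`, `position_cM`.
#' @return an object of class `mh_dataset`.
#' @export
mh_dataset <- function(genotypes, metadata, env = NULL, map = NULL) {
  req <- c("individual_id", "estuary", "basin", "life_stage", "coastal_distance_km")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  metadata$individual_id <- as.character(metadata$individual_id)
  if (anyDuplicated(metadata$individual_id)) stop("duplicated individual in metadata")
  if (!setequal(metadata$individual_id, genotypes$individuals)) {
    only_g <- setdiff(genotypes$individuals, metadata$individual_id)
    only_m <- setdiff(metadata$individual_id, genotypes$individuals)
    stop("genotype/metadata individual mismatch; only in genotypes: [",
         paste(head(only_g, 5), collapse = ", "), "], only in metadata: [",
         paste(head(only_m, 5), collapse = ", "), "]")
  }
  e2b <- unique(metadata[, c("estuary", "basin")])
  if (anyDuplicated(e2b$estuary)) stop("estuary maps to more than one basin")
  metadata <- metadata[match(genotypes$individuals, metadata$individual_id), ]
  rownames(metadata) <- NULL
  if (!is.null(env)) {
    if (!"estuary" %in% names(env)) stop("env table needs an 'estuary' column")
    vals <- env[, setdiff(names(env), "estuary"), drop = FALSE]
    if (anyNA(vals)) stop("env table must not contain missing values")
  }
  if (!is.null(map)) {
    req_m <- c("locus_id", "linkage_group", "position_cM")
    if (!all(req_m %in% names(map))) {
      stop("linkage map must have columns: ", paste(req_m, collapse = ", "))
    }
    if (anyDuplicated(map$locus_id)) stop("duplicated locus_id in linkage map")
  }
  structure(list(genotypes = genotypes, metadata = metadata, env = env, map = map),
            class = "mh_dataset")
}

#' @export
print.mh_dataset <- function(x, ...) {
  cat("<mh_dataset>", length(x$genotypes$loci), "loci x",
      length(x$genotypes$individuals), "individuals;",
      length(unique(x$metadata$estuary)), "estuaries in",
      length(unique(x$metadata$basin)), "basin(s)\n")
  invisible(x)
}

#' Population assignment helper
#'
#' @param ds an `mh_dataset`.
#' @param level `"estuary"` or `"basin"`.
#' @return named character vector (individual -> group), genotype order.
#' @export
assignment <- function(ds, level = c("estuary", "basin")) {
  level <- match.arg(level)
  setNames(as.character(ds$metadata[[level]]), ds$metadata$individual_id)
}
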