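# Collapse a phased multi-sample VCF into microhaplotype loci: one contig =
# one locus, each phased haplotype across the contig's SNPs = one allele
# string (sites concatenated in coordinate order). This re-creates haplotype
# collapsing from an already-phased VCF only; read-backed phasing belongs
# upstream.

#' Collapse a phased VCF into microhaplotype genotypes
#'
#' Individuals with any unphased or missing genotype at a contig are treated
#' as missing at that locus (counted and reported via a warning, not an
#' error). Contigs without variant sites do not appear in a VCF and are
#' therefore skipped by construction.
#'
#' @param vcf_path path to a VCF 4.x file with phased diploid `GT` fields.
#' @return an `mh_genotypes` object.
#' @export
collapse_phased_vcf <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(gt)))
  individuals <- colnames(gt)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  site_alleles <- lapply(seq_len(nrow(fix)), function(i) {
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
  })

  n_unphased <- 0L
  loci <- list(); a1_rows <- list(); a2_rows <- list()
  for (ctg in unique(chrom)) {
    rows <- which(chrom == ctg)
    rows <- rows[order(pos[rows])]
    S <- length(rows)
    hap1 <- hap2 <- matrix(NA_character_, S, length(individuals))
    for (si in seq_along(rows)) {
      g <- gt[rows[si], ]
      phased <- grepl("^[0-9]+\\|[0-9]+$", g) & !is.na(g)
      n_unphased <- n_unphased + sum(!phased)
      al <- site_alleles[[rows[si]]]
      parts <- strsplit(ifelse(phased, g, "x|x"), "|", fixed = TRUE)
      i1 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L))) + 1L
      i2 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))) + 1L
      hap1[si, phased] <- al[i1[phased]]
      hap2[si, phased] <- al[i2[phased]]
    }
    s1 <- apply(hap1, 2, function(x) if (anyNA(x)) NA_character_ else paste(x, collapse = ""))
    s2 <- apply(hap2, 2, function(x) if (anyNA(x)) NA_character_ else paste(x, collapse = ""))
    catalog <- sort(unique(c(s1[!is.na(s1)], s2[!is.na(s2)])))
    if (!length(catalog)) next  # no individual fully phased at this contig
    loci[[length(loci) + 1L]] <- mh_locus(ctg, ctg, catalog)
    a1_rows[[length(a1_rows) + 1L]] <- match(s1, catalog)
    a2_rows[[length(a2_rows) + 1L]] <- match(s2, catalog)
  }
  if (n_unphased > 0) {
    warning(n_unphased, " unphased or missing site genotypes set to locus-missing")
  }
  if (!length(loci)) stop("no collapsible contigs found in ", vcf_path)
  mh_genotypes(individuals, loci,
               do.call(rbind, a1_rows), do.call(rbind, a2_rows))
}
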