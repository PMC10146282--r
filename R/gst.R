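#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' `He = 1 - sum(p_i^2)` over the allele frequencies of a locus.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @return Expected heterozygosity in \[0, 1 - 1/k\] for k alleles.
#' @export
expected_het <- function(p, tol = 1e-6) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("allele frequencies must be non-negative and sum to 1")
  1 - sum(p^2)
}

#' Inter-population differentiation (GST) for a diallelic site
#'
#' One-versus-rest differentiation between a focal taxon and the equal-weight
#' pool of the remaining taxa:
#' `GST = (HeTot - (He_focal + He_rest)/2) / HeTot`, with the
#' total-population frequency taken as the unweighted mean of the two
#' subpopulation frequencies (every taxon weighted equally). `GST = 1` marks
#' full differentiation (the focal taxon fixed for one allele, the rest pool
#' fixed for the other); a monomorphic total population has no defined GST
#' and returns `NA`.
#'
#' @param p_focal alternate-allele frequency in the focal taxon (vectorized).
#' @param p_rest alternate-allele frequency in the equal-weight pool of the
#'   other taxa.
#' @return GST in \[0, 1\], or `NA` where the total population is monomorphic.
#' @export
gst <- function(p_focal, p_rest) {
  if (any(p_focal < 0 | p_focal > 1 | p_rest < 0 | p_rest > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  ptot <- (p_focal + p_rest) / 2
  he_tot <- 2 * ptot * (1 - ptot)
  he_sub <- (2 * p_focal * (1 - p_focal) + 2 * p_rest * (1 - p_rest)) / 2
  out <- (he_tot - he_sub) / he_tot
  out[he_tot == 0] <- NA_real_
  out
}

#' Mine taxon-diagnostic SNPs from reference-accession genotypes
#'
#' Sites with more than `max_missing` missing genotypes are excluded, taxon
#' alternate-allele frequencies are estimated by allele counting
#' (heterozygous diploid accessions contribute 0.5), and each taxon is
#' contrasted against the equal-weight pool of the others with [gst()].
#' Sites with `GST = 1` (within `tol`) are diagnostic: the focal taxon is
#' fixed for an allele that is absent from every other taxon.
#'
#' @param geno numeric matrix of alternate-allele dosages (0, 1, 2; NA for
#'   missing), rows = sites, columns = accessions.
#' @param taxa character vector of taxon assignments, one per accession
#'   (named or in column order).
#' @param sites data.frame with columns `chrom`, `pos` (one row per site);
#'   optional columns `ref`, `alt` are carried through.
#' @param max_missing maximum tolerated fraction of missing genotypes per
#'   site (default 0.20).
#' @param tol numeric tolerance used for the `GST = 1` test.
#' @return A DSNP panel: data.frame with columns `chrom`, `pos`, `taxon`,
#'   `diag_allele` ("ref" or "alt") and `gst`.
#' @seealso [dsnp_summary()] for per-taxon, per-chromosome counts.
#' @export
mine_dsnps <- function(geno, taxa, sites, max_missing = 0.20, tol = 1e-9) {
  stopifnot(is.matrix(geno), nrow(geno) == nrow(sites),
            length(taxa) == ncol(geno))
  if (!is.null(names(taxa)) && !is.null(colnames(geno)))
    taxa <- taxa[colnames(geno)]
  taxa <- as.character(taxa)
  tax_levels <- unique(taxa)
  if (any(table(taxa) < 1) || length(tax_levels) < 2)
    stop("need at least one accession in each of two or more taxa")

  keep <- rowMeans(is.na(geno)) <= max_missing
  # per-taxon alternate-allele frequency (allele counting; het = 0.5)
  freq <- sapply(tax_levels, function(tx) {
    g <- geno[, taxa == tx, drop = FALSE]
    rowMeans(g, na.rm = TRUE) / 2
  })
  keep <- keep & !apply(freq, 1, anyNA)  # a taxon with all-missing site -> excluded

  recs <- list()
  for (tx in tax_levels) {
    p_focal <- freq[, tx]
    p_rest <- rowMeans(freq[, setdiff(tax_levels, tx), drop = FALSE])
    g <- gst(p_focal, p_rest)
    hit <- keep & !is.na(g) & abs(g - 1) <= tol
    if (any(hit)) {
      recs[[tx]] <- data.frame(
        chrom = sites$chrom[hit], pos = sites$pos[hit], taxon = tx,
        diag_allele = ifelse(p_focal[hit] > 0.5, "alt", "ref"),
        gst = g[hit], stringsAsFactors = FALSE)
    }
  }
  panel <- if (length(recs)) do.call(rbind, recs)
           else data.frame(chrom = character(), pos = numeric(),
                           taxon = character(), diag_allele = character(),
                           gst = numeric(), stringsAsFactors = FALSE)
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "n_sites_tested") <- sum(keep)
  panel
}

#' Per-taxon, per-chromosome DSNP counts
#'
#' @param panel DSNP panel from [mine_dsnps()].
#' @return data.frame, chromosomes x taxa, with row and column totals and a
#'   percentage row.
#' @export
dsnp_summary <- function(panel) {
  tab <- table(panel$chrom, panel$taxon)
  out <- as.data.frame.matrix(tab)
  out$Total <- rowSums(out)
  tot <- colSums(out)
  pct <- 100 * tot / tot[["Total"]]
  rbind(out, Total = tot, `%` = round(pct, 2))
}
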