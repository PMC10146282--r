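#' Simulate reference-accession genotypes with planted diagnostic SNPs
#'
#' Emulates the panel of taxon reference accessions used to mine diagnostic
#' SNPs. Real diagnostic SNPs are dense (tens of thousands genome-wide), so
#' a 20-SNP window is physically narrow (~100 kb); the generator keeps that
#' property at desk scale by planting, for each ancestor and chromosome,
#' `windows_per_chrom` clusters of `snps_per_window` sites within a
#' `window_span` bp footprint, evenly spaced along the chromosome (cluster
#' centers of different ancestors are offset so the panels interleave).
#' At each planted site the focal taxon is fixed for the alternate allele
#' and all other taxa for the reference allele; `background` additional
#' sites are polymorphic without any fixed taxon difference. Genotypes are
#' diploid alternate-allele dosages with optional random missingness.
#'
#' @param genome a [genome_spec()].
#' @param accessions named integer vector: accessions per taxon. Default
#'   mirrors the study design (3 trifoliata, 1 maxima, 2 medica,
#'   2 reticulata).
#' @param windows_per_chrom planted 20-SNP clusters per taxon and
#'   chromosome.
#' @param snps_per_window sites per cluster (the window size downstream).
#' @param window_span physical footprint of one cluster in bp.
#' @param background number of non-diagnostic polymorphic sites genome-wide.
#' @param missing_rate per-genotype missing probability.
#' @param seed optional integer seed.
#' @return list with `geno` (site x accession dosage matrix), `taxa`
#'   (accession taxon assignments), `sites` (chrom, pos) and `truth`
#'   (the planted panel: chrom, pos, taxon).
#' @export
simulate_reference_panel <- function(genome,
                                     accessions = c(trifoliata = 3, maxima = 1,
                                                    medica = 2, reticulata = 2),
                                     windows_per_chrom = 10,
                                     snps_per_window = 20,
                                     window_span = 1e5,
                                     background = 1000,
                                     missing_rate = 0.02,
                                     seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.null(seed)) set.seed(seed)
  taxa <- rep(names(accessions), accessions)
  names(taxa) <- paste0(taxa, "_", unlist(lapply(accessions, seq_len)))
  nacc <- length(taxa)
  tax_levels <- names(accessions)

  planted <- list()
  for (ch in genome$chrom) {
    L <- genome$length[[ch]]
    for (ti in seq_along(tax_levels)) {
      centers <- L * (seq_len(windows_per_chrom) - 0.5) / windows_per_chrom +
        (ti - (length(tax_levels) + 1) / 2) * window_span * 1.5
      centers <- pmin(pmax(centers, window_span), L - window_span)
      pos <- rep(centers, each = snps_per_window) +
        stats::runif(windows_per_chrom * snps_per_window,
                     -window_span / 2, window_span / 2)
      planted[[paste(ch, ti)]] <- data.frame(
        chrom = ch, pos = round(pos), taxon = tax_levels[ti],
        stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, c(planted, make.row.names = FALSE))
  g_pl <- matrix(0L, nrow(planted), nacc, dimnames = list(NULL, names(taxa)))
  for (tx in tax_levels) g_pl[planted$taxon == tx, taxa == tx] <- 2L

  if (background > 0) {
    ch_bg <- sample(genome$chrom, background, replace = TRUE)
    pos_bg <- round(stats::runif(background, 1, genome$length[ch_bg] - 1))
    g_bg <- matrix(sample(0:2, background * nacc, replace = TRUE,
                          prob = c(0.25, 0.5, 0.25)),
                   background, nacc, dimnames = list(NULL, names(taxa)))
    bg <- data.frame(chrom = ch_bg, pos = pos_bg, taxon = NA_character_,
                     stringsAsFactors = FALSE)
  } else {
    g_bg <- matrix(integer(0), 0, nacc); bg <- planted[0, ]
  }

  all_sites <- rbind(planted, bg)
  geno <- rbind(g_pl, g_bg)
  ord <- order(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[ord, ]; geno <- geno[ord, , drop = FALSE]
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA
  rownames(all_sites) <- NULL

  list(geno = geno, taxa = taxa,
       sites = all_sites[, c("chrom", "pos")],
       truth = all_sites[!is.na(all_sites$taxon),
                         c("chrom", "pos", "taxon")])
}
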