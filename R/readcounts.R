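#' Simulate diagnostic-allele read counts over a DSNP panel
#'
#' Emulates reduced-representation sequencing coverage of the diagnostic
#' SNP panel in a tetraploid cohort. Per site and individual, the total read
#' count is Poisson with the configured mean depth (set to zero with the
#' site missing rate), and diagnostic-allele reads are Binomial with success
#' probability `clamp(d/4, error, 1 - error)` where `d` is the individual's
#' true ancestral dose at the site.
#'
#' @param hybrids a `hybrid_set` from [form_hybrids()].
#' @param panel DSNP panel data.frame with columns `chrom`, `pos`, `taxon`
#'   (see [mine_dsnps()]); counts are generated for every site, tracking the
#'   site's own taxon.
#' @param depth mean read depth per site.
#' @param error per-read error rate in \[0, 0.5).
#' @param missing per-site missing rate in \[0, 1\] (total reads forced to 0).
#' @param seed optional integer seed.
#' @return data.frame with columns `indiv`, `chrom`, `pos`, `taxon`,
#'   `diag_reads`, `tot_reads`.
#' @export
simulate_read_counts <- function(hybrids, panel, depth = 20, error = 0.01,
                                 missing = 0.02, seed = NULL) {
  stopifnot(inherits(hybrids, "hybrid_set"))
  if (depth < 0) stop("depth must be >= 0")
  if (error < 0 || error >= 0.5) stop("error must lie in [0, 0.5)")
  if (missing < 0 || missing > 1) stop("missing rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  genome_chroms <- names(hybrids[[1]]$ovule$chrom)
  if (!all(panel$chrom %in% genome_chroms))
    stop("panel sites must lie on hybrid chromosomes")

  ids <- vapply(hybrids, `[[`, "", "id")
  n <- length(hybrids)
  ns <- nrow(panel)

  # true dose per site x individual, vectorized per chromatid track
  d <- matrix(0L, ns, n)
  for (ch in unique(panel$chrom)) {
    sel <- which(panel$chrom == ch)
    pos <- panel$pos[sel]
    tax <- panel$taxon[sel]
    for (h in seq_len(n)) {
      trk <- c(hybrids[[h]]$ovule$chrom[[ch]]$chromatids,
               hybrids[[h]]$pollen$chrom[[ch]]$chromatids)
      dd <- integer(length(sel))
      for (t in trk) dd <- dd + (.seg_anc_at(t, pos) == tax)
      d[sel, h] <- dd
    }
  }

  tot <- stats::rpois(ns * n, depth)
  if (missing > 0) tot[stats::runif(ns * n) < missing] <- 0L
  f <- pmin(pmax(as.vector(d) / 4, error), 1 - error)
  diag <- stats::rbinom(ns * n, tot, f)

  data.frame(indiv = rep(ids, each = ns),
             chrom = rep(panel$chrom, n),
             pos = rep(panel$pos, n),
             taxon = rep(panel$taxon, n),
             diag_reads = diag,
             tot_reads = tot,
             stringsAsFactors = FALSE)
}

#' Write diagnostic-allele counts as a minimal VCF with AD fields
#'
#' One record per panel site; per-sample entries are `GT:AD` with an
#' uninformative `./.` genotype and `AD = diag,other` allele depths
#' (diagnostic allele first).
#'
#' @param counts count table from [simulate_read_counts()].
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path) {
  ids <- unique(counts$indiv)
  key <- paste(counts$chrom, counts$pos, counts$taxon, sep = ":")
  sites <- !duplicated(key)
  site_tab <- counts[sites, c("chrom", "pos", "taxon")]
  ord <- order(site_tab$chrom, site_tab$pos)
  site_tab <- site_tab[ord, ]
  skey <- paste(site_tab$chrom, site_tab$pos, site_tab$taxon, sep = ":")

  ad <- matrix("./.:0,0", nrow(site_tab), length(ids),
               dimnames = list(skey, ids))
  idx <- cbind(match(key, skey), match(counts$indiv, ids))
  ad[idx] <- sprintf("./.:%d,%d", counts$diag_reads,
                     counts$tot_reads - counts$diag_reads)

  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (diagnostic allele first)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(site_tab$chrom,
                format(site_tab$pos, scientific = FALSE, trim = TRUE),
                paste0(site_tab$taxon, "_", site_tab$chrom, "_",
                       format(site_tab$pos, scientific = FALSE, trim = TRUE)),
                "A", "T", ".", ".", paste0("TAXON=", site_tab$taxon), "GT:AD",
                apply(ad, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read diagnostic-allele counts back from a VCF with AD fields
#'
#' Expects the layout written by [write_counts_vcf()]: the first AD entry is
#' the diagnostic-allele depth and the INFO field carries `TAXON=`.
#'
#' @param path VCF file path.
#' @return data.frame in the layout of [simulate_read_counts()].
#' @export
read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"])
  taxon <- sub("^.*TAXON=([^;]+).*$", "\\1", v@fix[, "INFO"])
  a1 <- apply(ad, 2, function(x) as.integer(sub(",.*$", "", x)))
  a2 <- apply(ad, 2, function(x) as.integer(sub("^.*,", "", x)))
  data.frame(indiv = rep(colnames(ad), each = nrow(ad)),
             chrom = rep(chrom, ncol(ad)),
             pos = rep(pos, ncol(ad)),
             taxon = rep(taxon, ncol(ad)),
             diag_reads = as.vector(a1),
             tot_reads = as.vector(a1 + a2),
             stringsAsFactors = FALSE)
}
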