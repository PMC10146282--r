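#' Default configuration of the synthetic study
#'
#' The defaults encode the study conditions: a nine-chromosome genome, two
#' doubled-diploid parents (genome-wide reticulata/medica heterozygosity in
#' the ovule parent; trifoliata against a reticulata/maxima mosaic in the
#' pollen parent), per-chromosome tetrasomic parameters taken as
#' `1 - PP` from the published per-chromosome preferential pairing of the
#' two rootstocks, 96 hybrids, windows of 20 diagnostic SNPs, mean depth 20
#' with a 1% per-read error rate, the 15%/20% missing-data filters, the
#' 0.005 tau grid, the q < 0.05 deviation threshold, loess span 0.15 and
#' the p < 0.01 association threshold.
#'
#' @param n_chrom number of chromosomes (<= 9); trims all per-chromosome
#'   defaults consistently for smaller test genomes.
#' @return nested configuration list.
#' @export
default_config <- function(n_chrom = 9) {
  pp_vol <- c(0.583, 0.810, 0.317, 0.548, 0.000, 0.675, 0.663, 0.672, 0.250)
  pp_cit <- c(0.742, 0.625, 0.690, 0.850, 0.848, 0.925, 0.502, 0.923, 0.760)
  list(
    genome = list(n_chrom = n_chrom, centromere_frac = 0.45, cm_per_mb = 3),
    parents = list(citrumelo_break_fracs = c(0.4, 0.8)),
    meiosis = list(tau_volkamer = (1 - pp_vol)[seq_len(n_chrom)],
                   tau_citrumelo = (1 - pp_cit)[seq_len(n_chrom)]),
    cohort = list(n_hybrids = 96),
    panel = list(windows_per_chrom = 10, snps_per_window = 20,
                 window_span = 1e5, background = 1000,
                 accessions = c(trifoliata = 3, maxima = 1,
                                medica = 2, reticulata = 2),
                 missing_rate = 0.02, max_missing = 0.20),
    reads = list(depth = 20, error = 0.01, missing = 0.02,
                 min_reads = 10, lr_min = 1),
    windows = list(size = 20),
    cleaning = list(max_window_missing = 0.15, max_indiv_missing = 0.20,
                    aberrant_k = 3),
    fit = list(grid_step = 0.005, q_method = "BH", q_threshold = 0.05,
               min_n = 20),
    map = list(rf_threshold = 0.3, min_overlap = 20, span = 0.15,
               marey_min_markers = 10),
    assoc = list(p_threshold = 0.01, coding = "additive"),
    qtl = list(sd = 1,
               volkamer = data.frame(trait = c("root_surface", "root_diameter"),
                                     chrom = c("chr1", "chr1"),
                                     frac = c(0.9, 0.9),
                                     beta = c(-1, 0),
                                     stringsAsFactors = FALSE),
               citrumelo = data.frame(trait = c("root_surface", "root_diameter"),
                                      chrom = c("chr1", if (n_chrom >= 9) "chr9" else "chr1"),
                                      frac = c(0.9, 0.1),
                                      beta = c(1, 1),
                                      stringsAsFactors = FALSE)),
    seed = 20230412
  )
}

#' Simulate a complete tetrazyg study cohort with ground truth
#'
#' Generates the genome, the two doubled-diploid parents, ovules and
#' pollens under per-chromosome preferential pairing, tetraploid hybrids,
#' reference-accession genotypes for DSNP mining, diagnostic-allele read
#' counts over the mined panel, and additive QTL phenotypes — returning the
#' full simulator truth alongside.
#'
#' @param config configuration list from [default_config()] (possibly
#'   modified).
#' @param seed integer seed governing the whole cohort.
#' @return list with `genome`, `centromeres`, `parents`, `ovules`,
#'   `pollens`, `hybrids`, `reference` (mining inputs), `panel` (mined
#'   DSNPs), `partition`, `counts`, `phenotypes`, `qtl`, and `truth`
#'   (gamete dose matrices and pairing configurations).
#' @export
simulate_cohort <- function(config = default_config(), seed = config$seed) {
  set.seed(seed)
  genome <- default_genome(n_chrom = config$genome$n_chrom,
                           centromere_frac = config$genome$centromere_frac,
                           cm_per_mb = config$genome$cm_per_mb)
  cents <- centromere_table(genome)
  parents <- build_parent_karyotypes(
    genome, citrumelo_break_fracs = config$parents$citrumelo_break_fracs)

  n <- config$cohort$n_hybrids
  ovules <- simulate_meiosis(parents$volkamer, n,
                             tau = config$meiosis$tau_volkamer)
  pollens <- simulate_meiosis(parents$citrumelo, n,
                              tau = config$meiosis$tau_citrumelo)
  hybrids <- form_hybrids(ovules, pollens)

  ref <- simulate_reference_panel(
    genome,
    accessions = config$panel$accessions,
    windows_per_chrom = config$panel$windows_per_chrom,
    snps_per_window = config$panel$snps_per_window,
    window_span = config$panel$window_span,
    background = config$panel$background,
    missing_rate = config$panel$missing_rate)
  panel <- mine_dsnps(ref$geno, ref$taxa, ref$sites,
                      max_missing = config$panel$max_missing)
  tracked <- panel[panel$taxon %in% c("medica", "trifoliata"), , drop = FALSE]
  partition <- window_partition(tracked, size = config$windows$size)

  counts <- simulate_read_counts(hybrids, tracked,
                                 depth = config$reads$depth,
                                 error = config$reads$error,
                                 missing = config$reads$missing)

  wins <- partition$windows
  truth <- list(
    ovule_doses = gamete_doses(ovules, "medica",
                               wins[wins$ancestor == "medica", ]),
    pollen_doses = gamete_doses(pollens, "trifoliata",
                                wins[wins$ancestor == "trifoliata", ]),
    ovule_configs = pairing_configs(ovules),
    pollen_configs = pairing_configs(pollens))
  # gametes are labelled by the hybrid they produced, so truth rows line up
  # with called dose matrices and phenotype ids
  hyb_ids <- vapply(hybrids, `[[`, "", "id")
  rownames(truth$ovule_doses$dose) <- hyb_ids
  rownames(truth$pollen_doses$dose) <- hyb_ids

  # phenotypes: additive effects of ovule medica dose and pollen trifoliata
  # dose at the configured QTL windows, one shared trait table per hybrid
  qtl_rows <- list()
  phen <- data.frame(id = vapply(hybrids, `[[`, "", "id"),
                     stringsAsFactors = FALSE)
  traits <- unique(c(config$qtl$volkamer$trait, config$qtl$citrumelo$trait))
  for (tr in traits) phen[[tr]] <- stats::rnorm(n, 0, config$qtl$sd)
  for (side in c("volkamer", "citrumelo")) {
    spec <- config$qtl[[side]]
    dosem <- if (side == "volkamer") truth$ovule_doses else truth$pollen_doses
    for (i in seq_len(nrow(spec))) {
      if (spec$beta[i] == 0) next
      w <- dosem$windows
      wch <- w[w$chrom == spec$chrom[i], , drop = FALSE]
      target <- wch$window[which.min(abs(wch$pos / max(wch$end) - spec$frac[i]))]
      d <- dosem$dose[, target]
      phen[[spec$trait[i]]] <- phen[[spec$trait[i]]] + spec$beta[i] * d
      qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
        parent = side, trait = spec$trait[i], window = target,
        beta = spec$beta[i], stringsAsFactors = FALSE)
    }
  }

  list(genome = genome, centromeres = cents, parents = parents,
       ovules = ovules, pollens = pollens, hybrids = hybrids,
       reference = ref, panel = panel, partition = partition,
       counts = counts, phenotypes = phen,
       qtl = do.call(rbind, c(qtl_rows, make.row.names = FALSE)),
       truth = truth, config = config, seed = seed)
}
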