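#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage end-to-end on a simulated cohort: cohort
#' simulation, diagnostic-SNP mining, window dose calling, gamete inference
#' and cleaning, the meiotic-behavior fit, genetic maps with Marey
#' recombination profiles, linkage grouping, principal-coordinate analysis,
#' the dose-phenotype association scan and candidate-gene inheritance
#' tabulation. All stage outputs are written as plain-text tables under
#' `outdir` together with the resolved configuration; runs are
#' deterministic given the seed.
#'
#' @param config configuration list from [default_config()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed (default from the config).
#' @param genes optional candidate-gene table (`gene`, `trait`, `chrom`,
#'   `start`, `end`); defaults to [synthetic_candidate_genes()].
#' @return invisible list with every stage result and the output paths.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = config$seed,
                         genes = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- seed
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  co <- simulate_cohort(config, seed = seed)
  if (is.null(genes)) {
    wtrif <- co$partition$windows
    genes <- synthetic_candidate_genes(
      wtrif[wtrif$ancestor == "trifoliata", , drop = FALSE])
  }

  .write_tsv(co$panel, file.path(outdir, "dsnp_panel.tsv"))
  summ <- dsnp_summary(co$panel)
  utils::write.table(cbind(chromosome = rownames(summ), summ),
                     file.path(outdir, "dsnp_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_tsv(co$partition$windows, file.path(outdir, "windows.tsv"))
  .write_tsv(co$centromeres[, c("chrom", "start", "end")],
             file.path(outdir, "centromeres.bed"))
  utils::write.csv(co$phenotypes, file.path(outdir, "phenotypes.csv"),
                   row.names = FALSE)
  .write_truth(co, outdir)

  doses <- call_hybrid_doses(co$counts, co$partition,
                             ploidy = 4, error = config$reads$error,
                             min_reads = config$reads$min_reads,
                             lr_min = config$reads$lr_min)
  gam <- list(volkamer = infer_gametes(doses$medica, "ovule"),
              citrumelo = infer_gametes(doses$trifoliata, "pollen"))

  results <- list(cohort = co, doses = doses, genes = genes)
  for (side in names(gam)) {
    write_dose_matrix(gam[[side]],
                      file.path(outdir, paste0("gametes_", side, "_raw.tsv")))
    cl <- clean_gametes(gam[[side]],
                        max_window_missing = config$cleaning$max_window_missing,
                        max_indiv_missing = config$cleaning$max_indiv_missing,
                        k = config$cleaning$aberrant_k)
    cl$report$n_inconsistent <- attr(gam[[side]], "n_inconsistent")
    jsonlite::write_json(cl$report,
                         file.path(outdir, paste0("cleaning_", side, ".json")),
                         auto_unbox = TRUE)
    dm <- cl$matrix
    write_dose_matrix(dm, file.path(outdir, paste0("gametes_", side, ".tsv")))

    fit <- meiosis_fit(dm, co$centromeres,
                       grid_step = config$fit$grid_step,
                       q_method = config$fit$q_method,
                       q_threshold = config$fit$q_threshold,
                       min_n = config$fit$min_n)
    .write_tsv(fit$windows, file.path(outdir, paste0("meiosis_windows_", side, ".tsv")))
    .write_tsv(fit$chromosomes, file.path(outdir, paste0("meiosis_chromosomes_", side, ".tsv")))

    lg <- linkage_groups(dm, threshold = config$map$rf_threshold,
                         method = "cor", min_overlap = config$map$min_overlap)
    .write_tsv(data.frame(window = names(lg), group = lg),
               file.path(outdir, paste0("linkage_groups_", side, ".tsv")))

    map <- suppressWarnings(build_map(dm, min_overlap = config$map$min_overlap))
    .write_tsv(map$map, file.path(outdir, paste0("map_", side, ".tsv")))
    .write_tsv(map$summary, file.path(outdir, paste0("map_summary_", side, ".tsv")))
    marey <- suppressWarnings(marey_rate(map, span = config$map$span,
                                         min_markers = config$map$marey_min_markers))
    if (!is.null(marey))
      .write_tsv(marey, file.path(outdir, paste0("marey_", side, ".tsv")))

    D <- manhattan_dissimilarity(dm)
    pco <- factorial_coordinates(D, k = 3)
    utils::write.csv(data.frame(id = rownames(pco$points), pco$points,
                                check.names = FALSE),
                     file.path(outdir, paste0("pcoa_", side, ".csv")),
                     row.names = FALSE)

    assoc <- glm_scan(dm, co$phenotypes,
                      p_threshold = config$assoc$p_threshold,
                      coding = config$assoc$coding)
    .write_tsv(assoc, file.path(outdir, paste0("association_", side, ".tsv")))

    results[[side]] <- list(gametes = dm, cleaning = cl$report, fit = fit,
                            linkage_groups = lg, map = map, marey = marey,
                            pcoa = pco, association = assoc)
  }

  gi <- gene_inheritance(gam$citrumelo, genes)
  .write_tsv(gi$table, file.path(outdir, "gene_inheritance.tsv"))
  jsonlite::write_json(
    list(pct_at_least_one_everywhere = gi$pct_at_least_one_everywhere),
    file.path(outdir, "gene_inheritance_overall.json"), auto_unbox = TRUE)
  results$gene_inheritance <- gi
  results$outdir <- outdir
  invisible(results)
}

# simulator ground truth as flat plain-text tables
.write_truth <- function(co, outdir) {
  write_dose_matrix(co$truth$ovule_doses,
                    file.path(outdir, "truth_ovule_doses.tsv"))
  write_dose_matrix(co$truth$pollen_doses,
                    file.path(outdir, "truth_pollen_doses.tsv"))
  segs <- list(); xo <- list()
  for (set in c("ovules", "pollens")) {
    for (g in co[[set]]) {
      for (ch in names(g$chrom)) {
        for (k in 1:2) {
          s <- g$chrom[[ch]]$chromatids[[k]]
          segs[[length(segs) + 1L]] <- data.frame(
            set = set, gamete = g$id, chrom = ch, chromatid = k,
            start = s$start, end = s$end, ancestor = s$anc,
            stringsAsFactors = FALSE)
        }
        if (length(g$chrom[[ch]]$xo))
          xo[[length(xo) + 1L]] <- data.frame(
            set = set, gamete = g$id, chrom = ch,
            pos = g$chrom[[ch]]$xo,
            config = g$chrom[[ch]]$config, stringsAsFactors = FALSE)
      }
    }
  }
  .write_tsv(do.call(rbind, c(segs, make.row.names = FALSE)),
             file.path(outdir, "truth_gamete_segments.tsv"))
  if (length(xo))
    .write_tsv(do.call(rbind, c(xo, make.row.names = FALSE)),
               file.path(outdir, "truth_crossovers.tsv"))
  if (!is.null(co$qtl))
    .write_tsv(co$qtl, file.path(outdir, "truth_qtl.tsv"))
}

#' Synthetic candidate-gene intervals
#'
#' A small set of synthetic disease- and pest-resistance candidate genes,
#' shaped like the published candidate-gene inheritance table, placed
#' inside genotyped marker windows of the later chromosomes so that every
#' gene is covered by the panel. Purely synthetic coordinates.
#'
#' @param windows window table (e.g. the trifoliata rows of a
#'   [window_partition()] result).
#' @return data.frame with `gene`, `trait`, `chrom`, `start`, `end`.
#' @export
synthetic_candidate_genes <- function(windows) {
  ch <- unique(windows$chrom)
  pick <- function(i, frac) {
    w <- windows[windows$chrom == ch[min(i, length(ch))], , drop = FALSE]
    w[max(1L, round(frac * nrow(w))), ]
  }
  mk <- function(gene, trait, i, frac) {
    w <- pick(i, frac)
    mid <- round((w$start + w$end) / 2)
    data.frame(gene = gene, trait = trait, chrom = w$chrom,
               start = mid - 2500, end = mid + 2500,
               stringsAsFactors = FALSE)
  }
  rbind(mk("synth_hlb_1", "HLB_tolerance", 6, 0.55),
        mk("synth_hlb_2", "HLB_tolerance", 9, 0.60),
        mk("synth_ctv_1", "CTV_resistance", 7, 0.38),
        mk("synth_nem_1", "nematode_resistance", 7, 0.32),
        mk("synth_nem_2", "nematode_resistance", 7, 0.34))
}
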