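#' Dose-phenotype association scan (general linear model)
#'
#' Per window and trait, fits `phenotype ~ dose` with additive 0/1/2 dose
#' coding (or dose-class factor coding) and reports the F-test p-value.
#' Windows with a single observed dose class are skipped.
#'
#' @param dm a gamete `dose_matrix` whose row names match `phen$id`
#'   (gametes are labelled by the hybrid they produced).
#' @param phen phenotype data.frame with an `id` column and one numeric
#'   column per trait.
#' @param traits traits to scan (default: all non-id columns).
#' @param p_threshold significance annotation threshold (default 0.01).
#' @param coding `"additive"` (default) or `"factor"`.
#' @return data.frame with one row per trait x window: dose-class counts,
#'   slope estimate (additive coding), F statistic, `p`, `neg_log10_p`,
#'   `significant`.
#' @export
glm_scan <- function(dm, phen, traits = NULL, p_threshold = 0.01,
                     coding = c("additive", "factor")) {
  stopifnot(inherits(dm, "dose_matrix"), "id" %in% names(phen))
  coding <- match.arg(coding)
  ids <- intersect(rownames(dm$dose), phen$id)
  if (!length(ids)) stop("no phenotype ids match the dose matrix")
  if (is.null(traits)) traits <- setdiff(names(phen), "id")
  ph <- phen[match(ids, phen$id), , drop = FALSE]
  m <- dm$dose[ids, , drop = FALSE]

  rows <- list()
  for (tr in traits) {
    y_all <- ph[[tr]]
    for (w in seq_len(ncol(m))) {
      d <- m[, w]
      ok <- !is.na(d) & !is.na(y_all)
      d0 <- d[ok]; y <- y_all[ok]
      if (length(unique(d0)) < 2 || length(d0) < 3) next
      x <- if (coding == "additive") d0 else factor(d0)
      fit <- stats::lm(y ~ x)
      a <- stats::anova(fit)
      pval <- a[["Pr(>F)"]][1]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr,
        window = colnames(m)[w],
        chrom = dm$windows$chrom[w],
        pos = dm$windows$pos[w],
        n0 = sum(d0 == 0), n1 = sum(d0 == 1), n2 = sum(d0 == 2),
        effect = if (coding == "additive") stats::coef(fit)[[2]] else NA_real_,
        f_stat = a[["F value"]][1],
        p = pval,
        neg_log10_p = -log10(pval),
        significant = pval < p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no testable window (all windows monomorphic?)")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Tabulate candidate-gene ancestor-dose inheritance
#'
#' Maps each gene interval to the marker window(s) it overlaps, assigns
#' each hybrid the majority dose across those windows (missing or tied
#' votes are undetermined), and reports the percentage of hybrids carrying
#' 0, 1 or 2 doses of the tracked ancestor per gene, plus the overall
#' fraction of hybrids with at least one dose at every supplied gene.
#'
#' @param dm a `dose_matrix` of hybrid doses for the tracked ancestor
#'   (values 0-2 under the study design).
#' @param genes data.frame with columns `gene`, `trait`, `chrom`, `start`,
#'   `end`.
#' @return list with `table` (per-gene percentages, Table-5 shape) and
#'   `pct_at_least_one_everywhere`.
#' @export
gene_inheritance <- function(dm, genes) {
  stopifnot(inherits(dm, "dose_matrix"),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  w <- dm$windows
  if (!all(c("start", "end") %in% names(w)) || anyNA(w$start))
    w$start <- w$end <- w$pos
  nh <- nrow(dm$dose)
  per_gene_dose <- matrix(NA_real_, nh, nrow(genes),
                          dimnames = list(rownames(dm$dose), genes$gene))
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    hit <- which(w$chrom == genes$chrom[g] &
                 w$start <= genes$end[g] & w$end >= genes$start[g])
    if (!length(hit)) {
      warning("gene ", genes$gene[g],
              " overlaps no covered window; all hybrids undetermined")
      doses <- rep(NA_real_, nh)
    } else {
      sub <- dm$dose[, hit, drop = FALSE]
      doses <- apply(sub, 1, function(v) {
        v <- v[!is.na(v) & v <= 2]
        if (!length(v)) return(NA_real_)
        tab <- table(v)
        top <- tab[tab == max(tab)]
        if (length(top) > 1) NA_real_ else as.numeric(names(top))
      })
    }
    per_gene_dose[, g] <- doses
    rows[[g]] <- data.frame(
      gene = genes$gene[g],
      trait = if ("trait" %in% names(genes)) genes$trait[g] else NA_character_,
      chrom = genes$chrom[g], start = genes$start[g], end = genes$end[g],
      pct_dose0 = 100 * sum(doses == 0, na.rm = TRUE) / nh,
      pct_dose1 = 100 * sum(doses == 1, na.rm = TRUE) / nh,
      pct_dose2 = 100 * sum(doses == 2, na.rm = TRUE) / nh,
      pct_undetermined = 100 * sum(is.na(doses)) / nh,
      stringsAsFactors = FALSE)
  }
  carried <- apply(per_gene_dose, 1, function(v) all(!is.na(v) & v >= 1))
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       pct_at_least_one_everywhere = 100 * mean(carried))
}
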