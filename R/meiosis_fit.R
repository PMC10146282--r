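#' Diploid gamete class probabilities of a duplex locus
#'
#' Under bivalent meiosis of a doubled diploid without double reduction, a
#' duplex marker A1A1A2A2 produces the two homozygous diploid gamete classes
#' with probability `tau/6` each and the heterozygous class with probability
#' `1 - tau/3`, where `tau = 1 - PP` is the tetrasomic parameter. At
#' `tau = 1` (full tetrasomy) the classes are (1/6, 1/6, 4/6); at `tau = 0`
#' (strict disomy) every gamete is heterozygous.
#'
#' @param tau tetrasomic parameter in \[0, 1\].
#' @return named numeric vector `c(A1A1, A2A2, A1A2)` summing to 1.
#' @export
tetrasomic_probs <- function(tau) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  # (3 - tau)/3 rather than 1 - tau/3: algebraically identical, and exact in
  # floating point at tau = 1 (returns 2/3 bit-for-bit)
  c(A1A1 = tau / 6, A2A2 = tau / 6, A1A2 = (3 - tau) / 3)
}

#' Grid-search maximum-likelihood estimate of the tetrasomic parameter
#'
#' Maximizes the log-likelihood
#' `(x1 + x2) * log(tau/6) + x3 * log(1 - tau/3)` (the combinatorial
#' constant is irrelevant to the argmax) over a grid of `tau` values from 0
#' to 1. Ties break toward the smaller `tau`. Preferential pairing is
#' `PP = 1 - tau_hat`.
#'
#' @param x1,x2 counts of the two homozygous diploid gamete classes.
#' @param x3 count of heterozygous gametes.
#' @param step grid step (default 0.005).
#' @return list with `tau`, `pp`, and the profile `loglik` over the grid.
#' @export
estimate_tau <- function(x1, x2, x3, step = 0.005) {
  if (any(c(x1, x2, x3) < 0)) stop("class counts must be non-negative")
  n <- x1 + x2 + x3
  if (n <= 0) stop("at least one classified gamete is required")
  s <- x1 + x2
  grid <- seq(0, 1, by = step)
  hom_term <- if (s > 0) s * log(grid / 6) else numeric(length(grid))
  ll <- hom_term + x3 * log1p(-grid / 3)
  i <- which.max(ll)  # first maximum: ties go to the smaller tau
  list(tau = grid[i], pp = 1 - grid[i],
       loglik = stats::setNames(ll, grid))
}

#' Parental heterozygosity restitution per window
#'
#' The fraction of gametes heterozygous for the parent's two homeologous
#' haplotypes (dose 1) among non-missing calls, per window.
#'
#' @param dm a gamete `dose_matrix` (ploidy 2).
#' @return named numeric vector, one PHR per window (NA where no calls).
#' @export
phr <- function(dm) {
  stopifnot(inherits(dm, "dose_matrix"))
  apply(dm$dose, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v == 1)
  })
}

#' Gamete class counts per window
#'
#' @param dm a gamete `dose_matrix` (ploidy 2). Dose 2 is counted as the
#'   A1A1 class (both chromatids carry the tracked ancestor), dose 0 as
#'   A2A2 and dose 1 as A1A2.
#' @return data.frame with columns `window`, `x1`, `x2`, `x3`, `n`.
#' @export
gamete_class_counts <- function(dm) {
  stopifnot(inherits(dm, "dose_matrix"))
  x1 <- colSums(dm$dose == 2, na.rm = TRUE)
  x2 <- colSums(dm$dose == 0, na.rm = TRUE)
  x3 <- colSums(dm$dose == 1, na.rm = TRUE)
  data.frame(window = colnames(dm$dose), x1 = x1, x2 = x2, x3 = x3,
             n = x1 + x2 + x3, row.names = NULL, stringsAsFactors = FALSE)
}

#' Preferential pairing per chromosome from centromeric markers
#'
#' For each chromosome, the window nearest the centromere midpoint and its
#' two nearest flanking windows are treated as the centromeric markers;
#' `tau` is estimated at each by [estimate_tau()] and the chromosome PP is
#' the mean of the three marker PP values.
#'
#' @param dm a gamete `dose_matrix`.
#' @param centromeres data.frame with columns `chrom` and `mid` (bp), e.g.
#'   from [centromere_table()].
#' @param step grid step for [estimate_tau()].
#' @return list with `markers` (per-marker estimates) and `chromosomes`
#'   (per-chromosome mean PP).
#' @export
pp_per_chromosome <- function(dm, centromeres, step = 0.005) {
  stopifnot(inherits(dm, "dose_matrix"),
            all(c("chrom", "mid") %in% names(centromeres)))
  counts <- gamete_class_counts(dm)
  marker_rows <- list(); chrom_rows <- list()
  for (ch in unique(dm$windows$chrom)) {
    cols <- which(dm$windows$chrom == ch)
    cols <- cols[order(dm$windows$pos[cols])]
    if (length(cols) < 3)
      stop("chromosome ", ch, " has fewer than 3 windows")
    mid <- centromeres$mid[match(ch, centromeres$chrom)]
    if (is.na(mid)) stop("no centromere supplied for ", ch)
    j <- which.min(abs(dm$windows$pos[cols] - mid))
    j <- min(max(j, 2L), length(cols) - 1L)
    trio <- cols[(j - 1L):(j + 1L)]
    est <- lapply(trio, function(cc) {
      k <- match(dm$windows$window[cc], counts$window)
      estimate_tau(counts$x1[k], counts$x2[k], counts$x3[k], step)
    })
    marker_rows[[ch]] <- data.frame(
      chrom = ch, window = dm$windows$window[trio],
      pos = dm$windows$pos[trio],
      tau = vapply(est, `[[`, 0, "tau"),
      pp = vapply(est, `[[`, 0, "pp"),
      stringsAsFactors = FALSE)
    chrom_rows[[ch]] <- data.frame(
      chrom = ch, pp = mean(vapply(est, `[[`, 0, "pp")),
      tau = mean(vapply(est, `[[`, 0, "tau")),
      stringsAsFactors = FALSE)
  }
  list(markers = do.call(rbind, c(marker_rows, make.row.names = FALSE)),
       chromosomes = do.call(rbind, c(chrom_rows, make.row.names = FALSE)))
}

#' Chi-square scan for deviation from tetrasomic segregation
#'
#' Per window, the observed gamete class counts are tested against the
#' fully tetrasomic expectation `(N/6, N/6, 4N/6)` with a 2-df chi-square
#' statistic; multiplicity is controlled with Benjamini-Hochberg q-values
#' (or Storey's method with an estimated null proportion).
#'
#' @param dm a gamete `dose_matrix`.
#' @param q_method `"BH"` (default) or `"storey"`.
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param min_n windows with fewer classified gametes are flagged `low_n`.
#' @return data.frame with per-window `chi2`, `p`, `q`, `neg_log10_q`,
#'   `significant` and `low_n`.
#' @export
tetrasomic_deviation_scan <- function(dm, q_method = c("BH", "storey"),
                                      q_threshold = 0.05, min_n = 20) {
  stopifnot(inherits(dm, "dose_matrix"))
  q_method <- match.arg(q_method)
  counts <- gamete_class_counts(dm)
  counts <- counts[counts$n > 0, , drop = FALSE]
  obs <- as.matrix(counts[, c("x1", "x2", "x3")])
  expd <- counts$n %o% c(1 / 6, 1 / 6, 4 / 6)
  chi2 <- rowSums((obs - expd)^2 / expd)
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  q <- switch(q_method,
              BH = stats::p.adjust(p, method = "BH"),
              storey = .storey_q(p))
  k <- match(counts$window, dm$windows$window)
  data.frame(window = counts$window,
             chrom = dm$windows$chrom[k],
             pos = dm$windows$pos[k],
             n = counts$n, x1 = counts$x1, x2 = counts$x2, x3 = counts$x3,
             chi2 = chi2, p = p, q = q,
             neg_log10_q = -log10(q),
             significant = q < q_threshold,
             low_n = counts$n < min_n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Storey-style q-values: BH scaled by an estimated null proportion pi0
.storey_q <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Fit the meiotic-behavior model to a gamete dose matrix
#'
#' The one-stop estimator of a doubled-diploid parent's meiotic behavior:
#' per-window parental heterozygosity restitution (PHR), per-chromosome
#' preferential pairing (PP) by grid-search maximum likelihood at the three
#' centromeric markers, and a genome-wide chi-square scan for deviation from
#' tetrasomic segregation with FDR control.
#'
#' @param dm a cleaned gamete `dose_matrix` (ploidy 2).
#' @param centromeres data.frame with `chrom` and `mid` columns.
#' @param grid_step grid step of the tau likelihood search.
#' @param q_method,q_threshold,min_n see [tetrasomic_deviation_scan()].
#' @return An object of class `meiosis_fit` with elements `windows`
#'   (per-window statistics), `pp_markers`, `chromosomes` (per-chromosome
#'   summary in the shape of the usual PHR/PP and distortion report tables)
#'   and `genome` (whole-genome means).
#' @export
meiosis_fit <- function(dm, centromeres, grid_step = 0.005,
                        q_method = "BH", q_threshold = 0.05, min_n = 20) {
  stopifnot(inherits(dm, "dose_matrix"))
  scan <- tetrasomic_deviation_scan(dm, q_method = q_method,
                                    q_threshold = q_threshold, min_n = min_n)
  scan$phr <- phr(dm)[scan$window]
  pp <- pp_per_chromosome(dm, centromeres, step = grid_step)

  chroms <- do.call(rbind, lapply(split(scan, scan$chrom), function(s) {
    data.frame(chrom = s$chrom[1],
               n_windows = nrow(s),
               phr = mean(s$phr, na.rm = TRUE),
               mean_neg_log10_q = mean(s$neg_log10_q),
               n_significant = sum(s$significant),
               pct_significant = 100 * mean(s$significant),
               stringsAsFactors = FALSE)
  }))
  chroms$pp <- pp$chromosomes$pp[match(chroms$chrom, pp$chromosomes$chrom)]
  chroms <- chroms[order(match(chroms$chrom, unique(dm$windows$chrom))),
                   c("chrom", "n_windows", "phr", "pp", "mean_neg_log10_q",
                     "n_significant", "pct_significant")]
  rownames(chroms) <- NULL

  structure(list(windows = scan,
                 pp_markers = pp$markers,
                 chromosomes = chroms,
                 genome = data.frame(
                   phr = mean(scan$phr, na.rm = TRUE),
                   pp = mean(chroms$pp),
                   pct_significant = 100 * mean(scan$significant)),
                 n_gametes = nrow(dm$dose),
                 ancestor = dm$ancestor, parent = dm$parent,
                 q_threshold = q_threshold, grid_step = grid_step,
                 call = match.call()),
            class = "meiosis_fit")
}

#' @export
print.meiosis_fit <- function(x, ...) {
  cat("Meiotic behavior fit (", x$n_gametes, " gametes, ",
      nrow(x$windows), " windows, ancestor ", x$ancestor, ")\n", sep = "")
  cat(sprintf("  genome PHR %.3f, genome PP %.3f, %.1f%% windows deviate from tetrasomy (q < %g)\n",
              x$genome$phr, x$genome$pp, x$genome$pct_significant,
              x$q_threshold))
  invisible(x)
}

#' @export
summary.meiosis_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.meiosis_fit")
}

#' @export
print.summary.meiosis_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-chromosome meiotic parameters:\n")
  tab <- f$chromosomes
  tab$phr <- round(tab$phr, 3); tab$pp <- round(tab$pp, 3)
  tab$mean_neg_log10_q <- round(tab$mean_neg_log10_q, 3)
  tab$pct_significant <- round(tab$pct_significant, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.meiosis_fit <- function(object, ...) {
  stats::setNames(object$chromosomes$pp, object$chromosomes$chrom)
}

#' Pearson residuals of window class counts against the fitted model
#'
#' Observed gamete class counts per window against the tetrasomic-model
#' expectation at the chromosome's fitted tau.
#'
#' @param object a `meiosis_fit`.
#' @param ... unused.
#' @return numeric matrix windows x classes of Pearson residuals.
#' @export
residuals.meiosis_fit <- function(object, ...) {
  tau <- 1 - object$chromosomes$pp
  names(tau) <- object$chromosomes$chrom
  w <- object$windows
  out <- matrix(NA_real_, nrow(w), 3,
                dimnames = list(w$window, c("A1A1", "A2A2", "A1A2")))
  for (i in seq_len(nrow(w))) {
    pr <- tetrasomic_probs(tau[[w$chrom[i]]])
    expd <- w$n[i] * pr
    obs <- c(w$x1[i], w$x2[i], w$x3[i])
    out[i, ] <- (obs - expd) / sqrt(pmax(expd, .Machine$double.eps))
  }
  out
}

#' Parametric bootstrap of window class counts from a fitted model
#'
#' Draws multinomial gamete class counts per window at the fitted
#' per-chromosome tau, with the observed per-window sample sizes.
#'
#' @param object a `meiosis_fit`.
#' @param nsim number of replicate count tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of data.frames (`window`, `x1`, `x2`, `x3`).
#' @export
simulate.meiosis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tau <- 1 - object$chromosomes$pp
  names(tau) <- object$chromosomes$chrom
  w <- object$windows
  replicate(nsim, {
    counts <- t(vapply(seq_len(nrow(w)), function(i) {
      stats::rmultinom(1, w$n[i], tetrasomic_probs(tau[[w$chrom[i]]]))[, 1]
    }, numeric(3)))
    data.frame(window = w$window, x1 = counts[, 1], x2 = counts[, 2],
               x3 = counts[, 3], stringsAsFactors = FALSE)
  }, simplify = FALSE)
}

#' Plot meiotic-behavior statistics along the genome
#'
#' Two panels per fit: window PHR and the -log10 q-value of the tetrasomic
#' deviation test, against physical position, colored by chromosome.
#'
#' @param x a `meiosis_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meiosis_fit <- function(x, ...) {
  w <- x$windows
  chroms <- unique(w$chrom)
  col <- grDevices::hcl.colors(max(3, length(chroms)), "Dark 3")
  ci <- match(w$chrom, chroms)
  off <- c(0, cumsum(tapply(w$pos, factor(w$chrom, levels = chroms), max)))
  xpos <- w$pos + off[ci]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(xpos, w$phr, col = col[ci], pch = 16,
                 xlab = "cumulative position (bp)", ylab = "PHR",
                 main = paste("Parental heterozygosity restitution -",
                              x$ancestor), ylim = c(0, 1), ...)
  graphics::plot(xpos, w$neg_log10_q, col = col[ci], pch = 16,
                 xlab = "cumulative position (bp)",
                 ylab = expression(-log[10](q)),
                 main = "Deviation from tetrasomic segregation", ...)
  graphics::abline(h = -log10(x$q_threshold), lty = 2)
  invisible(x)
}
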