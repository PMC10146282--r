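#' Pairwise recombination fraction between two windows
#'
#' Two estimators are available.
#'
#' `"dose"` — apparent recombination: `sum(|d_i - d_j|) / (2 * N)` over
#' gametes with both calls, capped at 0.5. Each unit of dose change between
#' the loci evidences one crossover among the gamete's two chromatids. It is
#' exact for single-crossover intervals, undercounts double crossovers, and
#' only counts recombination that is visible as an ancestry change — so it
#' shrinks with preferential pairing, exactly like the apparent
#' interspecific recombination of the study system. Use it for map building.
#'
#' `"cor"` — correlation-based: `r = (1 - max(cor(d_i, d_j), 0)) / 2`. Under
#' the bivalent model the dose correlation between linked windows equals
#' `1 - 2r` whatever the pairing regime (pairing shrinks the dose variance
#' and covariance by the same factor), and is ~0 for unlinked windows, so
#' unlinked pairs sit at r = 0.5. Use it for linkage grouping, where the
#' dose estimator never reaches 0.5 for independent loci.
#'
#' @param dm a gamete `dose_matrix`.
#' @param i,j window ids or column indices.
#' @param method `"dose"` or `"cor"`.
#' @param min_overlap minimum number of gametes with both calls (default
#'   20); below it the estimate is `NA`.
#' @return estimated recombination fraction in \[0, 0.5\] or `NA`.
#' @export
pairwise_rf <- function(dm, i, j, method = c("dose", "cor"),
                        min_overlap = 20) {
  stopifnot(inherits(dm, "dose_matrix"))
  method <- match.arg(method)
  if (is.character(i)) i <- match(i, colnames(dm$dose))
  if (is.character(j)) j <- match(j, colnames(dm$dose))
  di <- dm$dose[, i]; dj <- dm$dose[, j]
  ok <- !is.na(di) & !is.na(dj)
  if (sum(ok) < min_overlap) return(NA_real_)
  .rf_pair(di[ok], dj[ok], method)
}

.rf_pair <- function(di, dj, method) {
  if (method == "dose") {
    min(0.5, sum(abs(di - dj)) / (2 * length(di)))
  } else {
    if (stats::sd(di) == 0 || stats::sd(dj) == 0) return(0.5)
    (1 - max(stats::cor(di, dj), 0)) / 2
  }
}

#' All-pairs recombination-fraction matrix
#'
#' @inheritParams pairwise_rf
#' @return symmetric matrix of rf estimates (NA diagonal set to 0).
#' @export
rf_matrix <- function(dm, method = c("dose", "cor"), min_overlap = 20) {
  method <- match.arg(method)
  m <- dm$dose
  nw <- ncol(m)
  out <- matrix(NA_real_, nw, nw, dimnames = list(colnames(m), colnames(m)))
  diag(out) <- 0
  for (i in seq_len(nw - 1)) {
    di <- m[, i]
    for (j in (i + 1):nw) {
      dj <- m[, j]
      ok <- !is.na(di) & !is.na(dj)
      r <- if (sum(ok) < min_overlap) NA_real_
           else .rf_pair(di[ok], dj[ok], method)
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Single-linkage linkage grouping
#'
#' Joins window pairs whose recombination fraction is below `threshold`
#' (single linkage); on synthetic cohorts the groups are expected to
#' coincide with chromosomes. Missing rf values are treated as unlinked
#' (0.5).
#'
#' @param dm a gamete `dose_matrix`, or a precomputed rf matrix.
#' @param threshold joining threshold (default 0.3); pairs with
#'   `rf < threshold` end up in the same group.
#' @param method rf estimator when `dm` is a dose matrix (default `"cor"`,
#'   see [pairwise_rf()]).
#' @param min_overlap passed to [rf_matrix()].
#' @return named integer vector of group memberships, one per window.
#' @export
linkage_groups <- function(dm, threshold = 0.3, method = "cor",
                           min_overlap = 20) {
  rfm <- if (inherits(dm, "dose_matrix"))
    rf_matrix(dm, method = method, min_overlap = min_overlap) else dm
  rfm[is.na(rfm)] <- 0.5
  hc <- stats::hclust(stats::as.dist(rfm), method = "single")
  stats::cutree(hc, h = threshold - 1e-12)
}

#' Kosambi map distance
#'
#' `cM = 25 * ln((1 + 2r) / (1 - 2r))`, allowing incomplete crossover
#' interference.
#'
#' @param r recombination fraction in \[0, 0.5).
#' @return map distance in centimorgans.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Build a genetic map on fixed physical order
#'
#' Windows are taken in physical order within each chromosome (no marker
#' reordering); the map position is the cumulative Kosambi distance of
#' adjacent-window recombination fractions (the `"dose"` apparent-rf
#' estimator). A missing adjacent rf, or an rf at the 0.5 cap where the
#' Kosambi function diverges, contributes zero length with a warning.
#'
#' @param dm a gamete `dose_matrix`.
#' @param min_overlap passed to [pairwise_rf()].
#' @param max_rf adjacent rf values at or above this are skipped
#'   (default 0.499).
#' @return An object of class `genetic_map`: list with `map` (window, chrom,
#'   pos bp, cm) and `summary` (per linkage group: marker count, length cM).
#' @export
build_map <- function(dm, min_overlap = 20, max_rf = 0.499) {
  stopifnot(inherits(dm, "dose_matrix"))
  rows <- list(); summ <- list()
  for (ch in unique(dm$windows$chrom)) {
    cols <- which(dm$windows$chrom == ch)
    cols <- cols[order(dm$windows$pos[cols])]
    cm <- numeric(length(cols))
    skipped <- 0L
    for (k in seq_along(cols)[-1]) {
      di <- dm$dose[, cols[k - 1]]; dj <- dm$dose[, cols[k]]
      ok <- !is.na(di) & !is.na(dj)
      r <- if (sum(ok) < min_overlap) NA_real_
           else .rf_pair(di[ok], dj[ok], "dose")
      if (is.na(r) || r >= max_rf) {
        skipped <- skipped + 1L
        d <- 0
      } else d <- kosambi_cm(r)
      cm[k] <- cm[k - 1] + d
    }
    if (skipped > 0)
      warning(skipped, " interval(s) on ", ch,
              " had missing or capped rf; zero length assigned")
    rows[[ch]] <- data.frame(chrom = ch,
                             window = dm$windows$window[cols],
                             pos = dm$windows$pos[cols],
                             cm = cm, stringsAsFactors = FALSE)
    summ[[ch]] <- data.frame(chrom = ch, n_markers = length(cols),
                             length_cm = cm[length(cm)],
                             stringsAsFactors = FALSE)
  }
  structure(list(map = do.call(rbind, c(rows, make.row.names = FALSE)),
                 summary = do.call(rbind, c(summ, make.row.names = FALSE))),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x$map), "markers in", nrow(x$summary),
      sprintf("linkage groups, total %.2f cM\n", sum(x$summary$length_cm)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Marey-map local recombination rate profile
#'
#' Local linear regression of genetic position (cM) on physical position
#' (Mb) with tricube weights over a `span` fraction of the markers of each
#' linkage group; the local slope at each marker is the recombination rate
#' in cM/Mb, with negative slopes clipped to zero.
#'
#' @param map a `genetic_map` from [build_map()].
#' @param span fraction of markers in each local fit (default 0.15); at
#'   least 4 markers are always used.
#' @param min_markers linkage groups with fewer markers are skipped with a
#'   warning.
#' @return data.frame with `chrom`, `window`, `pos`, `rate_cm_mb`.
#' @export
marey_rate <- function(map, span = 0.15, min_markers = 10) {
  stopifnot(inherits(map, "genetic_map"))
  out <- list()
  for (ch in unique(map$map$chrom)) {
    s <- map$map[map$map$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    if (n < min_markers) {
      warning("linkage group ", ch, " has fewer than ", min_markers,
              " markers; skipped")
      next
    }
    x <- s$pos / 1e6
    if (length(unique(x)) < 2)
      stop("degenerate linkage group ", ch, ": all markers at one position")
    y <- s$cm
    q <- max(4L, ceiling(span * n))
    rate <- vapply(seq_len(n), function(i) {
      d <- abs(x - x[i])
      idx <- order(d)[seq_len(q)]
      dmax <- max(d[idx])
      w <- if (dmax == 0) rep(1, q) else (1 - pmin(d[idx] / dmax, 1)^3)^3
      w[w <= 0] <- 1e-9
      fit <- stats::lm.wfit(cbind(1, x[idx]), y[idx], w)
      max(0, fit$coefficients[2])
    }, 0)
    out[[ch]] <- data.frame(chrom = ch, window = s$window, pos = s$pos,
                            rate_cm_mb = rate, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
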