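#' Partition a DSNP panel into genomic windows
#'
#' Consecutive same-ancestor diagnostic SNPs on a chromosome are grouped
#' `size` at a time (default 20). A terminal remainder of at least `size/2`
#' sites becomes its own window; a smaller remainder is merged into the
#' previous window (or kept alone if it is the only window of the
#' chromosome). The representative position of a window is the arithmetic
#' mean of its member positions.
#'
#' @param panel DSNP panel data.frame (`chrom`, `pos`, `taxon`).
#' @param size window size in DSNPs.
#' @return list with `windows` (data.frame: `window`, `chrom`, `ancestor`,
#'   `start`, `end`, `pos`, `n_snp`) and `sites` (the panel with a
#'   `window` id column).
#' @export
window_partition <- function(panel, size = 20) {
  if (nrow(panel) == 0) stop("empty DSNP panel")
  panel <- panel[order(panel$taxon, panel$chrom, panel$pos), , drop = FALSE]
  panel$window <- NA_character_
  win_rows <- list()
  for (tx in unique(panel$taxon)) {
    for (ch in unique(panel$chrom[panel$taxon == tx])) {
      idx <- which(panel$taxon == tx & panel$chrom == ch)
      k <- length(idx)
      nw <- k %/% size
      rem <- k - nw * size
      wid <- rep(seq_len(max(nw, 1)), each = size, length.out = k)
      if (nw >= 1 && rem > 0) {
        if (rem >= size / 2) wid[(nw * size + 1):k] <- nw + 1
        else wid[(nw * size + 1):k] <- nw
      }
      labels <- sprintf("%s_%s_w%03d", tx, ch, wid)
      panel$window[idx] <- labels
      for (w in unique(wid)) {
        p <- panel$pos[idx[wid == w]]
        win_rows[[length(win_rows) + 1L]] <-
          data.frame(window = sprintf("%s_%s_w%03d", tx, ch, w),
                     chrom = ch, ancestor = tx,
                     start = min(p), end = max(p), pos = mean(p),
                     n_snp = length(p), stringsAsFactors = FALSE)
      }
    }
  }
  windows <- do.call(rbind, win_rows)
  windows <- windows[order(windows$ancestor, windows$chrom, windows$pos), ]
  rownames(windows) <- NULL
  list(windows = windows, sites = panel)
}

#' Dose likelihood for pooled window read counts
#'
#' For a tetraploid (or gamete) window with `a` diagnostic-allele reads out
#' of `t` total, the likelihood of dose `d` is
#' `Binomial(a | t, f_d)` with `f_d = clamp(d/P, error, 1 - error)`.
#' The call is the maximum-likelihood dose; it is set to missing when the
#' window has fewer than `min_reads` reads or when the log10 likelihood
#' ratio of the best against the second-best dose falls below `lr_min`.
#'
#' @param a diagnostic-allele read count (0 <= a <= t).
#' @param t total read count.
#' @param ploidy maximum dose (4 for hybrids, 2 for gametes).
#' @param error per-read error rate.
#' @param min_reads minimum window coverage to call (default 10).
#' @param lr_min minimum log10 likelihood ratio between best and runner-up
#'   dose (default 1, i.e. a 10-fold likelihood margin).
#' @return list with `dose` (NA when no confident call) and `loglik`
#'   (named log-likelihood per candidate dose).
#' @export
window_dose_likelihood <- function(a, t, ploidy = 4, error = 0.01,
                                   min_reads = 10, lr_min = 1) {
  if (a > t) stop("diagnostic reads cannot exceed total reads")
  d <- 0:ploidy
  f <- pmin(pmax(d / ploidy, error), 1 - error)
  ll <- stats::dbinom(a, t, f, log = TRUE)
  names(ll) <- d
  ord <- order(ll, decreasing = TRUE)
  call <- d[ord[1]]
  lr10 <- (ll[ord[1]] - ll[ord[2]]) / log(10)
  if (t < min_reads || lr10 < lr_min) call <- NA_integer_
  list(dose = call, loglik = ll)
}

# vectorized core: A, T vectors -> integer calls (NA where unconfident)
.dose_call_vec <- function(A, T, ploidy, error, min_reads, lr_min) {
  d <- 0:ploidy
  f <- pmin(pmax(d / ploidy, error), 1 - error)
  ll <- vapply(f, function(fd) stats::dbinom(A, T, fd, log = TRUE),
               numeric(length(A)))
  if (length(A) == 1L) ll <- matrix(ll, 1L)
  best <- max.col(ll, ties.method = "first")
  sorted <- t(apply(ll, 1, sort, decreasing = TRUE))
  lr10 <- (sorted[, 1] - sorted[, 2]) / log(10)
  call <- d[best]
  call[T < min_reads | lr10 < lr_min] <- NA_integer_
  as.integer(call)
}

#' Call per-window ancestral doses of tetraploid hybrids from read counts
#'
#' Reads are pooled across the member DSNPs of each window (the multilocus
#' read count of the window) and the pooled binomial likelihood of
#' [window_dose_likelihood()] is maximized per individual and window. One
#' dose matrix is returned per tracked ancestor.
#'
#' @param counts read-count table (`indiv`, `chrom`, `pos`, `taxon`,
#'   `diag_reads`, `tot_reads`), e.g. from [simulate_read_counts()].
#' @param partition output of [window_partition()].
#' @param ploidy ploidy of the genotyped individuals (4 for hybrids).
#' @inheritParams window_dose_likelihood
#' @return named list of `dose_matrix` objects, one per ancestor present in
#'   the partition.
#' @export
call_hybrid_doses <- function(counts, partition, ploidy = 4, error = 0.01,
                              min_reads = 10, lr_min = 1) {
  windows <- partition$windows
  sites <- partition$sites
  skey <- paste(sites$chrom, sites$pos, sites$taxon, sep = ":")
  ckey <- paste(counts$chrom, counts$pos, counts$taxon, sep = ":")
  counts$window <- sites$window[match(ckey, skey)]
  counts <- counts[!is.na(counts$window), , drop = FALSE]
  if (nrow(counts) == 0) stop("no read counts overlap the window partition")

  ids <- sort(unique(counts$indiv))
  # complete indiv x window aggregation (absent combinations -> 0 reads)
  agg_a <- tapply(counts$diag_reads, list(counts$indiv, counts$window), sum)
  agg_t <- tapply(counts$tot_reads, list(counts$indiv, counts$window), sum)
  agg_a[is.na(agg_a)] <- 0; agg_t[is.na(agg_t)] <- 0

  out <- list()
  for (tx in unique(windows$ancestor)) {
    w <- windows[windows$ancestor == tx, , drop = FALSE]
    w <- w[order(w$chrom, w$pos), , drop = FALSE]
    present <- intersect(w$window, colnames(agg_t))
    w <- w[w$window %in% present, , drop = FALSE]
    A <- agg_a[ids, w$window, drop = FALSE]
    T <- agg_t[ids, w$window, drop = FALSE]
    calls <- .dose_call_vec(as.vector(A), as.vector(T), ploidy, error,
                            min_reads, lr_min)
    m <- matrix(calls, nrow(A), ncol(A), dimnames = dimnames(A))
    out[[tx]] <- dose_matrix(m, w, ploidy = ploidy, ancestor = tx)
  }
  out
}
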