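#' Manhattan dissimilarity between individuals
#'
#' `D(i, j) = mean(|x_ik - x_jk|)` over the loci where both individuals
#' have calls. Pairs without any shared non-missing locus get `NA` with a
#' warning.
#'
#' @param x a `dose_matrix` or a plain numeric matrix (rows = individuals).
#' @return symmetric dissimilarity matrix.
#' @export
manhattan_dissimilarity <- function(x) {
  m <- if (inherits(x, "dose_matrix")) x$dose else as.matrix(x)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      D[i, j] <- D[j, i] <- if (!any(ok)) NA_real_
                            else mean(abs(m[i, ok] - m[j, ok]))
    }
  }
  if (anyNA(D)) warning("some individual pairs share no non-missing locus")
  D
}

#' Factorial analysis (principal coordinates) of a dissimilarity matrix
#'
#' Classical PCoA: double-centering of the squared dissimilarities followed
#' by eigendecomposition; axes are sorted by eigenvalue and the variance
#' share of each axis is its eigenvalue over the sum of positive
#' eigenvalues.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param k number of axes to return (default 3).
#' @return list with `points` (individuals x k coordinates), `eig`
#'   (all eigenvalues) and `pct_variance` (percent variance per returned
#'   axis).
#' @export
factorial_coordinates <- function(D, k = 3) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8, na.rm = TRUE))
    stop("D must be square and symmetric")
  k <- min(k, nrow(D) - 1)
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  pct <- 100 * fit$eig[seq_len(k)] / sum(pos)
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate configurations return fewer axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
    pct <- c(pct[seq_len(ncol(fit$points))], rep(0, k - ncol(fit$points)))
  }
  colnames(pts) <- paste0("Axis", seq_len(k))
  list(points = pts, eig = fit$eig, pct_variance = pct)
}
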