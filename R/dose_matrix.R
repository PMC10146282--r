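#' Ancestral dose matrix
#'
#' Container pairing an individuals-by-windows matrix of ancestral allele
#' doses (integers within the ploidy bound, or NA for missing) with its
#' window table and ploidy context (4 for tetraploid hybrids, 2 for diploid
#' gametes).
#'
#' @param m numeric matrix, rows = individuals, columns = windows.
#' @param windows data.frame with at least `window`, `chrom`, `pos`; one row
#'   per column of `m`, same order.
#' @param ploidy 2 or 4.
#' @param ancestor tracked ancestor label.
#' @param parent optional parent label ("ovule" / "pollen" or a parent id).
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(m, windows, ploidy, ancestor = NA_character_,
                        parent = NA_character_) {
  windows <- .check_windows(windows)
  if (ncol(m) != nrow(windows))
    stop("windows table must have one row per matrix column")
  if (!identical(colnames(m), windows$window))
    colnames(m) <- windows$window
  vals <- m[!is.na(m)]
  if (length(vals) && (any(vals < 0) || any(vals > ploidy)))
    stop("doses must lie within the ploidy bound")
  structure(list(dose = m, windows = windows, ploidy = ploidy,
                 ancestor = ancestor, parent = parent),
            class = "dose_matrix")
}

#' @export
as.matrix.dose_matrix <- function(x, ...) x$dose

#' @export
dim.dose_matrix <- function(x) dim(x$dose)

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("Dose matrix: %d individuals x %d windows (ploidy %d, ancestor %s)\n",
              nrow(x$dose), ncol(x$dose), x$ploidy, x$ancestor))
  miss <- mean(is.na(x$dose))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

# subset a dose_matrix keeping the window table in sync
.dm_subset <- function(dm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(dm$dose))
  if (is.null(cols)) cols <- seq_len(ncol(dm$dose))
  dose_matrix(dm$dose[rows, cols, drop = FALSE],
              dm$windows[cols, , drop = FALSE],
              dm$ploidy, dm$ancestor, dm$parent)
}
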