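#' Infer diploid gamete doses from tetraploid hybrid doses
#'
#' In the study design only one parent contributes the tracked ancestor
#' (*C. medica* arrives only through the ovule parent, *P. trifoliata* only
#' through the pollen parent), so the gamete dose equals the hybrid dose
#' verbatim. Hybrid doses of 3 or 4 are impossible under that design, are
#' counted as inconsistencies and set to missing.
#'
#' @param hybrid_dm a `dose_matrix` of hybrid doses (ploidy 4).
#' @param parent label for the gamete population ("ovule" or "pollen").
#' @return A `dose_matrix` of ploidy 2 with attribute `n_inconsistent`.
#' @export
infer_gametes <- function(hybrid_dm, parent = c("ovule", "pollen")) {
  stopifnot(inherits(hybrid_dm, "dose_matrix"))
  parent <- match.arg(parent)
  m <- hybrid_dm$dose
  bad <- !is.na(m) & m > 2
  m[bad] <- NA
  out <- dose_matrix(m, hybrid_dm$windows, ploidy = 2,
                     ancestor = hybrid_dm$ancestor, parent = parent)
  attr(out, "n_inconsistent") <- sum(bad)
  out
}

#' Replace singleton calls with missing data
#'
#' A singleton is an interior window call that differs from both its nearest
#' non-missing flanking calls while those flanks agree with each other —
#' the signature of a genotyping error rather than a double crossover at
#' window resolution. Chromosome ends are left untouched. All singletons
#' are detected on the original matrix and replaced simultaneously.
#'
#' @param dm a `dose_matrix` with windows ordered by chromosome and position.
#' @return The cleaned `dose_matrix`, with attribute `n_singletons`.
#' @export
remove_singletons <- function(dm) {
  stopifnot(inherits(dm, "dose_matrix"))
  m <- dm$dose
  n_rep <- 0L
  for (ch in unique(dm$windows$chrom)) {
    cols <- which(dm$windows$chrom == ch)
    cols <- cols[order(dm$windows$pos[cols])]
    for (i in seq_len(nrow(m))) {
      v <- m[i, cols]
      obs <- which(!is.na(v))
      if (length(obs) < 3) next
      x <- v[obs]
      k <- 2:(length(obs) - 1)
      single <- x[k] != x[k - 1] & x[k] != x[k + 1] & x[k - 1] == x[k + 1]
      if (any(single)) {
        m[i, cols[obs[k[single]]]] <- NA
        n_rep <- n_rep + sum(single)
      }
    }
  }
  out <- dose_matrix(m, dm$windows, dm$ploidy, dm$ancestor, dm$parent)
  attr(out, "n_singletons") <- n_rep
  out
}

#' Drop windows and individuals with excess missing data
#'
#' Windows with more than `max_window_missing` missing calls are removed
#' first, then individuals with more than `max_indiv_missing` missing calls
#' over the retained windows — the defaults mirror the 15% / 20% filters
#' applied before genetic mapping.
#'
#' @param dm a `dose_matrix`.
#' @param max_window_missing maximum missing fraction per window.
#' @param max_indiv_missing maximum missing fraction per individual.
#' @return Filtered `dose_matrix` with attributes `windows_dropped` and
#'   `individuals_dropped`.
#' @export
filter_dose_matrix <- function(dm, max_window_missing = 0.15,
                               max_indiv_missing = 0.20) {
  stopifnot(inherits(dm, "dose_matrix"))
  wmiss <- colMeans(is.na(dm$dose))
  keep_w <- wmiss <= max_window_missing
  if (!any(keep_w)) stop("all windows exceed the missing-data threshold")
  out <- .dm_subset(dm, cols = which(keep_w))
  imiss <- rowMeans(is.na(out$dose))
  keep_i <- imiss <= max_indiv_missing
  if (!any(keep_i)) stop("all individuals exceed the missing-data threshold")
  out <- .dm_subset(out, rows = which(keep_i))
  attr(out, "windows_dropped") <- colnames(dm$dose)[!keep_w]
  attr(out, "individuals_dropped") <- rownames(dm$dose)[!keep_i]
  out
}

#' Remove individuals with an aberrant number of apparent recombinations
#'
#' The per-individual transition count is the sum of |dose change| over
#' adjacent non-missing window pairs within chromosomes. Individuals whose
#' count exceeds `median + k * IQR` of the cohort distribution are removed —
#' a robust automatic stand-in for visual inspection of the global
#' recombination distribution.
#'
#' @param dm a `dose_matrix` with at least 10 individuals.
#' @param k IQR multiplier (default 3).
#' @return Filtered `dose_matrix` with attributes `individuals_dropped` and
#'   `transition_counts`.
#' @export
drop_aberrant_individuals <- function(dm, k = 3) {
  stopifnot(inherits(dm, "dose_matrix"))
  if (nrow(dm$dose) < 10)
    stop("need at least 10 individuals to calibrate the aberrance cutoff")
  tc <- transition_counts(dm)
  cutoff <- stats::median(tc) + k * stats::IQR(tc)
  keep <- tc <= cutoff
  out <- .dm_subset(dm, rows = which(keep))
  attr(out, "individuals_dropped") <- rownames(dm$dose)[!keep]
  attr(out, "transition_counts") <- tc
  out
}

#' Per-individual apparent recombination transition counts
#'
#' @param dm a `dose_matrix`.
#' @return named numeric vector, one count per individual.
#' @export
transition_counts <- function(dm) {
  tc <- numeric(nrow(dm$dose))
  for (ch in unique(dm$windows$chrom)) {
    cols <- which(dm$windows$chrom == ch)
    cols <- cols[order(dm$windows$pos[cols])]
    if (length(cols) < 2) next
    sub <- dm$dose[, cols, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v <- sub[i, ]
      v <- v[!is.na(v)]
      if (length(v) >= 2) tc[i] <- tc[i] + sum(abs(diff(v)))
    }
  }
  names(tc) <- rownames(dm$dose)
  tc
}

#' Run the full gamete-matrix cleaning chain
#'
#' Singleton replacement, missing-data filters (windows then individuals)
#' and aberrant-individual removal, with a machine-readable report.
#'
#' @param dm a `dose_matrix` of gamete doses.
#' @inheritParams filter_dose_matrix
#' @inheritParams drop_aberrant_individuals
#' @param aberrant apply the aberrant-individual filter (needs >= 10
#'   individuals).
#' @return list with `matrix` (cleaned `dose_matrix`) and `report` (counts
#'   of singletons and dropped windows/individuals).
#' @export
clean_gametes <- function(dm, max_window_missing = 0.15,
                          max_indiv_missing = 0.20, k = 3,
                          aberrant = TRUE) {
  s <- remove_singletons(dm)
  f <- filter_dose_matrix(s, max_window_missing, max_indiv_missing)
  report <- list(
    n_singletons = attr(s, "n_singletons"),
    windows_dropped = attr(f, "windows_dropped"),
    individuals_dropped_missing = attr(f, "individuals_dropped")
  )
  if (aberrant && nrow(f$dose) >= 10) {
    f2 <- drop_aberrant_individuals(f, k)
    report$individuals_dropped_aberrant <- attr(f2, "individuals_dropped")
    f <- f2
  } else {
    report$individuals_dropped_aberrant <- character(0)
  }
  list(matrix = f, report = report)
}
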