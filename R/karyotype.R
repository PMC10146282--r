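# Ancestry tracks are data.frames (start, end, anc) tiling [0, L) of a
# chromosome; a doubled-diploid parent carries two homolog sequences, each
# present in two identical copies.

.seg_new <- function(start, end, anc) {
  data.frame(start = start, end = end, anc = anc, stringsAsFactors = FALSE)
}

.seg_validate <- function(seg, L) {
  if (nrow(seg) == 0 || seg$start[1] != 0 || seg$end[nrow(seg)] != L)
    stop("ancestry segments must tile the chromosome")
  if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9))
    stop("ancestry segments must be contiguous (no gaps or overlaps)")
  invisible(seg)
}

# ancestor label at each position of `pos` (vectorized)
.seg_anc_at <- function(seg, pos) {
  seg$anc[findInterval(pos, seg$start)]
}

.seg_head <- function(seg, x) {
  keep <- seg$start < x
  out <- seg[keep, , drop = FALSE]
  out$end[nrow(out)] <- x
  out
}

.seg_tail <- function(seg, x) {
  keep <- seg$end > x
  out <- seg[keep, , drop = FALSE]
  out$start[1] <- x
  out
}

# reciprocal exchange of the tails of two chromatids at position x
.seg_crossover <- function(a, b, x) {
  list(rbind(.seg_head(a, x), .seg_tail(b, x)),
       rbind(.seg_head(b, x), .seg_tail(a, x)))
}

#' Construct a doubled-diploid parent karyotype
#'
#' A doubled diploid carries two identical copies of each of its two original
#' homologs. `homologs` supplies the two distinct homolog ancestry tracks per
#' chromosome; the four chromatids of the parent are H1, H1, H2, H2.
#'
#' @param id parent identifier.
#' @param homologs named list (by chromosome) of lists with elements `H1` and
#'   `H2`, each a data.frame with columns `start`, `end`, `anc` tiling the
#'   chromosome.
#' @param genome a [genome_spec()].
#' @param ancestors character vector of valid ancestor labels.
#' @return An object of class `parent_karyotype`.
#' @export
parent_karyotype <- function(id, homologs, genome,
                             ancestors = c("reticulata", "medica",
                                           "maxima", "trifoliata")) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!setequal(names(homologs), genome$chrom))
    stop("homologs must be supplied for every chromosome")
  for (ch in genome$chrom) {
    for (h in c("H1", "H2")) {
      seg <- homologs[[ch]][[h]]
      .seg_validate(seg, genome$length[[ch]])
      bad <- setdiff(unique(seg$anc), ancestors)
      if (length(bad))
        stop("unknown ancestor label: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(id = id, homologs = homologs, genome = genome,
                 ancestors = ancestors),
            class = "parent_karyotype")
}

#' Build the two study parent karyotypes
#'
#' The ovule parent ("volkamer", a doubled-diploid Volkamer-lemon-like
#' rootstock) is heterozygous *C. reticulata* / *C. medica* along its whole
#' genome: one homolog is fully reticulata, the other fully medica, each
#' doubled. The pollen parent ("citrumelo", a doubled-diploid
#' citrumelo-like rootstock) carries one homolog that is fully
#' *P. trifoliata* and one that is a mosaic alternating *C. reticulata* and
#' *C. maxima* segments, each doubled.
#'
#' @param genome a [genome_spec()].
#' @param citrumelo_breaks per-chromosome list of breakpoint positions (bp)
#'   at which the non-trifoliata citrumelo homolog switches between
#'   reticulata and maxima. Defaults to breaks at 40% and 80% of each
#'   chromosome. Use `numeric(0)` entries (or
#'   `citrumelo_break_fracs = numeric(0)`) for a single-ancestor homolog.
#' @param citrumelo_break_fracs fractions of chromosome length used to build
#'   default breakpoints when `citrumelo_breaks` is NULL.
#' @return list with elements `volkamer` and `citrumelo`, both
#'   [parent_karyotype()] objects.
#' @export
build_parent_karyotypes <- function(genome, citrumelo_breaks = NULL,
                                    citrumelo_break_fracs = c(0.4, 0.8)) {
  stopifnot(inherits(genome, "genome_spec"))
  vol <- cit <- list()
  for (ch in genome$chrom) {
    L <- genome$length[[ch]]
    vol[[ch]] <- list(H1 = .seg_new(0, L, "reticulata"),
                      H2 = .seg_new(0, L, "medica"))
    br <- if (is.null(citrumelo_breaks)) sort(citrumelo_break_fracs) * L
          else sort(citrumelo_breaks[[ch]])
    if (length(br) && (any(br <= 0) || any(br >= L)))
      stop("citrumelo breakpoints must lie inside the chromosome")
    bounds <- c(0, br, L)
    anc <- rep_len(c("reticulata", "maxima"), length(bounds) - 1)
    cit[[ch]] <- list(H1 = .seg_new(0, L, "trifoliata"),
                      H2 = .seg_new(bounds[-length(bounds)], bounds[-1], anc))
  }
  list(volkamer = parent_karyotype("volkamer", vol, genome),
       citrumelo = parent_karyotype("citrumelo", cit, genome))
}

#' @export
print.parent_karyotype <- function(x, ...) {
  cat("Doubled-diploid parent karyotype:", x$id, "(",
      length(x$genome$chrom), "chromosomes )\n")
  invisible(x)
}
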