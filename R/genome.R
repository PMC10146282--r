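#' Define a genome coordinate frame for simulation
#'
#' A genome specification holds the chromosome names and lengths, the
#' centromere midpoints and the expected genetic length (in Morgans) of each
#' chromosome. It is the coordinate frame on which parents, gametes, hybrids
#' and marker windows live, standing in for the nine-chromosome trifoliate
#' orange reference assembly used to anchor real data.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, > 0).
#' @param centromere numeric vector of centromere midpoints (bp), one per
#'   chromosome, each strictly inside its chromosome.
#' @param map_length numeric vector of expected genetic lengths in Morgans
#'   per chromosome (>= 0). This is the expected number of crossovers on a
#'   single transmitted chromatid.
#'
#' @return An object of class `genome_spec`.
#' @seealso [default_genome()], [centromere_table()]
#' @export
genome_spec <- function(chromosomes, centromere, map_length) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  centromere <- rep_len(as.numeric(centromere), nrow(chromosomes))
  map_length <- rep_len(as.numeric(map_length), nrow(chromosomes))
  if (any(centromere <= 0 | centromere >= chromosomes$length))
    stop("centromere midpoints must lie strictly inside their chromosome")
  if (any(map_length < 0))
    stop("map_length must be >= 0")
  structure(list(chrom = chromosomes$chrom,
                 length = stats::setNames(chromosomes$length, chromosomes$chrom),
                 centromere = stats::setNames(centromere, chromosomes$chrom),
                 map_length = stats::setNames(map_length, chromosomes$chrom)),
            class = "genome_spec")
}

#' Default nine-chromosome synthetic genome
#'
#' Chromosome lengths loosely follow the trifoliate orange assembly
#' (21-50 Mb per chromosome, ~320 Mb total), centromeres sit near
#' mid-chromosome, and genetic lengths default to 3 cM/Mb.
#'
#' @param n_chrom number of chromosomes (default 9).
#' @param lengths chromosome lengths in bp.
#' @param centromere_frac centromere position as a fraction of length.
#' @param cm_per_mb genome-wide recombination rate used to derive
#'   `map_length` (centimorgans per megabase).
#' @return A [genome_spec()] object.
#' @export
default_genome <- function(n_chrom = 9,
                           lengths = c(48, 36, 50, 27, 42, 26, 31, 27, 30)[seq_len(n_chrom)] * 1e6,
                           centromere_frac = 0.45,
                           cm_per_mb = 3) {
  lengths <- rep_len(lengths, n_chrom)
  genome_spec(
    chromosomes = data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                             length = lengths),
    centromere = lengths * centromere_frac,
    map_length = lengths / 1e6 * cm_per_mb / 100
  )
}

#' BED-like centromere interval table
#'
#' @param genome a [genome_spec()] object.
#' @param halfwidth half-width of the reported interval in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `mid`.
#' @export
centromere_table <- function(genome, halfwidth = 5e5) {
  stopifnot(inherits(genome, "genome_spec"))
  data.frame(chrom = genome$chrom,
             start = pmax(0, genome$centromere[genome$chrom] - halfwidth),
             end = pmin(genome$length[genome$chrom],
                        genome$centromere[genome$chrom] + halfwidth),
             mid = genome$centromere[genome$chrom],
             row.names = NULL)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome specification:", length(x$chrom), "chromosomes,",
      sprintf("%.1f Mb, %.0f cM expected\n",
              sum(x$length) / 1e6, 100 * sum(x$map_length)))
  invisible(x)
}
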