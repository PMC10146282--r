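# Plain-text interchange helpers: every pipeline stage reads and writes
# inspectable TSV/CSV/BED-like tables.

#' Read diploid genotypes from a VCF into an alternate-dosage matrix
#'
#' Keeps diallelic SNPs only; genotypes become alternate-allele dosages
#' (0, 1, 2; NA for missing).
#'
#' @param path VCF file.
#' @return list with `geno` (site x sample dosage matrix) and `sites`
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", v@fix[, "ALT"]) & nchar(v@fix[, "REF"]) == 1 &
    nchar(v@fix[, "ALT"]) == 1
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  list(geno = dos,
       sites = data.frame(chrom = v@fix[, "CHROM"],
                          pos = as.integer(v@fix[, "POS"]),
                          ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                          stringsAsFactors = FALSE))
}

#' Read a two-column accession-to-taxon map
#'
#' @param path TSV with columns accession, taxon (no header required).
#' @return named character vector (accession -> taxon).
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("accession", "taxon"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$taxon, tab$accession)
}

#' Read a BED-like centromere interval table
#'
#' @param path tab-separated chrom/start/end file (BED-like, no header).
#' @return data.frame with `chrom`, `start`, `end`, `mid`.
#' @export
read_centromeres <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end"),
                           stringsAsFactors = FALSE)
  tab$mid <- (tab$start + tab$end) / 2
  tab
}

#' Read a phenotype CSV (id column plus numeric trait columns)
#'
#' @param path CSV file with a header.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a dose matrix as TSV (individuals x windows)
#'
#' @param dm a `dose_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dose_matrix <- function(dm, path) {
  out <- data.frame(id = rownames(dm$dose), dm$dose, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dose matrix written by [write_dose_matrix()]
#'
#' @param path TSV file.
#' @param windows window table matching the matrix columns.
#' @param ploidy,ancestor,parent see [dose_matrix()].
#' @return a `dose_matrix`.
#' @export
read_dose_matrix <- function(path, windows, ploidy, ancestor = NA, parent = NA) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  windows <- windows[match(colnames(m), windows$window), , drop = FALSE]
  dose_matrix(m, windows, ploidy, ancestor, parent)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
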