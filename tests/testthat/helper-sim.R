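# small fixtures built in code

tiny_genome <- function(n_chrom = 1, length_bp = 3e7, morgans = 1,
                        centromere_frac = 0.5) {
  genome_spec(
    chromosomes = data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                             length = rep(length_bp, n_chrom)),
    centromere = rep(length_bp * centromere_frac, n_chrom),
    map_length = rep(morgans, n_chrom))
}

tiny_parents <- function(genome = tiny_genome()) {
  build_parent_karyotypes(genome)
}

# dose matrix straight from a plain matrix, one chromosome, unit spacing
dm_from_matrix <- function(m, chrom = "chr1", ploidy = 2) {
  nw <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("w%03d", seq_len(nw))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  w <- data.frame(window = colnames(m),
                  chrom = rep_len(chrom, nw),
                  pos = ave(seq_len(nw), rep_len(chrom, nw), FUN = seq_along) * 1e6,
                  stringsAsFactors = FALSE)
  dose_matrix(m, w, ploidy = ploidy, ancestor = "A1")
}

# reference genotype fixture: 4 taxa x 2 accessions, planted diagnostics
tiny_reference <- function() {
  taxa <- rep(c("A", "B", "C", "D"), each = 2)
  names(taxa) <- paste0(taxa, 1:2)
  sites <- data.frame(chrom = "chr1", pos = 1:6 * 1000)
  geno <- rbind(
    c(2, 2, 0, 0, 0, 0, 0, 0),  # diagnostic for A
    c(0, 0, 2, 2, 0, 0, 0, 0),  # diagnostic for B
    c(2, 1, 0, 0, 0, 0, 0, 0),  # polymorphic within A -> not diagnostic
    c(1, 1, 1, 1, 1, 1, 1, 1),  # shared heterozygosity
    c(2, 2, 2, 2, 0, 0, 0, 0),  # fixed in two taxa -> not one-vs-rest
    c(0, 0, 0, 0, 0, 0, 2, 2))  # diagnostic for D
  colnames(geno) <- names(taxa)
  list(geno = geno, taxa = taxa, sites = sites)
}
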