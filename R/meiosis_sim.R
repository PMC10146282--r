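#' Simulate bivalent meiosis of a doubled-diploid parent
#'
#' Each chromosome of a doubled diploid exists as two identical copies of
#' homolog H1 and two of H2. Per meiosis and chromosome, a pairing
#' configuration is drawn: homologous bivalents (H1-H1 and H2-H2) with
#' probability `1 - 2*tau/3`, or one of the two heterologous configurations
#' (both bivalents H1-H2) each with probability `tau/3`. This mapping
#' reproduces the centromeric diploid-gamete class frequencies
#' `(tau/6, tau/6, 1 - tau/3)` for the two homozygous and the heterozygous
#' class of a duplex locus. Crossover counts per bivalent are Poisson with
#' mean twice the chromosome's genetic length in Morgans (so a transmitted
#' chromatid carries the configured map length on average), crossover
#' positions are uniform, each crossover picks one random chromatid of each
#' pairing partner (no chromatid interference), and the gamete receives one
#' random chromatid from each of the two bivalents. Double reduction is
#' structurally impossible: only bivalents are formed.
#'
#' @param parent a [parent_karyotype()].
#' @param n number of gametes to draw (>= 1).
#' @param tau tetrasomic parameter in \[0, 1\] (`tau = 1 - PP`); scalar or one
#'   value per chromosome (recycled, in genome chromosome order).
#' @param xo_mean optional override of the Poisson crossover mean per
#'   bivalent; default `2 * map_length` from the genome spec. Scalar or per
#'   chromosome.
#' @param seed optional integer seed (set once before drawing).
#' @return list of gametes; each gamete is a list with `id` and, per
#'   chromosome, the two chromatid ancestry tracks, the pairing
#'   `config` (`"homologous"` or `"heterologous"`) and the crossover
#'   positions of its bivalents. Class `gamete_set`.
#' @export
simulate_meiosis <- function(parent, n, tau, xo_mean = NULL, seed = NULL) {
  stopifnot(inherits(parent, "parent_karyotype"), n >= 1)
  genome <- parent$genome
  nc <- length(genome$chrom)
  tau <- rep_len(as.numeric(tau), nc)
  if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]")
  if (is.null(xo_mean)) xo_mean <- 2 * genome$map_length[genome$chrom]
  xo_mean <- rep_len(as.numeric(xo_mean), nc)
  if (!is.null(seed)) set.seed(seed)

  # pre-draw the per-gamete, per-chromosome randomness in bulk
  cfg <- matrix(stats::runif(n * nc) < rep(2 * tau / 3, each = n), n, nc)
  ncx <- matrix(stats::rpois(2L * n * nc, rep(xo_mean, each = 2L * n)),
                2L * n, nc)

  gametes <- vector("list", n)
  for (g in seq_len(n)) {
    chroms <- vector("list", nc)
    names(chroms) <- genome$chrom
    for (k in seq_len(nc)) {
      ch <- genome$chrom[k]
      L <- genome$length[[ch]]
      H1 <- parent$homologs[[ch]]$H1
      H2 <- parent$homologs[[ch]]$H2
      het <- cfg[g, k]
      # bivalents as pairs of homolog sequences
      biv <- if (het) list(list(H1, H2), list(H1, H2))
             else list(list(H1, H1), list(H2, H2))
      picked <- vector("list", 2L)
      xo_all <- numeric(0)
      for (b in 1:2) {
        m <- ncx[2L * (g - 1L) + b, k]
        chromatids <- list(biv[[b]][[1]], biv[[b]][[1]],
                           biv[[b]][[2]], biv[[b]][[2]])
        if (m > 0) {
          pos <- sort(stats::runif(m, 0, L))
          xo_all <- c(xo_all, pos)
          for (x in pos) {
            i <- sample.int(2L, 1L)        # chromatid of first partner
            j <- sample.int(2L, 1L) + 2L   # chromatid of second partner
            sw <- .seg_crossover(chromatids[[i]], chromatids[[j]], x)
            chromatids[[i]] <- sw[[1]]
            chromatids[[j]] <- sw[[2]]
          }
        }
        picked[[b]] <- chromatids[[sample.int(4L, 1L)]]
      }
      chroms[[k]] <- list(chromatids = picked,
                          config = if (het) "heterologous" else "homologous",
                          xo = xo_all)
    }
    gametes[[g]] <- list(id = sprintf("g%05d", g), chrom = chroms)
  }
  structure(gametes, class = "gamete_set", parent = parent$id)
}

#' Ancestral dose of gametes at given positions
#'
#' Counts, for each gamete and query position, how many of the two chromatids
#' carry the tracked ancestor (0, 1 or 2).
#'
#' @param gametes a `gamete_set` from [simulate_meiosis()].
#' @param ancestor ancestor label to count.
#' @param windows data.frame with columns `window`, `chrom`, `pos` (see
#'   [make_windows()] or [window_partition()]).
#' @return A `dose_matrix` (ploidy 2): gametes x windows.
#' @export
gamete_doses <- function(gametes, ancestor, windows) {
  stopifnot(inherits(gametes, "gamete_set"))
  windows <- .check_windows(windows)
  m <- matrix(NA_integer_, length(gametes), nrow(windows),
              dimnames = list(vapply(gametes, `[[`, "", "id"),
                              windows$window))
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    pos <- windows$pos[sel]
    for (g in seq_along(gametes)) {
      trk <- gametes[[g]]$chrom[[ch]]$chromatids
      m[g, sel] <- (.seg_anc_at(trk[[1]], pos) == ancestor) +
                   (.seg_anc_at(trk[[2]], pos) == ancestor)
    }
  }
  dose_matrix(m, windows, ploidy = 2, ancestor = ancestor)
}

#' Pairing configuration drawn for each gamete and chromosome
#'
#' @param gametes a `gamete_set`.
#' @return character matrix gametes x chromosomes.
#' @export
pairing_configs <- function(gametes) {
  stopifnot(inherits(gametes, "gamete_set"))
  chroms <- names(gametes[[1]]$chrom)
  t(vapply(gametes,
           function(g) vapply(g$chrom, `[[`, "", "config"),
           character(length(chroms))))
}

#' Unite ovules and pollens into tetraploid hybrids
#'
#' Each hybrid is the union of one diploid ovule and one diploid pollen;
#' ancestral doses add (ovule dose + pollen dose).
#'
#' @param ovules,pollens `gamete_set` objects of equal length, or lists to be
#'   paired by position after optional resampling.
#' @param n optional number of hybrids; when given, ovules and pollens are
#'   sampled with replacement.
#' @param seed optional integer seed (used only when sampling).
#' @return list of hybrids (class `hybrid_set`), each with `id`, `ovule`,
#'   `pollen`.
#' @export
form_hybrids <- function(ovules, pollens, n = NULL, seed = NULL) {
  if (length(ovules) == 0 || length(pollens) == 0)
    stop("empty gamete lists")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) {
    if (length(ovules) != length(pollens))
      stop("ovule and pollen lists differ in length; supply n to sample")
    io <- seq_along(ovules); ip <- seq_along(pollens)
  } else {
    io <- sample.int(length(ovules), n, replace = TRUE)
    ip <- sample.int(length(pollens), n, replace = TRUE)
  }
  hybrids <- vector("list", length(io))
  for (h in seq_along(io)) {
    hybrids[[h]] <- list(id = sprintf("hyb%04d", h),
                         ovule = ovules[[io[h]]],
                         pollen = pollens[[ip[h]]])
  }
  structure(hybrids, class = "hybrid_set")
}

#' Ancestral dose of tetraploid hybrids at given positions
#'
#' @param hybrids a `hybrid_set` from [form_hybrids()].
#' @inheritParams gamete_doses
#' @return A `dose_matrix` (ploidy 4): hybrids x windows.
#' @export
hybrid_doses <- function(hybrids, ancestor, windows) {
  stopifnot(inherits(hybrids, "hybrid_set"))
  windows <- .check_windows(windows)
  m <- matrix(NA_integer_, length(hybrids), nrow(windows),
              dimnames = list(vapply(hybrids, `[[`, "", "id"),
                              windows$window))
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    pos <- windows$pos[sel]
    for (h in seq_along(hybrids)) {
      trk <- c(hybrids[[h]]$ovule$chrom[[ch]]$chromatids,
               hybrids[[h]]$pollen$chrom[[ch]]$chromatids)
      d <- integer(sum(sel))
      for (t in trk) d <- d + (.seg_anc_at(t, pos) == ancestor)
      m[h, sel] <- d
    }
  }
  dose_matrix(m, windows, ploidy = 4, ancestor = ancestor)
}

#' Draw marginal gamete classes at independent duplex loci
#'
#' Fast sampler of the per-locus diploid gamete classes of a duplex marker
#' under the bivalent model: doses 0 and 2 each with probability `tau/6`,
#' dose 1 with probability `1 - tau/3`, independently across windows.
#' Useful for null-distribution studies where inter-window linkage is not
#' wanted.
#'
#' @param n_gametes,n_windows matrix dimensions.
#' @param tau tetrasomic parameter in \[0, 1\].
#' @param seed optional integer seed.
#' @param windows optional windows data.frame; defaults to `n_windows`
#'   synthetic windows on one chromosome.
#' @return A `dose_matrix` (ploidy 2).
#' @export
simulate_gamete_classes <- function(n_gametes, n_windows, tau, seed = NULL,
                                    windows = NULL) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- tetrasomic_probs(tau)
  m <- matrix(sample(c(2L, 0L, 1L), n_gametes * n_windows, replace = TRUE,
                     prob = p),
              n_gametes, n_windows,
              dimnames = list(sprintf("g%05d", seq_len(n_gametes)), NULL))
  if (is.null(windows))
    windows <- data.frame(window = sprintf("w%04d", seq_len(n_windows)),
                          chrom = rep("chr1", n_windows),
                          pos = seq_len(n_windows) * 1e6,
                          stringsAsFactors = FALSE)
  colnames(m) <- windows$window
  dose_matrix(m, windows, ploidy = 2, ancestor = "A1")
}

#' Evenly spaced marker windows for direct simulation
#'
#' Builds a window table without going through diagnostic-SNP mining:
#' `per_chrom` representative positions evenly spaced along each chromosome.
#'
#' @param genome a [genome_spec()].
#' @param per_chrom windows per chromosome.
#' @param ancestor label stored in the table.
#' @return data.frame with columns `window`, `chrom`, `ancestor`, `start`,
#'   `end`, `pos`, `n_snp`.
#' @export
make_windows <- function(genome, per_chrom, ancestor = "A1") {
  stopifnot(inherits(genome, "genome_spec"))
  out <- do.call(rbind, lapply(genome$chrom, function(ch) {
    L <- genome$length[[ch]]
    pos <- L * (seq_len(per_chrom) - 0.5) / per_chrom
    data.frame(window = sprintf("%s_%s_w%03d", ancestor, ch, seq_len(per_chrom)),
               chrom = ch, ancestor = ancestor,
               start = pos - L / (2 * per_chrom),
               end = pos + L / (2 * per_chrom),
               pos = pos, n_snp = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.check_windows <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("window", "chrom", "pos") %in% names(windows)))
  windows
}
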