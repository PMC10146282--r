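test_that("parent karyotypes match the study design", {
  g <- tiny_genome(n_chrom = 2)
  p <- build_parent_karyotypes(g)
  for (ch in g$chrom) {
    expect_identical(unique(p$volkamer$homologs[[ch]]$H1$anc), "reticulata")
    expect_identical(unique(p$volkamer$homologs[[ch]]$H2$anc), "medica")
    expect_identical(unique(p$citrumelo$homologs[[ch]]$H1$anc), "trifoliata")
    expect_setequal(unique(p$citrumelo$homologs[[ch]]$H2$anc),
                    c("reticulata", "maxima"))
  }
  # trifoliata dose of the citrumelo parent is 2 everywhere (doubled F1)
  w <- make_windows(g, 4, "trifoliata")
  gam <- simulate_meiosis(p$citrumelo, 5, tau = 0.5, seed = 1)
  hyb <- form_hybrids(gam, gam)
  expect_true(all(hybrid_doses(hyb, "trifoliata", w)$dose %in% 0:4))

  # zero alternation breakpoints -> single-ancestor second homolog
  p0 <- build_parent_karyotypes(g, citrumelo_break_fracs = numeric(0))
  for (ch in g$chrom)
    expect_length(unique(p0$citrumelo$homologs[[ch]]$H2$anc), 1L)

  expect_error(build_parent_karyotypes(g, citrumelo_breaks =
    stats::setNames(rep(list(5e7), 2), g$chrom)), "inside")
})

test_that("tau = 0 meiosis transmits full heterozygosity", {
  p <- tiny_parents()
  gam <- simulate_meiosis(p$volkamer, 40, tau = 0, seed = 3)
  d <- gamete_doses(gam, "medica", make_windows(p$volkamer$genome, 6, "medica"))
  expect_true(all(d$dose == 1))
})

test_that("tau = 1 centromeric gamete classes follow (1/6, 1/6, 4/6)", {
  p <- tiny_parents()
  n <- 6000
  gam <- simulate_meiosis(p$volkamer, n, tau = 1, xo_mean = 0, seed = 11)
  w <- data.frame(window = "cen", chrom = "chr1", pos = 1.5e7)
  d <- gamete_doses(gam, "medica", w)$dose[, 1]
  freq <- c(mean(d == 2), mean(d == 0), mean(d == 1))
  expt <- c(1 / 6, 1 / 6, 4 / 6)
  sd3 <- 3 * sqrt(expt * (1 - expt) / n)
  expect_true(all(abs(freq - expt) < sd3))
})

test_that("meiosis is deterministic under a fixed seed", {
  p <- tiny_parents()
  g1 <- simulate_meiosis(p$citrumelo, 8, tau = 0.4, seed = 99)
  g2 <- simulate_meiosis(p$citrumelo, 8, tau = 0.4, seed = 99)
  expect_identical(g1, g2)
  expect_error(simulate_meiosis(p$citrumelo, 8, tau = 1.2), "tau")
})

test_that("expected gamete heterozygosity is 1 - tau/3 across tau", {
  p <- tiny_parents()
  w <- data.frame(window = "cen", chrom = "chr1", pos = 1.5e7)
  n <- 4000
  for (tau in c(0, 0.3, 0.6, 1)) {
    gam <- simulate_meiosis(p$volkamer, n, tau = tau, seed = 1000 + tau * 10)
    het <- mean(gamete_doses(gam, "medica", w)$dose == 1)
    expt <- 1 - tau / 3
    expect_lt(abs(het - expt), 3 * sqrt(expt * (1 - expt) / n) + 1e-12)
  }
})

test_that("hybrid doses are the sum of gamete doses", {
  p <- tiny_parents()
  w <- make_windows(p$volkamer$genome, 5, "medica")
  ov <- simulate_meiosis(p$volkamer, 15, tau = 0.5, seed = 5)
  po <- simulate_meiosis(p$citrumelo, 15, tau = 0.3, seed = 6)
  hy <- form_hybrids(ov, po)
  expect_length(hy, 15)
  dh <- hybrid_doses(hy, "medica", w)$dose
  dov <- gamete_doses(ov, "medica", w)$dose
  dpo <- gamete_doses(po, "medica", w)$dose
  expect_true(all(dpo == 0))  # pollen parent carries no medica
  expect_equal(unname(dh), unname(dov + dpo))
  # trifoliata arrives only through the pollen
  wt <- make_windows(p$volkamer$genome, 5, "trifoliata")
  expect_equal(unname(hybrid_doses(hy, "trifoliata", wt)$dose),
               unname(gamete_doses(po, "trifoliata", wt)$dose))
  expect_error(form_hybrids(list(), po), "empty")
})

test_that("read-count generator follows the binomial dose model", {
  p <- tiny_parents()
  ov <- simulate_meiosis(p$volkamer, 2, tau = 0, seed = 2)
  ov2 <- simulate_meiosis(p$volkamer, 2, tau = 0, seed = 3)
  hy <- form_hybrids(ov, ov2)  # selfed-like union: medica dose 1 + 1 = 2
  panel <- data.frame(chrom = "chr1", pos = seq(1e6, 2.9e7, length.out = 500),
                      taxon = "medica", stringsAsFactors = FALSE)

  # true medica dose is 2 (duplex) everywhere; with error 0.01 and high
  # depth the diagnostic fraction concentrates at 0.5
  cnt <- simulate_read_counts(hy, panel, depth = 1000, error = 0.01,
                              missing = 0, seed = 4)
  frac <- cnt$diag_reads / cnt$tot_reads
  expect_lt(abs(mean(frac) - 0.5), 3 * sqrt(0.25 / (1000 * nrow(cnt))) + 1e-3)

  # missing sites come back with zero total reads
  cntm <- simulate_read_counts(hy, panel, depth = 50, error = 0.01,
                               missing = 0.3, seed = 6)
  expect_gt(mean(cntm$tot_reads == 0), 0.2)
})

test_that("degenerate read-count cases are exact", {
  p <- tiny_parents()
  panel <- data.frame(chrom = "chr1", pos = c(1e6, 2e6), taxon = "trifoliata")
  # heterologous pairing can transmit two trifoliata chromatids; pick such
  # gametes so the hybrid reaches trifoliata dose 4
  po <- simulate_meiosis(p$citrumelo, 60, tau = 1, xo_mean = 0, seed = 7)
  d <- gamete_doses(po, "trifoliata",
                    data.frame(window = "w", chrom = "chr1", pos = 1.5e6))
  duplex <- which(d$dose[, 1] == 2)[1:3]
  hy <- form_hybrids(po[duplex], po[duplex])
  class(hy) <- "hybrid_set"
  cnt <- simulate_read_counts(hy, panel, depth = 40, error = 0, missing = 0,
                              seed = 8)
  expect_identical(cnt$diag_reads, cnt$tot_reads)

  ov <- simulate_meiosis(p$volkamer, 3, tau = 0, seed = 9)
  hy0 <- form_hybrids(ov, ov)  # no trifoliata at all
  cnt0 <- simulate_read_counts(hy0, panel, depth = 40, error = 0, missing = 0,
                               seed = 10)
  expect_true(all(cnt0$diag_reads == 0))

  expect_error(simulate_read_counts(hy0, panel, error = 0.7), "error")
  expect_error(simulate_read_counts(hy0, transform(panel, chrom = "chrX")),
               "chromosomes")
})

test_that("phenotype simulation is additive and reproducible", {
  m <- matrix(c(0, 1, 2, 1, 1, 1), 3, 2)
  dm <- dm_from_matrix(m)
  qtl <- data.frame(trait = "t1", window = "w001", beta = 1)
  ph <- simulate_phenotypes(dm, qtl, intercept = 5, sd = 0, seed = 1)
  expect_equal(ph$t1, 5 + m[, 1])
  # beta = 0, sd = 0 -> intercept only
  ph0 <- simulate_phenotypes(dm, transform(qtl, beta = 0), intercept = 2,
                             sd = 0, seed = 1)
  expect_equal(ph0$t1, rep(2, 3))
  # reproducibility
  a <- simulate_phenotypes(dm, qtl, sd = 1, seed = 42)
  b <- simulate_phenotypes(dm, qtl, sd = 1, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_phenotypes(dm, transform(qtl, window = "nope")),
               "unknown QTL window")
})

test_that("marginal class sampler matches tetrasomic expectations", {
  d <- simulate_gamete_classes(5000, 4, tau = 0.6, seed = 13)
  expect_s3_class(d, "dose_matrix")
  freq <- mean(d$dose == 1)
  expect_lt(abs(freq - 0.8), 3 * sqrt(0.8 * 0.2 / (5000 * 4)))
  expect_true(all(tetrasomic_probs(0.37) > 0))
  for (tau in seq(0, 1, by = 0.1))
    expect_equal(sum(tetrasomic_probs(tau)), 1)
})
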