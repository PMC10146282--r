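test_that("tetrasomic class probabilities hit the printed anchor points", {
  expect_equal(unname(tetrasomic_probs(1)), c(1 / 6, 1 / 6, 4 / 6))
  expect_identical(tetrasomic_probs(1)[["A1A2"]], 2 / 3)
  expect_equal(unname(tetrasomic_probs(0)), c(0, 0, 1))
  expect_equal(unname(tetrasomic_probs(0.6)), c(0.1, 0.1, 0.8))
  expect_error(tetrasomic_probs(-0.1), "tau")
  expect_error(tetrasomic_probs(1.1), "tau")
})

test_that("grid-search tau agrees with the closed form", {
  # closed form: tau_hat = min(1, 3*(x1+x2)/N)
  expect_equal(estimate_tau(0, 0, 96)$tau, 0)
  expect_equal(estimate_tau(0, 0, 96)$pp, 1)
  expect_equal(estimate_tau(10, 10, 80)$tau, 0.6)
  expect_equal(estimate_tau(10, 10, 80)$pp, 0.4)
  expect_equal(estimate_tau(20, 20, 60)$tau, 1)  # 1.2 clipped to the grid end
  # asymmetric counts and a coarse spot-check sweep
  for (s in c(1, 7, 33)) {
    for (x3 in c(5, 50, 95)) {
      closed <- min(1, 3 * s / (s + x3))
      expect_lt(abs(estimate_tau(s, 0, x3)$tau - closed), 0.005 + 1e-9)
    }
  }
  expect_error(estimate_tau(0, 0, 0), "at least one")
})

test_that("PHR counts heterozygous gametes among non-missing calls", {
  m <- rbind(c(1, 0, NA), c(1, 1, NA), c(1, 2, NA),
             c(1, 1, 1), c(0, 1, NA), c(2, 1, NA),
             c(1, 1, NA), c(1, 1, NA), c(1, 1, NA), c(1, 1, NA))
  dm <- dm_from_matrix(m)
  v <- phr(dm)
  expect_equal(unname(v[1]), 0.8)   # counts (1,8,1) over doses (0,1,2)
  expect_equal(unname(v[2]), 0.8)
  expect_equal(unname(v[3]), 1.0)   # only one non-missing call, dose 1
  expect_true(is.na(phr(dm_from_matrix(matrix(NA_real_, 3, 1)))))
})

test_that("chromosome PP averages the three centromeric markers", {
  # build a 5-window chromosome whose class counts are exact multinomial
  # expectations for tau = 0.6, so each marker estimate equals 0.6
  n <- 100
  col <- c(rep(2, 10), rep(0, 10), rep(1, 80))
  m <- matrix(rep(col, 5), n, 5)
  dm <- dm_from_matrix(m)
  cen <- data.frame(chrom = "chr1", mid = 3e6)
  out <- pp_per_chromosome(dm, cen)
  expect_equal(nrow(out$markers), 3)
  expect_equal(out$markers$window, c("w002", "w003", "w004"))
  expect_equal(out$chromosomes$pp, 0.4)
  expect_equal(out$chromosomes$tau, 0.6)
  expect_error(pp_per_chromosome(dm_from_matrix(m[, 1:2]), cen), "fewer than 3")
  expect_error(pp_per_chromosome(dm, data.frame(chrom = "chrX", mid = 1)),
               "centromere")
})

test_that("PP recovery from simulated gametes is unbiased at tau 0 and 1", {
  g <- tiny_genome()
  p <- tiny_parents(g)
  w <- make_windows(g, 7, "medica")
  cen <- centromere_table(g)
  gam0 <- simulate_meiosis(p$volkamer, 300, tau = 0, seed = 91)
  fit0 <- pp_per_chromosome(gamete_doses(gam0, "medica", w), cen)
  expect_equal(fit0$chromosomes$pp, 1)

  gam1 <- simulate_meiosis(p$volkamer, 800, tau = 1, seed = 92)
  fit1 <- pp_per_chromosome(gamete_doses(gam1, "medica", w), cen)
  expect_lt(fit1$chromosomes$pp, 0.12)
})

test_that("tetrasomic deviation chi-square matches closed forms and chisq.test", {
  # exact expectation -> statistic 0, p = 1
  m16 <- c(rep(2, 16), rep(0, 16), rep(1, 64))
  dm <- dm_from_matrix(cbind(m16))
  scan <- tetrasomic_deviation_scan(dm)
  expect_equal(scan$chi2, 0)
  expect_equal(scan$p, 1)
  expect_false(scan$significant)

  # all-heterozygous window: chi2 = 16 + 16 + 16 = 48
  dm2 <- dm_from_matrix(cbind(rep(1, 96)))
  scan2 <- tetrasomic_deviation_scan(dm2)
  expect_equal(scan2$chi2, 48)
  expect_equal(scan2$p, pchisq(48, 2, lower.tail = FALSE))
  expect_lt(scan2$p, 1e-10)

  # independent route: stats::chisq.test on random count triples
  set.seed(101)
  for (i in 1:5) {
    counts <- as.vector(rmultinom(1, 90, c(0.25, 0.15, 0.6)))
    col <- c(rep(2, counts[1]), rep(0, counts[2]), rep(1, counts[3]))
    sc <- tetrasomic_deviation_scan(dm_from_matrix(cbind(col)))
    ct <- suppressWarnings(chisq.test(counts, p = c(1 / 6, 1 / 6, 4 / 6)))
    expect_equal(sc$chi2, unname(ct$statistic))
    expect_equal(sc$p, unname(ct$p.value))
  }
})

test_that("q-values are monotone in p and ordering-invariant", {
  set.seed(111)
  dm <- simulate_gamete_classes(60, 40, tau = 0.7)
  scan <- tetrasomic_deviation_scan(dm)
  ord <- order(scan$p)
  expect_true(all(diff(scan$q[ord]) >= -1e-12))
  expect_true(all(scan$q >= scan$p - 1e-12))
  # shuffling the windows changes nothing about which are significant
  shuf <- sample(ncol(dm$dose))
  dm2 <- dose_matrix(dm$dose[, shuf], dm$windows[shuf, ], 2, "A1")
  scan2 <- tetrasomic_deviation_scan(dm2)
  expect_setequal(scan$window[scan$significant], scan2$window[scan2$significant])
  # Storey q-values never exceed BH q-values (pi0 <= 1)
  scan3 <- tetrasomic_deviation_scan(dm, q_method = "storey")
  expect_true(all(scan3$q <= scan$q + 1e-12))
})

test_that("the meiosis_fit object carries coherent summaries and methods", {
  set.seed(121)
  g <- tiny_genome(n_chrom = 2)
  p <- tiny_parents(g)
  gam <- simulate_meiosis(p$volkamer, 80, tau = c(0.2, 1), seed = 122)
  dm <- gamete_doses(gam, "medica", make_windows(g, 6, "medica"))
  fit <- meiosis_fit(dm, centromere_table(g))
  expect_s3_class(fit, "meiosis_fit")
  expect_named(coef(fit), c("chr1", "chr2"))
  # the disomic chromosome restores more heterozygosity than the tetrasomic
  expect_gt(fit$chromosomes$phr[1], fit$chromosomes$phr[2])
  expect_gt(coef(fit)[["chr1"]], coef(fit)[["chr2"]])
  expect_output(print(fit), "Meiotic behavior fit")
  expect_output(print(summary(fit)), "Per-chromosome")
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(fit$windows), 3L))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$x1 + sims[[1]]$x2 + sims[[1]]$x3, fit$windows$n)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("centromeric PHR and PP obey E[PHR] = 1 - (1 - PP)/3", {
  g <- tiny_genome()
  p <- tiny_parents(g)
  cen <- centromere_table(g)
  w <- make_windows(g, 7, "medica")
  n <- 1500
  for (tau in c(0.25, 0.75)) {
    gam <- simulate_meiosis(p$volkamer, n, tau = tau, seed = 131 + tau * 4)
    dm <- gamete_doses(gam, "medica", w)
    est <- pp_per_chromosome(dm, cen)
    mk <- est$markers$window
    expt <- 1 - tau / 3
    obs <- mean(phr(dm)[mk])
    expect_lt(abs(obs - expt), 3 * sqrt(expt * (1 - expt) / n))
  }
})
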