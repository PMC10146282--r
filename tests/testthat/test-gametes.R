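test_that("gamete inference copies doses and flags impossible cells", {
  m <- matrix(c(0, 1, 2, 3, 4, 1), 2, 3)
  dm <- dose_matrix(m, data.frame(window = c("w1", "w2", "w3"),
                                  chrom = "chr1", pos = 1:3 * 1e6),
                    ploidy = 4, ancestor = "medica")
  gam <- infer_gametes(dm, "ovule")
  expect_equal(gam$ploidy, 2)
  expect_equal(unname(gam$dose[1, 1]), 0)
  expect_equal(unname(gam$dose[2, 1]), 1)
  expect_equal(unname(gam$dose[1, 2]), 2)
  expect_true(is.na(gam$dose[2, 2]))  # dose 3 impossible under the design
  expect_true(is.na(gam$dose[1, 3]))  # dose 4 impossible
  expect_equal(attr(gam, "n_inconsistent"), 2L)
})

test_that("singleton cleaning follows the agreeing-flanks rule", {
  rows <- rbind(c(1, 1, 0, 1, 1),   # classic singleton
                c(1, 0, 0, 1, 1),   # run of two: untouched
                c(0, 2, 1, 0, 2),   # all flanks disagree: untouched
                c(1, 1, 2, 1, 1))   # another singleton
  dm <- dm_from_matrix(rows)
  out <- remove_singletons(dm)
  expect_true(is.na(out$dose[1, 3]))
  expect_equal(out$dose[2, ], dm$dose[2, ])
  expect_equal(out$dose[3, ], dm$dose[3, ])
  expect_true(is.na(out$dose[4, 3]))
  expect_equal(attr(out, "n_singletons"), 2L)

  # disagreeing flanks leave the middle call alone
  dm2 <- dm_from_matrix(rbind(c(0, 1, 2)))
  expect_equal(remove_singletons(dm2)$dose, dm2$dose)

  # chromosome ends are never treated as singletons
  dm3 <- dm_from_matrix(rbind(c(0, 1, 1, 1, 2)))
  expect_equal(remove_singletons(dm3)$dose, dm3$dose)

  # nearest non-missing flanks are used across gaps
  dm4 <- dm_from_matrix(rbind(c(1, NA, 0, NA, 1)))
  expect_true(is.na(remove_singletons(dm4)$dose[1, 3]))
})

test_that("missing-data filters drop windows first, then individuals", {
  m <- matrix(1, 10, 6)
  m[1:3, 1] <- NA          # window 1: 30% missing -> dropped
  m[10, 2:6] <- NA         # individual 10: 100% missing after window drop
  dm <- dm_from_matrix(m)
  out <- filter_dose_matrix(dm)
  expect_equal(ncol(out$dose), 5)
  expect_equal(nrow(out$dose), 9)
  expect_identical(attr(out, "windows_dropped"), "w001")
  expect_identical(attr(out, "individuals_dropped"), "g010")

  # 10% individual missingness is retained under the 20% threshold
  m2 <- matrix(1, 10, 10); m2[1, 1] <- NA
  expect_equal(dim(filter_dose_matrix(dm_from_matrix(m2))$dose), c(10, 10))

  # a clean matrix passes through unchanged
  m3 <- matrix(rep(0:2, length.out = 60), 6, 10)
  expect_equal(filter_dose_matrix(dm_from_matrix(m3))$dose,
               dm_from_matrix(m3)$dose)
})

test_that("aberrant-recombination individuals are removed robustly", {
  set.seed(61)
  n <- 30; nw <- 40
  # smooth gametes: a single dose switch along the chromosome
  m <- t(vapply(seq_len(n), function(i) {
    sw <- sample(nw, 1)
    c(rep(1, sw), rep(2, nw - sw))[seq_len(nw)]
  }, numeric(nw)))
  dm <- dm_from_matrix(m)
  out0 <- drop_aberrant_individuals(dm)
  expect_equal(nrow(out0$dose), n)  # all transition counts identical-ish

  # an individual with shuffled windows has a wildly inflated count
  m2 <- m; m2[5, ] <- sample(m[5, ])
  out <- drop_aberrant_individuals(dm_from_matrix(m2))
  expect_true("g005" %in% attr(out, "individuals_dropped"))
  expect_false("g001" %in% attr(out, "individuals_dropped"))

  expect_error(drop_aberrant_individuals(dm_from_matrix(m[1:5, ])),
               "at least 10")
})

test_that("identical transition counts remove nobody", {
  m <- matrix(rep(c(1, 1, 2, 2), 12), 12, 4, byrow = TRUE)
  out <- drop_aberrant_individuals(dm_from_matrix(m))
  expect_equal(nrow(out$dose), 12)
})

test_that("cleaning never invents calls and only adds missingness", {
  set.seed(71)
  m <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                     prob = c(0.1, 0.7, 0.15, 0.05)), 10, 20)
  dm <- dm_from_matrix(m)
  out <- remove_singletons(dm)
  was_na <- is.na(dm$dose)
  expect_true(all(is.na(out$dose)[was_na]))
  same <- !is.na(out$dose)
  expect_true(all(out$dose[same] == dm$dose[same]))
})

test_that("gamete inference inverts hybrid formation on noiseless truth", {
  g <- tiny_genome(n_chrom = 2)
  p <- tiny_parents(g)
  ov <- simulate_meiosis(p$volkamer, 25, tau = 0.5, seed = 81)
  po <- simulate_meiosis(p$citrumelo, 25, tau = 0.3, seed = 82)
  hy <- form_hybrids(ov, po)
  w <- make_windows(g, 8, "medica")
  hyb_dm <- hybrid_doses(hy, "medica", w)
  gam <- infer_gametes(hyb_dm, "ovule")
  expect_equal(unname(gam$dose), unname(gamete_doses(ov, "medica", w)$dose))
  expect_equal(attr(gam, "n_inconsistent"), 0L)
})
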