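test_that("Kosambi mapping function matches closed-form values", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambi_cm(0.1), 2), 10.14)
  expect_equal(round(kosambi_cm(0.25), 2), 27.47)
  expect_error(kosambi_cm(0.5), "0.5")
  # strictly increasing and at least as large as the recombination percent
  r <- seq(0, 0.49, by = 0.01)
  cm <- kosambi_cm(r)
  expect_true(all(diff(cm) > 0))
  expect_true(all(cm >= 100 * r - 1e-9))
  # convexity on the interior grid
  expect_true(all(diff(cm, differences = 2) > -1e-9))
})

test_that("dose rf counts apparent ancestry changes", {
  m <- matrix(1, 50, 2)
  dm <- dm_from_matrix(m)
  expect_equal(pairwise_rf(dm, 1, 2, method = "dose"), 0)
  m2 <- m; m2[7, 2] <- 0
  expect_equal(pairwise_rf(dm_from_matrix(m2), 1, 2, method = "dose"), 0.01)
  # insufficient overlap -> NA
  m3 <- m; m3[1:45, 1] <- NA
  expect_true(is.na(pairwise_rf(dm_from_matrix(m3), 1, 2, method = "dose")))
})

test_that("correlation rf saturates at 0.5 for unlinked windows", {
  set.seed(141)
  g2 <- tiny_genome(n_chrom = 2)
  p <- tiny_parents(g2)
  gam <- simulate_meiosis(p$volkamer, 400, tau = 1, seed = 142)
  w <- make_windows(g2, 1, "medica")  # one window per chromosome
  dm <- gamete_doses(gam, "medica", w)
  r <- pairwise_rf(dm, 1, 2, method = "cor")
  expect_gt(r, 0.4)  # ~0.5 up to sampling noise
  # identical columns are fully linked under both estimators
  dm2 <- dm_from_matrix(matrix(rep(c(0, 1, 1, 2), 10), 40, 2))
  expect_equal(pairwise_rf(dm2, 1, 2, method = "cor"), 0)
})

test_that("linkage grouping recovers chromosomes and degenerates sanely", {
  set.seed(151)
  g <- tiny_genome(n_chrom = 2)
  p <- tiny_parents(g)
  gam <- simulate_meiosis(p$volkamer, 150, tau = 0.5, seed = 152)
  dm <- gamete_doses(gam, "medica", make_windows(g, 5, "medica"))
  lg <- linkage_groups(dm, threshold = 0.3)
  expect_length(unique(lg), 2)
  split_chrom <- split(dm$windows$chrom, lg)
  expect_true(all(vapply(split_chrom, function(x) length(unique(x)) == 1, TRUE)))
  # threshold 0: nothing joins
  lg0 <- linkage_groups(dm, threshold = 0)
  expect_length(unique(lg0), ncol(dm$dose))
})

test_that("map building accumulates Kosambi distances in physical order", {
  # 11 windows, each adjacent pair at rf 0.01 -> ~10.1 cM total
  set.seed(161)
  n <- 200
  m <- matrix(1, n, 11)
  for (k in 2:11) {
    m[, k] <- m[, k - 1]
    flip <- sample(n, 2)
    # move each flipped gamete one dose step, staying within 0..2
    m[flip, k] <- ifelse(m[flip, k] == 1, c(0, 2), 1)
  }
  # rf per interval = sum|diff| / (2n) = 2 / 400 = 0.005
  dm <- dm_from_matrix(m)
  map <- build_map(dm)
  expect_equal(map$summary$n_markers, 11)
  expect_equal(map$summary$length_cm, 10 * kosambi_cm(0.005), tolerance = 1e-8)
  expect_true(all(diff(map$map$cm) >= 0))

  # all-equal doses -> zero-length group (disomy hides crossovers)
  dm0 <- dm_from_matrix(matrix(1, 30, 5))
  expect_equal(build_map(dm0)$summary$length_cm, 0)
})

test_that("apparent map length shrinks with preferential pairing", {
  g <- tiny_genome()
  p <- tiny_parents(g)
  w <- make_windows(g, 10, "medica")
  lens <- sapply(c(1, 0.5, 0), function(tau) {
    gam <- simulate_meiosis(p$volkamer, 250, tau = tau,
                            seed = round(171 + tau * 10))
    build_map(gamete_doses(gam, "medica", w))$summary$length_cm
  })
  expect_true(lens[1] > lens[2])
  expect_true(lens[2] > lens[3])
  expect_equal(unname(lens[3]), 0)
})

test_that("Marey profile recovers a linear recombination rate", {
  # perfectly linear map at 2 cM/Mb
  pos <- seq(1e6, 3e7, length.out = 30)
  map <- structure(list(
    map = data.frame(chrom = "chr1", window = sprintf("w%02d", 1:30),
                     pos = pos, cm = 2 * pos / 1e6),
    summary = data.frame(chrom = "chr1", n_markers = 30,
                         length_cm = 60)), class = "genetic_map")
  prof <- marey_rate(map, span = 0.3)
  expect_equal(prof$rate_cm_mb, rep(2, 30), tolerance = 1e-6)

  # plateau region drops to ~0, never negative
  cm <- c(seq(0, 10, length.out = 10), rep(10, 10), seq(10, 20, length.out = 10))
  map$map$cm <- cm
  prof2 <- marey_rate(map, span = 0.2)
  expect_true(all(prof2$rate_cm_mb >= 0))
  expect_lt(min(prof2$rate_cm_mb[13:17]), 0.2)
  expect_warning(marey_rate(map, min_markers = 50), "fewer than")
})

test_that("Marey profile dips at a crossover-suppressed centromere", {
  # crossovers concentrated away from the centromere: cumulative cM follows
  # a sigmoid-free piecewise profile with a flat middle
  pos <- seq(1e6, 3e7, length.out = 40)
  mid <- abs(pos - 1.5e7) < 5e6
  rate <- ifelse(mid, 0.1, 3)
  cm <- cumsum(rate * c(0, diff(pos / 1e6)))
  map <- structure(list(
    map = data.frame(chrom = "chr1", window = sprintf("w%02d", 1:40),
                     pos = pos, cm = cm),
    summary = data.frame(chrom = "chr1", n_markers = 40,
                         length_cm = max(cm))), class = "genetic_map")
  prof <- marey_rate(map, span = 0.15)
  # the profile minimum falls inside the suppressed pericentromeric region
  expect_true(abs(prof$pos[which.min(prof$rate_cm_mb)] - 1.5e7) < 5e6)
  expect_lt(min(prof$rate_cm_mb), 0.5)
})

test_that("Manhattan dissimilarity and PCoA behave on planted structure", {
  expect_equal(manhattan_dissimilarity(rbind(c(0, 1), c(0, 1)))[1, 2], 0)
  expect_equal(manhattan_dissimilarity(rbind(c(0, 1), c(2, 1)))[1, 2], 1)
  D <- manhattan_dissimilarity(rbind(c(0, 1, NA), c(2, 1, 0)))
  expect_equal(D[1, 2], D[2, 1])  # symmetric, over shared loci only
  expect_equal(D[1, 2], 1)

  # collinear points: first axis carries ~all variance
  X <- cbind(seq(0, 2, length.out = 12))
  pc <- factorial_coordinates(manhattan_dissimilarity(cbind(X, X)), k = 2)
  expect_gt(pc$pct_variance[1], 99)

  # two planted clusters separate on axis 1
  set.seed(181)
  m <- rbind(matrix(rbinom(60, 2, 0.1), 10),
             matrix(rbinom(60, 2, 0.9), 10))
  pc2 <- factorial_coordinates(manhattan_dissimilarity(m), k = 2)
  grp <- rep(1:2, each = 10)
  expect_true(min(pc2$points[grp == 2, 1]) > max(pc2$points[grp == 1, 1]) ||
              min(pc2$points[grp == 1, 1]) > max(pc2$points[grp == 2, 1]))
  expect_error(factorial_coordinates(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
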