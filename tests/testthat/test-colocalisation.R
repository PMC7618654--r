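test_that("masked Pearson matches hand-computed correlations", {
  m <- matrix(TRUE, 2, 2)
  ch1 <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(masked_pearson(ch1, 2 * ch1, m), 1)
  expect_equal(masked_pearson(ch1, -ch1 + 7, m), -1)
  # hand covariance: cov = 4/3, var = 5/3 each -> R = 0.8
  ch2 <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(masked_pearson(ch1, ch2, m), 0.8)
  # mask restricts the computation
  big1 <- matrix(c(1, 2, 3, 4, 100, -50), 2)
  big2 <- matrix(c(1, 3, 2, 4, -7, 99), 2)
  sel <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(masked_pearson(big1, big2, sel), 0.8)
  expect_warning(r <- masked_pearson(matrix(5, 2, 2), ch1, m), "constant")
  expect_true(is.na(r))
})

test_that("masked Pearson is invariant under positive affine rescaling", {
  set.seed(9)
  a <- matrix(stats::rnorm(400), 20)
  b <- matrix(stats::rnorm(400), 20)
  m <- matrix(stats::runif(400) < 0.7, 20)
  r0 <- masked_pearson(a, b, m)
  expect_equal(masked_pearson(3.2 * a + 11, b, m), r0)
  expect_equal(masked_pearson(a, 0.4 * b - 2, m), r0)
})

test_that("perfectly coupled channels drive the threshold to the minimum", {
  set.seed(5)
  ch1 <- matrix(sample(10:200, 64 * 64, TRUE), 64)
  res <- costes_threshold_bisection(ch1, 2 * ch1, matrix(TRUE, 64, 64))
  expect_equal(res$T1, min(ch1))
  expect_equal(res$a, 2, tolerance = 1e-9)
})

test_that("thresholds ignore pixels outside the mask", {
  set.seed(15)
  p <- knee_pair()
  res1 <- costes_threshold_bisection(p$ch1, p$ch2, p$mask)
  ch1b <- p$ch1
  ch2b <- p$ch2
  ch1b[!p$mask] <- sample(0:255, sum(!p$mask), TRUE)
  ch2b[!p$mask] <- sample(0:255, sum(!p$mask), TRUE)
  res2 <- costes_threshold_bisection(ch1b, ch2b, p$mask)
  expect_identical(res1$T1, res2$T1)
  expect_identical(res1$a, res2$a)
})

test_that("bisection equals the exhaustive-scan oracle on well-posed pairs", {
  set.seed(77)
  for (i in 1:20) {
    p <- knee_pair(knee = sample(60:140, 1), up = stats::runif(1, 0.5, 1.2),
                   down = stats::runif(1, 0.3, 0.9))
    expect_threshold_agreement(p)
  }
  # mild noise moves the crossing by at most a few steps
  for (i in 1:10) {
    p <- knee_pair(knee = sample(80:120, 1), noise_sd = 4)
    b <- suppressWarnings(costes_threshold_bisection(p$ch1, p$ch2, p$mask))
    s <- suppressWarnings(costes_threshold_scan(p$ch1, p$ch2, p$mask))
    expect_lt(abs(b$T1 - s$T1), 15)
  }
})

test_that("non-positive regression slope leaves thresholds undefined", {
  set.seed(8)
  ch1 <- matrix(sample(0:255, 4096, TRUE), 64)
  ch2 <- matrix(255 - ch1 + sample(-5:5, 4096, TRUE), 64)
  expect_warning(res <- costes_threshold_bisection(ch1, ch2,
                                                   matrix(TRUE, 64, 64)),
                 "slope")
  expect_true(is.na(res$T1))
})

test_that("randomisation p-value follows the add-one convention", {
  sc <- simulate_scene(1, regimes = "colocalised", target_r = 0.9, seed = 2)
  m <- sc$nucleus_mask == 1
  rnd <- costes_randomisation(sc$channels$factorA, sc$channels$factorB, m,
                              rounds = 20, seed = 4)
  expect_equal(rnd$p, 1 / 21)
  expect_equal(length(rnd$null), 20L)
  expect_gt(rnd$observed, max(rnd$null, na.rm = TRUE))
  # constant channel 1 errors upstream
  expect_error(suppressWarnings(costes_randomisation(matrix(5, 64, 64),
                                                     sc$channels$factorB, m)),
               "undefined|constant|degenerate")
})

test_that("block shuffling permutes exactly the in-mask tile intensities", {
  set.seed(3)
  mask <- matrix(FALSE, 32, 32)
  mask[5:27, 4:28] <- TRUE
  tiles <- methfid:::mask_tiles(mask, 4L)
  expect_gt(length(tiles), 2L)
  px <- unlist(tiles)
  expect_true(all(mask[px]))
  expect_equal(length(px), length(unique(px)))
  expect_true(all(lengths(tiles) == 16L))
  ch <- matrix(stats::rnorm(32 * 32), 32)
  perm <- sample(length(tiles))
  shuffled <- ch
  shuffled[px] <- ch[unlist(tiles[perm])]
  expect_equal(sort(shuffled[px]), sort(ch[px]))        # multiset preserved
  expect_equal(shuffled[!mask], ch[!mask])              # outside untouched
})

test_that("profile sampling scales per channel between 0 and 1", {
  img <- matrix(rep(seq(2, 6, length.out = 10), each = 10), 10)
  line <- rbind(c(1, 5), c(10, 5))
  pr <- profile_plot(list(a = img, b = 10 * img + 3), line, samples = 3)
  expect_equal(pr$a, c(0, 0.5, 1))
  expect_equal(pr$b, c(0, 0.5, 1))  # scaling independent per channel
  expect_equal(pr$distance_frac, c(0, 0.5, 1))
  expect_warning(pr2 <- profile_plot(list(f = matrix(7, 10, 10)), line, 3),
                 "constant")
  expect_equal(pr2$f, c(0, 0, 0))
})

test_that("foci detection finds planted spots and nothing on flat cells", {
  # flat channel: no foci
  mask <- matrix(0L, 64, 64)
  mask[10:50, 10:50] <- 1L
  set.seed(20)
  flat <- matrix(1000 + stats::rnorm(64 * 64, 0, 20), 64)
  expect_equal(nrow(detect_foci(flat, mask)), 0L)
  # one synthetic Gaussian spot well above background -> exactly one focus
  yy <- matrix(1:64, 64, 64)
  xx <- t(yy)
  spot <- 500 * exp(-((yy - 30)^2 + (xx - 28)^2) / (2 * 3^2))
  one <- detect_foci(flat + spot, mask, min_prominence_sigmas = 5,
                     min_radius_px = 2)
  expect_equal(nrow(one), 1L)
  expect_lt(abs(one$x - 28), 1.5)
  expect_lt(abs(one$y - 30), 1.5)
  expect_error(detect_foci(flat, matrix(0L, 64, 64)), "empty")
})

test_that("foci fraction recovers the simulated prevalence", {
  frac_truth <- 0.4
  rows <- list()
  for (img in 1:3) {
    sc <- simulate_scene(20, regimes = "independent",
                         foci_cells = stats::runif(20) < frac_truth,
                         seed = 100 + img)
    foci <- detect_foci(sc$channels$factorA, sc$nucleus_mask,
                        min_prominence_sigmas = 6)
    rows[[img]] <- tibble::tibble(
      image = img, cell = 1:20,
      has_foci = (1:20) %in% foci$cell,
      truth = sc$truth$cells$has_foci)
  }
  cells <- dplyr::bind_rows(rows)
  expect_equal(cells$has_foci, cells$truth)  # perfect recovery at this SNR
  ff <- foci_fraction(cells)
  se <- sqrt(frac_truth * (1 - frac_truth) / nrow(cells))
  expect_lt(abs(ff$fraction - frac_truth), 3 * se + 1e-9)
  expect_true(is.finite(ff$sem))
})

test_that("DAPI-dense mask matches quantile area and nests in nuclei", {
  set.seed(44)
  dapi <- matrix(stats::runif(64 * 64, 0, 1000), 64)
  mask <- matrix(1L, 64, 64)
  dm <- dapi_dense_mask(dapi, mask, 0.99)
  expect_equal(mean(dm), 0.01, tolerance = 0.3)
  sc <- simulate_scene(4, seed = 9)
  dm2 <- dapi_dense_mask(sc$channels$dapi, sc$nucleus_mask, 0.7)
  expect_true(all(sc$nucleus_mask[dm2] > 0))
  jac <- sum(dm2 & sc$truth$het_mask) / sum(dm2 | sc$truth$het_mask)
  expect_gte(jac, 0.8)
})

test_that("spot overlap uses the partial-overlap rule", {
  dense <- matrix(FALSE, 32, 32)
  dense[16, 20] <- TRUE
  nuc <- matrix(0L, 32, 32)
  nuc[4:28, 4:28] <- 1L
  spots <- tibble::tibble(cell = 1L,
                          x = c(20, 18, 8, 30), y = c(16, 16, 8, 30),
                          radius = 2)
  expect_warning(cl <- spot_overlap_classify(spots, dense, nuc), "excluded")
  expect_equal(nrow(cl), 3L)
  expect_true(cl$heterochromatic[1])    # spot centred on the dense pixel
  expect_true(cl$heterochromatic[2])    # exactly one shared pixel suffices
  expect_false(cl$heterochromatic[3])   # disjoint spot stays euchromatic
  cl$image <- 1L
  of <- overlap_fraction(cl)
  expect_equal(of$fraction, 1)  # the cell has >= 1 heterochromatic spot
})
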