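test_that("Savitzky-Golay reproduces polynomials up to the fit order exactly", {
  x <- 1:31
  for (ord in 2:3) {
    y <- 2 + 0.5 * x - 0.03 * x^2 + if (ord >= 3) 1e-3 * x^3 else 0
    out <- savitzky_golay(y, window = 7, polyorder = ord)
    expect_equal(out, y, tolerance = 1e-9)
  }
  expect_equal(savitzky_golay(rep(4, 20), 5, 2), rep(4, 20))
  expect_error(savitzky_golay(1:20, window = 6, polyorder = 2), "odd")
  expect_error(savitzky_golay(1:20, window = 5, polyorder = 5), "smaller")
  expect_error(savitzky_golay(1:4, window = 5, polyorder = 2), "shorter")
})

test_that("window-5 order-2 central weights match the least-squares solve", {
  # direct solve: projection row of the local quadratic fit at the center
  A <- outer(-2:2, 0:2, "^")
  w_direct <- (A %*% solve(crossprod(A)))[, 1]
  expect_equal(w_direct, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  # applying the filter to impulse positions recovers those weights
  y <- rep(0, 11); y[6] <- 1
  out <- savitzky_golay(y, 5, 2)
  expect_equal(out[4:8], rev(c(-3, 12, 17, 12, -3) / 35), tolerance = 1e-12)
})

test_that("smoothed output agrees with an independent per-window fit", {
  set.seed(8)
  y <- sin(seq(0, 3, length.out = 41)) + rnorm(41, sd = 0.05)
  expect_equal(savitzky_golay(y, 9, 3), savgol_direct(y, 9, 3),
               tolerance = 1e-8)
})

test_that("band affinity is a symmetric unit-diagonal correlation", {
  set.seed(12)
  x <- matrix(rnorm(200), 50, 4)
  x[, 2] <- x[, 1]            # duplicate band
  x[, 3] <- -x[, 1] + 2      # negated (after centering)
  aff <- band_affinity(x)
  expect_equal(aff[1, 2], 1)
  expect_equal(aff[1, 3], -1)
  expect_equal(aff, t(aff))
  expect_equal(diag(aff), rep(1, 4), ignore_attr = TRUE)
  x[, 4] <- 7                 # constant band
  aff2 <- band_affinity(x)
  expect_true(attr(aff2, "degenerate")[4])
  expect_equal(aff2[4, ], rep(1, 4))
})

test_that("affinity pruning keeps the forced count and the distinct band", {
  B <- 7
  aff_same <- matrix(1, B, B)
  kept <- prune_similar_bands(aff_same, keep_fraction = 0.5)
  expect_length(kept$kept, ceiling(0.5 * B))
  expect_equal(kept$kept, 1:4)  # ties keep the lower wavelength
  # one band uncorrelated with all others is always retained
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  x <- cbind(x %*% matrix(runif(9, 0.8, 1.2), 3), rnorm(20))
  aff <- band_affinity(x)
  for (kf in c(0.25, 0.5, 0.75)) {
    expect_true(4 %in% prune_similar_bands(aff, kf)$kept)
  }
  expect_equal(prune_similar_bands(aff, 1)$kept, 1:4)
  expect_error(prune_similar_bands(aff, 0), "keep_fraction")
  expect_error(prune_similar_bands(aff, 1.2), "keep_fraction")
})

test_that("divergence scores are the absolute mean differences, summed over pairs", {
  a <- rep(0.3, 20); b <- a
  expect_equal(divergence_per_band(list(a, b)), rep(0, 20))
  b2 <- a; b2[6:10] <- a[6:10] + 0.2
  d <- divergence_per_band(list(a, b2))
  expect_equal(d[6:10], rep(0.2, 5))
  expect_equal(d[-(6:10)], rep(0, 15))
  expect_equal(divergence_per_band(matrix(0.4, 4, 20)), rep(0, 20))
  expect_error(divergence_per_band(list(1:5, 1:6)), "grids")
})

test_that("outlier exclusion drops exactly the anomalous sample", {
  mk <- function(areas, tissue = "ICA_PEELED") {
    nb <- 10
    structure(list(values = outer(areas / nb, rep(1, nb)),
                   wavelengths = seq_len(nb),
                   meta = data.frame(tissue = tissue,
                                     specimen_id = seq_along(areas),
                                     spot_id = 1,
                                     region_id = seq_along(areas))),
              class = "spectrum_samples")
  }
  same <- mk(rep(10, 5))
  out <- exclude_outlier_samples(same)
  expect_equal(nrow(out$excluded), 0)
  # four samples at area 10 and one at 100: modified z (mean-AD fallback,
  # MAD is zero) = 90 / (1.253314 * 18) = 3.99 > 3.5
  mix <- mk(c(10, 10, 10, 10, 100))
  out2 <- exclude_outlier_samples(mix)
  expect_equal(out2$excluded$specimen_id, 5)
  expect_equal(out2$excluded$score, 90 / (1.253314 * 18), tolerance = 1e-6)
  expect_equal(nrow(out2$kept$values), 4)
  expect_equal(nrow(exclude_outlier_samples(mix, threshold_mad = Inf)$excluded), 0)
  expect_warning(exclude_outlier_samples(mk(c(10, 100))), "fewer than 3")
})

test_that("band selection concentrates on the planted contrast interval", {
  pb <- planted_contrast_scene(interval = c(480, 600), seed = 19)
  sc <- pb$scene
  bs <- select_optimal_bands(sc$cube, sc$mask, n_select = 20)
  expect_gte(mean(bs$wavelength >= 480 & bs$wavelength <= 600), 0.8)
  expect_true(all(bs$score >= 0))
  expect_true(!anyDuplicated(bs$wavelength))
})

test_that("the top-k subset is a prefix of the top-(k+1) subset", {
  pb <- planted_contrast_scene(wavelengths = wl_small(33), seed = 6)
  sc <- pb$scene
  prev <- NULL
  for (k in 1:12) {
    bs <- select_optimal_bands(sc$cube, sc$mask, n_select = k, sg_window = 5)
    if (!is.null(prev)) expect_equal(bs$wavelength[seq_len(k - 1)], prev)
    prev <- bs$wavelength
  }
})

test_that("global cube scaling changes scores but not the selected order", {
  pb <- planted_contrast_scene(wavelengths = wl_small(33), seed = 9)
  sc <- pb$scene
  bs1 <- select_optimal_bands(sc$cube, sc$mask, n_select = 10, sg_window = 5)
  scaled <- reflectance_cube(sc$cube$data * 0.5, sc$cube$wavelengths)
  bs2 <- select_optimal_bands(scaled, sc$mask, n_select = 10, sg_window = 5)
  expect_equal(bs1$wavelength, bs2$wavelength)
  expect_equal(bs2$score, 0.5 * bs1$score, tolerance = 1e-9)
  aff1 <- band_affinity(sc$cube, sc$mask)
  aff2 <- band_affinity(scaled, sc$mask)
  expect_equal(unclass(aff1), unclass(aff2), tolerance = 1e-12)
})

test_that("degenerate selections are handled explicitly", {
  pb <- planted_contrast_scene(wavelengths = wl_small(17), seed = 2)
  sc <- pb$scene
  expect_error(select_optimal_bands(sc$cube, sc$mask, n_select = 1000,
                                    sg_window = 5),
               "keep_fraction")
  # two identical classes: zero divergence everywhere, flagged zero-ranking
  wl <- wl_small(17)
  mask2 <- matrix(0L, 16, 16)
  mask2[2:7, 2:7] <- 1L
  mask2[10:15, 10:15] <- 2L
  spectrum <- seq(0.2, 0.4, length.out = 17)
  cube_const <- reflectance_cube(
    array(rep(spectrum, each = 256), c(16, 16, 17)), wl)
  bs <- select_optimal_bands(cube_const, mask2, n_select = 5, sg_window = 5)
  expect_true(attr(bs, "provenance")$zero_ranking)
  expect_equal(bs$score, rep(0, 5))
})

test_that("smoothing moves a planted divergence peak by at most half a window", {
  nb <- 41
  peak <- 21
  a <- rep(0.3, nb)
  b <- a + 0.2 * exp(-((seq_len(nb) - peak) / 3)^2)
  for (w in c(5, 9, 11)) {
    sm <- abs(savitzky_golay(b, w, 3) - savitzky_golay(a, w, 3))
    expect_lte(abs(which.max(sm) - peak), w / 2)
  }
})
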