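test_that("max-normalization follows its definition and is idempotent", {
  expect_equal(normalize_spectrum(c(0.1, 0.2, 0.4)), c(0.25, 0.5, 1.0))
  expect_equal(normalize_spectrum(c(3, 3, 3)), c(1, 1, 1))
  set.seed(2)
  for (i in 1:20) {
    v <- runif(16, 0.01, 2)
    n1 <- normalize_spectrum(v)
    expect_equal(max(n1), 1)
    expect_equal(normalize_spectrum(n1), n1)
  }
  expect_error(normalize_spectrum(c(0, 0)), "positive")
  expect_error(normalize_spectrum(c(-1, -2)), "positive")
})

test_that("quartiles follow the weighted-average-at-(n+1)p rule", {
  d <- descriptive_stats(c(1, 2, 3, 4))
  expect_equal(d$q1, 1.25)
  expect_equal(d$median, 2.5)
  expect_equal(d$q3, 3.75)
  expect_equal(d$iqr, 2.5)
  dc <- descriptive_stats(rep(5, 6))
  expect_equal(dc$iqr, 0)
})

test_that("group mean CI matches the t formula and handles degenerate input", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  ci <- group_mean_ci(x)
  expect_equal(ci$mean, 3)
  expect_equal(ci$half_width,
               qt(0.975, 4) * sd(1:5) / sqrt(5), tolerance = 1e-12)
  cc <- group_mean_ci(matrix(7, 4, 2))
  expect_equal(cc$half_width, c(0, 0))
  expect_error(group_mean_ci(matrix(1, 1, 3)), "n >= 2")
})

test_that("rank test reproduces hand-enumerated exact cases", {
  bt <- mann_whitney_per_band(c(1, 2, 3), c(4, 5, 6))
  expect_equal(bt$u, 0)
  expect_equal(bt$p, 0.1)  # 2 / choose(6, 3) extreme labelings
  bt2 <- mann_whitney_per_band(c(1, 2), c(3, 4))
  expect_equal(bt2$p, 2 / 6, tolerance = 1e-12)
  bt3 <- mann_whitney_per_band(c(1, 2, 3), c(1, 2, 3))
  expect_equal(bt3$u, 4.5)
  expect_gte(bt3$p, 0.99)
  expect_error(mann_whitney_per_band(numeric(0), c(1, 2)), "at least 2")
})

test_that("rank test matches exhaustive enumeration for all sizes with n1+n2 <= 12", {
  set.seed(31)
  for (n1 in 2:8) for (n2 in 2:8) {
    if (n1 + n2 > 12) next
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    got <- mann_whitney_per_band(x, y)
    want <- enumerate_mann_whitney(x, y)
    expect_equal(got$u, want$u, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # unbalanced splits covered by the total-size rule
  for (sizes in list(c(2, 10), c(3, 9), c(2, 9))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2], 1)
    got <- mann_whitney_per_band(x, y)
    want <- enumerate_mann_whitney(x, y)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("normality screen behaves on null, skewed and constant data", {
  set.seed(17)
  a <- matrix(rnorm(20 * 161), 20)
  b <- matrix(rnorm(20 * 161), 20)
  sw <- shapiro_wilk_per_band(a, b)
  rej <- mean(c(sw$p_a, sw$p_b) < 0.05)
  # ~5% rejections under the null, within a generous binomial band
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
  skewed <- matrix(exp(rnorm(20 * 50, sd = 2)), 20)
  sw2 <- shapiro_wilk_per_band(skewed, skewed + 1)
  expect_gt(mean(sw2$p_a < 0.05), 0.5)
  const <- matrix(1, 5, 3)
  sw3 <- shapiro_wilk_per_band(const, matrix(rnorm(15), 5))
  expect_true(all(!sw3$testable))
  expect_equal(nrow(sw3$normal_ranges), 0)
})

test_that("range consolidation reports maximal runs at the right alpha", {
  wl <- seq(400, 420, by = 2)
  p <- rep(1, 11)
  p[1:3] <- 0.01  # 400-404 nm
  bt <- data.frame(wavelength = wl, p = p)
  rg <- consolidate_ranges(bt)
  expect_equal(nrow(rg), 1)
  expect_equal(rg$lambda_start, 400)
  expect_equal(rg$lambda_end, 404)
  expect_equal(rg$alpha, 0.05)
  # alternating significant bands vanish under min_run = 2
  p_alt <- rep(c(0.01, 1), length.out = 11)
  expect_equal(nrow(consolidate_ranges(data.frame(wavelength = wl, p = p_alt))), 0)
  # a run entirely below the stricter alpha is reported once, at 0.001
  p2 <- rep(1, 11); p2[4:8] <- 1e-5
  rg2 <- consolidate_ranges(data.frame(wavelength = wl, p = p2))
  expect_equal(nrow(rg2), 1)
  expect_equal(rg2$alpha, 0.001)
  # mixed run: the 0.001 core and 0.05 shoulders are split, not duplicated
  p3 <- rep(1, 11); p3[3:9] <- 0.01; p3[5:7] <- 1e-4
  rg3 <- consolidate_ranges(data.frame(wavelength = wl, p = p3))
  expect_equal(sort(rg3$alpha), c(0.001, 0.05, 0.05))
})

test_that("consolidation partitions the significant band set before run filtering", {
  set.seed(5)
  wl <- seq(400, 500, by = 2)
  for (rep in 1:20) {
    p <- runif(length(wl))^3
    rg <- consolidate_ranges(data.frame(wavelength = wl, p = p),
                             alpha_levels = c(0.05, 0.001), min_run = 1)
    covered <- rep(FALSE, length(wl))
    for (i in seq_len(nrow(rg))) {
      run <- wl >= rg$lambda_start[i] & wl <= rg$lambda_end[i]
      expect_false(any(covered & run))  # no double-claiming
      covered <- covered | run
    }
    expect_identical(covered, p < 0.05)
    # bands claimed at 0.001 are exactly those below 0.001
    covered001 <- rep(FALSE, length(wl))
    for (i in which(rg$alpha == 0.001)) {
      covered001 <- covered001 | (wl >= rg$lambda_start[i] & wl <= rg$lambda_end[i])
    }
    expect_identical(covered001, p < 0.001)
  }
})

test_that("more planted shift never yields fewer significant bands", {
  # noise-free quantile-matched groups: a deterministic location contrast
  q <- qnorm((1:10) / 11)
  wl <- seq_len(30)
  ramp <- seq(0, 1, length.out = 30)
  n_sig <- sapply(c(0.25, 0.5, 1, 2, 4), function(shift) {
    a <- matrix(rep(q, 30), nrow = 10)
    b <- a + matrix(rep(shift * ramp, each = 10), nrow = 10)
    sum(mann_whitney_per_band(a, b, wl)$p < 0.05)
  })
  expect_true(all(diff(n_sig) >= 0))
})

test_that("spot extraction is seeded, disk-averaged and respects spacing", {
  wl <- wl_small()
  sp <- board_scene_spec(classes = c("ICA_NORMAL", "FN_DISTAL"),
                         n_specimens = 2, wavelengths = wl,
                         noise_sd = 0, specular_fraction = 0, seed = 3)
  sc <- generate_scene(sp)
  s1 <- extract_sample_spectra(sc$cube, sc$region_mask, sc$regions, seed = 5)
  s2 <- extract_sample_spectra(sc$cube, sc$region_mask, sc$regions, seed = 5)
  expect_identical(s1$values, s2$values)
  expect_equal(nrow(s1$values), 2 * 2 * 4)
  # homogeneous noiseless region: every spot equals the region spectrum
  for (rid in sc$regions$region_id) {
    rows <- which(s1$meta$region_id == rid)
    ref <- sc$cube$data[which(sc$region_mask == rid)[1] +
                          (seq_along(wl) - 1) * prod(dim(sc$mask))]
    for (r in rows) expect_equal(unname(s1$values[r, ]), ref, tolerance = 1e-12)
  }
  # a region too small for four separated spots errors with its name
  tiny <- scene_spec(12, 12,
                     regions = list(list(class_id = "ICA_NORMAL",
                                         polygon = rect_polygon(3, 3, 7, 7),
                                         specimen_id = 1)),
                     wavelengths = wl, noise_sd = 0, specular_fraction = 0,
                     seed = 1)
  tsc <- generate_scene(tiny)
  expect_error(extract_sample_spectra(tsc$cube, tsc$region_mask, tsc$regions,
                                      n_spots = 4, spot_radius = 2),
               "ICA_NORMAL")
})

test_that("interval recovery metric behaves at its extremes", {
  wl <- seq(400, 500, by = 2)
  rg <- data.frame(lambda_start = 420, lambda_end = 460)
  expect_equal(interval_jaccard(rg, c(420, 460), wl), 1)
  expect_equal(interval_jaccard(rg, c(480, 500), wl), 0)
  expect_equal(interval_jaccard(rg[0, ], c(480, 500), wl), 0)
})
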