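test_that("Jaccard IoU obeys its identities and symmetries", {
  a <- matrix(0L, 8, 8); a[2:4, 2:4] <- 1L
  expect_equal(jaccard_iou(a, a, 1), 1)
  b <- matrix(0L, 8, 8); b[6:8, 6:8] <- 1L
  expect_equal(jaccard_iou(a, b, 1), 0)
  # pred 4 px, truth 4 px, overlap 2 px -> 2/6
  p <- matrix(0L, 4, 4); p[1, 1:4] <- 1L
  t <- matrix(0L, 4, 4); t[1, 3:4] <- 1L; t[2, 1:2] <- 1L
  expect_equal(jaccard_iou(p, t, 1), 2 / 6)
  # symmetry and label permutation
  set.seed(44)
  x <- matrix(sample(0:3, 100, TRUE), 10)
  y <- matrix(sample(0:3, 100, TRUE), 10)
  expect_equal(jaccard_iou(x, y), jaccard_iou(y, x))
  perm <- c(0L, 2L, 3L, 1L)
  xp <- matrix(perm[x + 1L], 10); yp <- matrix(perm[y + 1L], 10)
  iou <- jaccard_iou(x, y); ioup <- jaccard_iou(xp, yp)
  for (cl in 0:3) expect_equal(unname(ioup[as.character(perm[cl + 1])]),
                               unname(iou[as.character(cl)]))
  expect_error(jaccard_iou(a, matrix(0L, 4, 4)), "shape")
})

test_that("empty scenes evaluate to full accuracy with no tissue IoU", {
  z <- matrix(0L, 6, 6)
  ev <- evaluate_segmentation(z, z)
  expect_equal(ev$pixel_accuracy, 1)
  expect_equal(names(ev$per_class_iou), "0")
})

test_that("the network preserves spatial shape and emits a probability simplex", {
  for (size in c(32, 48)) {
    spec <- unet_spec(in_channels = 4, n_classes = 3, depth = 2,
                      base_channels = 4)
    model <- build_unet(spec, seed = 2)
    x <- array(runif(size * size * 4), c(size, size, 4))
    out <- predict_unet(model, x)
    expect_equal(dim(out$labels), c(size, size))
    expect_equal(dim(out$probs), c(size, size, 3))
    sums <- apply(out$probs, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  # depth-3 model on a 96x96 input (divisible by 8)
  m3 <- build_unet(unet_spec(3, 3, depth = 3, base_channels = 2), seed = 1)
  out3 <- predict_unet(m3, array(runif(96 * 96 * 3), c(96, 96, 3)))
  expect_equal(dim(out3$labels), c(96, 96))
  # non-divisible sizes are reflection-padded and cropped back
  m2 <- build_unet(unet_spec(3, 3, depth = 2, base_channels = 2), seed = 1)
  out2 <- predict_unet(m2, array(runif(50 * 50 * 3), c(50, 50, 3)))
  expect_equal(dim(out2$labels), c(50, 50))
})

test_that("channel and band-order mismatches are rejected", {
  model <- build_unet(unet_spec(5, 3, depth = 1, base_channels = 2), seed = 1)
  expect_error(predict_unet(model, array(0.1, c(16, 16, 4))), "channel mismatch")
  wl <- wl_small(5)
  cube <- reflectance_cube(array(0.3, c(16, 16, 5)), wl)
  fit <- train_unet(model, list(cube), list(matrix(0L, 16, 16)),
                    training_config(epochs = 1, seed = 1))
  other <- reflectance_cube(array(0.3, c(16, 16, 5)), wl + 2)
  expect_error(predict_unet(fit$model, other), "band-order mismatch")
})

test_that("training is seeded-reproducible and learns on a synthetic scene", {
  wl <- wl_small()
  sc <- generate_scene(quadrant_scene_spec(size = 32, wavelengths = wl,
                                           noise_sd = 0.01,
                                           specular_fraction = 0, seed = 4))
  spec <- unet_spec(length(wl), 5, depth = 2, base_channels = 4)
  cfg <- training_config(epochs = 12, seed = 7)
  f1 <- train_unet(build_unet(spec, seed = 7), list(sc$cube), list(sc$mask), cfg)
  f2 <- train_unet(build_unet(spec, seed = 7), list(sc$cube), list(sc$mask), cfg)
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
  expect_gt(tail(f1$history$mean_iou, 1), f1$history$mean_iou[1])
})

test_that("the learning curve rises early and flattens by 80 epochs", {
  wl <- wl_small()
  sc <- generate_scene(quadrant_scene_spec(size = 48, wavelengths = wl,
                                           seed = 13))
  spec <- unet_spec(length(wl), 5, depth = 2, base_channels = 8)
  fit <- train_unet(build_unet(spec, seed = 3), list(sc$cube), list(sc$mask),
                    training_config(epochs = 100, seed = 3))
  h <- fit$history
  expect_gt(h$mean_iou[25], h$mean_iou[1])
  expect_lt(h$mean_iou[100] - h$mean_iou[80], 0.02)
})

test_that("divergence-selected bands train at least as well as random bands", {
  # two classes whose only contrast sits in a planted interval, so band
  # informativeness is controlled: the selected 20 bands target the
  # interval while a random 20-band draw mostly misses it
  wl <- default_wavelengths()
  scenes <- lapply(1:3, function(i) {
    planted_contrast_scene(interval = c(480, 600), noise_sd = 0.12,
                           n_specimens = 2, seed = 60 + i)$scene
  })
  bs <- select_optimal_bands(scenes[[1]]$cube, scenes[[1]]$mask, n_select = 20)
  sel_wl <- sort(bs$wavelength)
  run <- function(band_wl, seed) {
    cubes <- lapply(scenes[1:2], function(s) subset_bands(s$cube, band_wl))
    masks <- lapply(scenes[1:2], `[[`, "mask")
    model <- build_unet(unet_spec(20, 3, depth = 2, base_channels = 8),
                        seed = seed)
    fit <- train_unet(model, cubes, masks,
                      training_config(epochs = 50, seed = seed))
    pred <- predict_unet(fit$model, subset_bands(scenes[[3]]$cube, band_wl))
    evaluate_segmentation(pred$labels, scenes[[3]]$mask)$mean_iou
  }
  sel_iou <- ran_iou <- numeric(5)
  for (s in 1:5) {
    sel_iou[s] <- run(sel_wl, s)
    set.seed(1000 + s)
    ran_iou[s] <- run(sort(sample(wl, 20)), s)
  }
  expect_gte(mean(sel_iou), mean(ran_iou))
})

test_that("the default palette maps tissues to their display colors", {
  pal <- default_palette()
  expect_equal(unname(pal["ICA_NORMAL"]), "#FF0000")   # red
  expect_equal(unname(pal["ICA_PEELED"]), "#0000FF")   # blue
  expect_equal(unname(pal["FN_DISTAL"]), "#FF8C00")    # orange
  expect_equal(unname(pal["FN_PROXIMAL"]), "#00A000")  # green
  labels <- matrix(0L, 10, 10); labels[3:7, 3:7] <- 1L
  img <- render_overlay(labels)
  expect_equal(dim(img), c(10, 10, 3))
  # border pixels of class 1 are pure red; interior pixels keep the base
  expect_equal(img[3, 3, ], c(1, 0, 0))
  expect_equal(img[5, 5, ], c(0.5, 0.5, 0.5))
})
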