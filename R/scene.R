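#' Axis-aligned rectangle polygon
#'
#' Vertices in pixel coordinates (x = column, y = row, 0-based). With the
#' boundary-inclusive pixel-center rasterizer, the rectangle covers
#' `(x1 - x0 + 1) * (y1 - y0 + 1)` pixels.
#'
#' @param x0,y0,x1,y1 Corner coordinates (inclusive).
#' @return 4 x 2 matrix of vertices.
#' @export
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Specify a synthetic narrow-band scene
#'
#' @param height,width Image size in pixels.
#' @param regions List of regions, each a list with `class_id`, `polygon`
#'   (matrix of x, y vertices), `specimen_id` (integer) and optionally
#'   `anomaly = list(kind, magnitude)`.
#' @param wavelengths Wavelength grid (nm), strictly increasing.
#' @param noise_sd Per-pixel-per-band additive Gaussian noise sd.
#' @param specular_fraction Fraction of pixels replaced by bright specular
#'   grain (uniform high reflectance across all bands); must be < 0.2.
#' @param n_specimens Number of specimens the scene draws scales for.
#' @param seed Integer seed; identical specs generate identical scenes.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, regions,
                       wavelengths = default_wavelengths(),
                       noise_sd = 0.02, specular_fraction = 0.02,
                       n_specimens = 5, seed = 1L) {
  stopifnot(height >= 1, width >= 1, noise_sd >= 0)
  if (specular_fraction < 0 || specular_fraction >= 0.2) {
    stop("specular_fraction must be in [0, 0.2)")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  for (k in seq_along(regions)) {
    p <- regions[[k]]$polygon
    if (any(p[, 1] < 0 | p[, 1] > width - 1 | p[, 2] < 0 | p[, 2] > height - 1)) {
      stop("region ", k, " polygon lies outside the image")
    }
  }
  structure(list(height = height, width = width, regions = regions,
                 wavelengths = as.numeric(wavelengths), noise_sd = noise_sd,
                 specular_fraction = specular_fraction,
                 n_specimens = n_specimens, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Specimen-board scene: a grid of tissue samples on dark cardboard
#'
#' Emulates the annotated specimen boards used for spectral screening: one
#' row per tissue class, one column per specimen, rectangular samples on a
#' dark background.
#'
#' @param classes Tissue classes (rows of the board).
#' @param n_specimens Specimens (columns of the board).
#' @param region_size Side of each square sample, pixels.
#' @param margin Gap between samples, pixels.
#' @param anomalies Named list mapping `"CLASS.specimen"` (e.g.
#'   `"ICA_PEELED.1"`) to `list(kind, magnitude)`.
#' @inheritParams scene_spec
#' @param ... Passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
board_scene_spec <- function(classes = tissue_classes(), n_specimens = 5,
                             region_size = 14, margin = 6,
                             anomalies = list(), seed = 1L, ...) {
  pitch <- region_size + margin
  width <- n_specimens * pitch + margin
  height <- length(classes) * pitch + margin
  regions <- list()
  for (ci in seq_along(classes)) {
    for (si in seq_len(n_specimens)) {
      x0 <- margin + (si - 1) * pitch
      y0 <- margin + (ci - 1) * pitch
      reg <- list(class_id = classes[ci],
                  polygon = rect_polygon(x0, y0, x0 + region_size - 1,
                                         y0 + region_size - 1),
                  specimen_id = si)
      key <- paste0(classes[ci], ".", si)
      if (!is.null(anomalies[[key]])) reg$anomaly <- anomalies[[key]]
      regions[[length(regions) + 1]] <- reg
    }
  }
  scene_spec(height, width, regions, n_specimens = n_specimens, seed = seed, ...)
}

#' Single-specimen scene with one sample of each tissue class per quadrant
#'
#' The scene layout used for segmentation training/evaluation: four tissue
#' samples from one specimen arranged on a dark background.
#'
#' @param specimen_id Specimen the scene belongs to.
#' @param size Scene side, pixels.
#' @param classes Tissue classes placed in the four quadrants.
#' @inheritParams scene_spec
#' @param ... Passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
quadrant_scene_spec <- function(specimen_id = 1, size = 64,
                                classes = tissue_classes(), seed = 1L, ...) {
  stopifnot(length(classes) == 4)
  m <- 4
  half <- size %/% 2
  rs <- half - 2 * m  # sample side
  anchors <- list(c(m, m), c(half + m, m), c(m, half + m), c(half + m, half + m))
  regions <- lapply(seq_along(classes), function(k) {
    a <- anchors[[k]]
    list(class_id = classes[k],
         polygon = rect_polygon(a[1], a[2], a[1] + rs - 1, a[2] + rs - 1),
         specimen_id = specimen_id)
  })
  scene_spec(size, size, regions, seed = seed, ...)
}

#' Two-class screening benchmark with a planted spectral contrast
#'
#' A specimen board carrying two tissue classes whose mean curves differ by
#' exactly `effect_size` inside `interval` and are identical outside it.
#' Noise is calibrated for the per-band screening benchmark: no
#' between-specimen level scatter and no specular grain, so the 20 spot
#' spectra per class (5 specimens x 4 spots) are exchangeable and the
#' out-of-interval bands behave as a clean null.
#'
#' @param interval `c(lo, hi)` planted contrast interval in nm.
#' @param effect_size Additive contrast inside the interval.
#' @param noise_sd Per-pixel-per-band Gaussian noise sd.
#' @param n_specimens Specimens per class.
#' @param wavelengths Wavelength grid.
#' @param seed Scene seed.
#' @return List with `scene` (an `nbi_scene`) and `models`.
#' @export
planted_contrast_scene <- function(interval = c(480, 600), effect_size = 0.04,
                                   noise_sd = 0.05, n_specimens = 5,
                                   wavelengths = default_wavelengths(),
                                   seed = 1L) {
  base <- list(offset = 0.10, amp = 0.45, mid = 580, width = 60,
               dips = list(c(0.06, 435, 18)))
  models <- list(
    CLASS_A = tissue_spectrum_model("CLASS_A", base$offset, base$amp,
                                    base$mid, base$width, base$dips,
                                    sample_scale_sd = 0),
    CLASS_B = tissue_spectrum_model("CLASS_B", base$offset, base$amp,
                                    base$mid, base$width, base$dips,
                                    effect_bands = interval,
                                    effect_size = effect_size,
                                    sample_scale_sd = 0),
    BACKGROUND = tissue_spectrum_model("BACKGROUND", 0.02, 0, 560, 60,
                                       sample_scale_sd = 0)
  )
  spec <- board_scene_spec(classes = c("CLASS_A", "CLASS_B"),
                           n_specimens = n_specimens,
                           wavelengths = wavelengths, noise_sd = noise_sd,
                           specular_fraction = 0, seed = seed)
  list(scene = generate_scene(spec, models), models = models)
}

#' Generate an annotated synthetic reflectance cube
#'
#' Renders a [scene_spec()] using per-class spectrum models: each pixel
#' inside a region gets the class curve, modified by the region's anomaly,
#' scaled by a log-normal per-(specimen, class) factor, with additive
#' Gaussian noise and bright specular grain on a dark cardboard background.
#' The same spec (including seed) always produces bitwise-identical output.
#'
#' @param spec A [scene_spec()].
#' @param models Named list of [tissue_spectrum_model()]s covering every
#'   `class_id` used in the spec plus `BACKGROUND`.
#' @return Object of class `nbi_scene`: list with `cube`
#'   ([reflectance_cube()]), `mask` (class label matrix), `region_mask`
#'   (region index matrix), `regions` (data frame), `annotations`
#'   (VIA-compatible annotation set) and `spec`.
#' @export
generate_scene <- function(spec, models = default_models()) {
  stopifnot(inherits(spec, "scene_spec"))
  used <- unique(vapply(spec$regions, `[[`, character(1), "class_id"))
  unknown <- setdiff(used, names(models))
  if (length(unknown) > 0) {
    stop("configuration error: no spectrum model for class_id ",
         paste(unknown, collapse = ", "))
  }
  class_palette <- setdiff(names(models), "BACKGROUND")
  annotations <- lapply(spec$regions, function(r) {
    list(region_label = r$class_id, polygon = r$polygon,
         specimen_id = r$specimen_id)
  })
  mask <- rasterize_annotations(annotations, c(spec$height, spec$width),
                                class_palette, on_overlap = "error")
  region_mask <- attr(mask, "region_owner")
  attr(mask, "region_owner") <- NULL

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  # log-normal per-(specimen, class) level scatter, drawn in a fixed order
  scales <- matrix(1, spec$n_specimens, length(class_palette),
                   dimnames = list(NULL, class_palette))
  for (si in seq_len(spec$n_specimens)) {
    for (cl in class_palette) {
      scales[si, cl] <- stats::rlnorm(1, 0, models[[cl]]$sample_scale_sd)
    }
  }

  h <- spec$height; w <- spec$width
  wl <- spec$wavelengths
  nb <- length(wl)
  npx <- h * w
  bg <- eval_spectrum_model(models$BACKGROUND, wl)
  cube <- array(rep(bg, each = npx), c(h, w, nb))
  for (k in seq_along(spec$regions)) {
    reg <- spec$regions[[k]]
    curve <- eval_spectrum_model(models[[reg$class_id]], wl)
    if (!is.null(reg$anomaly)) {
      curve <- apply_anomaly(curve, reg$anomaly$kind,
                             reg$anomaly$magnitude, wl)
    }
    curve <- curve * scales[reg$specimen_id, reg$class_id]
    idx <- which(region_mask == k)
    cube[outer(idx, (seq_len(nb) - 1L) * npx, "+")] <-
      rep(curve, each = length(idx))
  }
  if (spec$noise_sd > 0) {
    cube <- cube + stats::rnorm(length(cube), 0, spec$noise_sd)
  }
  if (spec$specular_fraction > 0) {
    n_spec <- round(spec$specular_fraction * npx)
    if (n_spec > 0) {
      pix <- sample.int(npx, n_spec)
      vals <- stats::runif(n_spec, 1.2, 1.9)
      cube[outer(pix, (seq_len(nb) - 1L) * npx, "+")] <-
        rep(vals, times = nb)
    }
  }
  cube <- pmin(pmax(cube, 0), 2)
  dim(cube) <- c(h, w, nb)

  regions_df <- data.frame(
    region_id = seq_along(spec$regions),
    tissue = vapply(spec$regions, `[[`, character(1), "class_id"),
    specimen_id = vapply(spec$regions, function(r) as.integer(r$specimen_id),
                         integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(cube = reflectance_cube(cube, wl), mask = mask,
                 region_mask = region_mask, regions = regions_df,
                 annotations = annotations, spec = spec),
            class = "nbi_scene")
}

#' Turn a rendered scene back into raw detector stacks
#'
#' Inverts the reflectance calibration with flat synthetic white and dark
#' references (I = D + R (W - D)), so that the calibration contract can be
#' exercised end to end on generated data.
#'
#' @param scene An `nbi_scene`.
#' @param white_level,dark_level Flat reference count levels.
#' @return List with `sample`, `white`, `dark` raw frame stacks.
#' @export
scene_to_raw_stacks <- function(scene, white_level = 0.9, dark_level = 0.05) {
  stopifnot(inherits(scene, "nbi_scene"), white_level > dark_level)
  d <- dim(scene$cube$data)
  wl <- scene$cube$wavelengths
  white <- array(white_level, d)
  dark <- array(dark_level, d)
  samp <- dark + scene$cube$data * (white - dark)
  list(
    sample = structure(list(frames = samp, wavelengths = wl, role = "SAMPLE"),
                       class = "raw_frame_stack"),
    white = structure(list(frames = white, wavelengths = wl, role = "WHITE"),
                      class = "raw_frame_stack"),
    dark = structure(list(frames = dark, wavelengths = wl, role = "DARK"),
                     class = "raw_frame_stack")
  )
}
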