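#' Tissue classes used throughout the package
#'
#' The four microsurgical tissue types handled by the pipeline, in the order
#' used for integer label masks (1..4; 0 is background/unlabelled).
#'
#' @return Character vector of class identifiers.
#' @export
tissue_classes <- function() {
  c("ICA_NORMAL", "ICA_PEELED", "FN_PROXIMAL", "FN_DISTAL")
}

#' Default wavelength grid
#'
#' Visible-range narrow-band scan from 400 to 720 nm in 2 nm steps (161
#' bands), the grid produced by a liquid crystal tunable filter sweep.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() {
  seq(400, 720, by = 2)
}

#' Construct a tissue spectrum model
#'
#' A smooth parametric reflectance curve over wavelength: a logistic rise
#' toward the red end plus Gaussian absorption dips, optionally shifted by a
#' planted additive contrast on a wavelength interval (used to encode the
#' difference between paired tissue conditions, e.g. intact vs. peeled
#' adventitia).
#'
#' @param class_id One of [tissue_classes()] or `"BACKGROUND"`.
#' @param offset Baseline reflectance (unitless, in \[0, 1\]).
#' @param amp Amplitude of the logistic rise.
#' @param mid Logistic midpoint wavelength (nm).
#' @param width Logistic width (nm).
#' @param dips List of `c(depth, center_nm, width_nm)` Gaussian dips.
#' @param effect_bands Optional `c(lo, hi)` wavelength interval (nm) on which
#'   this class is shifted relative to its paired class.
#' @param effect_size Additive reflectance shift applied on `effect_bands`.
#' @param sample_scale_sd Log-normal sd of the multiplicative between-specimen
#'   scatter (conserved curve shape, shifted level).
#' @return An object of class `tissue_spectrum_model`.
#' @export
tissue_spectrum_model <- function(class_id, offset, amp, mid, width,
                                  dips = list(), effect_bands = NULL,
                                  effect_size = 0, sample_scale_sd = 0.04) {
  if (!is.null(effect_bands)) {
    stopifnot(length(effect_bands) == 2, effect_bands[1] < effect_bands[2])
    if (effect_bands[1] < 400 || effect_bands[2] > 720) {
      stop("effect_bands must lie within [400, 720] nm")
    }
  }
  structure(
    list(class_id = class_id, offset = offset, amp = amp, mid = mid,
         width = width, dips = dips, effect_bands = effect_bands,
         effect_size = effect_size, sample_scale_sd = sample_scale_sd),
    class = "tissue_spectrum_model"
  )
}

#' Evaluate a tissue spectrum model on a wavelength grid
#'
#' @param model A [tissue_spectrum_model()].
#' @param wavelengths Wavelengths (nm).
#' @return Mean reflectance curve (unitless, clamped to \[0, 1\]).
#' @export
eval_spectrum_model <- function(model, wavelengths = default_wavelengths()) {
  stopifnot(inherits(model, "tissue_spectrum_model"))
  y <- model$offset + model$amp * stats::plogis((wavelengths - model$mid) / model$width)
  for (d in model$dips) {
    y <- y - d[1] * exp(-((wavelengths - d[2]) / d[3])^2)
  }
  if (!is.null(model$effect_bands) && model$effect_size != 0) {
    inside <- wavelengths >= model$effect_bands[1] & wavelengths <= model$effect_bands[2]
    y <- y + model$effect_size * inside
  }
  pmin(1, pmax(0, y))
}

#' Default spectrum models for the four tissue classes plus background
#'
#' The internal carotid artery (ICA) pair shares a base curve with the peeled
#' condition shifted upward in the blue end (400-480 nm); the facial nerve
#' (FN) pair shares a base curve with the distal condition shifted upward
#' across 500-700 nm. Artery and nerve base curves differ broadly, so the
#' across-tissue contrasts span most of the visible range. The background is
#' a dark constant (cardboard at reflectance 0.02).
#'
#' @param effect_size Additive contrast planted between the members of each
#'   tissue pair (unitless reflectance; the default keeps adjacent-band jumps
#'   below 0.05 while remaining detectable by the rank-test screen).
#' @param sample_scale_sd Between-specimen log-normal scatter sd.
#' @return Named list of [tissue_spectrum_model()] objects
#'   (`ICA_NORMAL`, `ICA_PEELED`, `FN_PROXIMAL`, `FN_DISTAL`, `BACKGROUND`).
#' @export
default_models <- function(effect_size = 0.04, sample_scale_sd = 0.04) {
  hb_dips <- list(c(0.06, 435, 18), c(0.05, 545, 15), c(0.05, 575, 12))
  list(
    ICA_NORMAL = tissue_spectrum_model(
      "ICA_NORMAL", offset = 0.10, amp = 0.45, mid = 580, width = 60,
      dips = hb_dips, sample_scale_sd = sample_scale_sd),
    ICA_PEELED = tissue_spectrum_model(
      "ICA_PEELED", offset = 0.10, amp = 0.45, mid = 580, width = 60,
      dips = hb_dips, effect_bands = c(400, 480), effect_size = effect_size,
      sample_scale_sd = sample_scale_sd),
    FN_PROXIMAL = tissue_spectrum_model(
      "FN_PROXIMAL", offset = 0.14, amp = 0.40, mid = 550, width = 55,
      dips = list(c(0.05, 430, 20), c(0.04, 560, 18)),
      sample_scale_sd = sample_scale_sd),
    FN_DISTAL = tissue_spectrum_model(
      "FN_DISTAL", offset = 0.14, amp = 0.40, mid = 550, width = 55,
      dips = list(c(0.05, 430, 20), c(0.04, 560, 18)),
      effect_bands = c(500, 700), effect_size = effect_size,
      sample_scale_sd = sample_scale_sd),
    BACKGROUND = tissue_spectrum_model(
      "BACKGROUND", offset = 0.02, amp = 0, mid = 560, width = 60,
      sample_scale_sd = 0)
  )
}

#' Apply a sample-level spectral anomaly to a reflectance curve
#'
#' Emulates the anomalies observed on individual specimens: atherosclerotic
#' plaque (higher reflectance with a distorted curve shape), overlapping
#' adventitia (uniformly lowered reflectance), and discoloration (curve
#' flattened toward its wavelength mean).
#'
#' @param curve Reflectance curve (one value per wavelength).
#' @param kind One of `"PLAQUE"`, `"OVERLAP"`, `"DISCOLORATION"`, `"NONE"`.
#' @param magnitude Anomaly strength; 0 is identity, 1 is the full effect
#'   (for `DISCOLORATION`, magnitude 1 flattens the curve completely).
#' @param wavelengths Wavelengths (nm), needed for the plaque shape term.
#' @return Modified curve, clamped to \[0, 1\].
#' @export
apply_anomaly <- function(curve, kind = c("NONE", "PLAQUE", "OVERLAP", "DISCOLORATION"),
                          magnitude = 0.5, wavelengths = default_wavelengths()) {
  kind <- match.arg(kind)
  stopifnot(length(curve) == length(wavelengths), magnitude >= 0)
  out <- switch(kind,
    NONE = curve,
    PLAQUE = curve * (1 + 0.6 * magnitude) +
      0.10 * magnitude * exp(-((wavelengths - 500) / 40)^2),
    OVERLAP = curve - 0.08 * magnitude,
    DISCOLORATION = {
      m <- mean(curve)
      m + (curve - m) * (1 - magnitude)
    }
  )
  pmin(1, pmax(0, out))
}
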