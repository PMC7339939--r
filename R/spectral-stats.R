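#' Max-normalize a spectrum
#'
#' Divides the spectral vector by its maximum value, so the normalized
#' spectrum peaks at 1. Used for comparable signature plots across specimens.
#'
#' @param values Reflectance values; at least one must be strictly positive.
#' @return Normalized values with `max(out) == 1`.
#' @export
normalize_spectrum <- function(values) {
  if (!all(is.finite(values))) stop("spectrum contains non-finite values")
  m <- max(values)
  if (m <= 0) stop("cannot normalize: no strictly positive value in spectrum")
  values / m
}

#' Extract disk-averaged spot spectra from labelled regions
#'
#' For every labelled region, samples `n_spots` spot centers (seeded,
#' reproducible) whose disks lie entirely inside the region and are at least
#' `2 * spot_radius` apart, and averages the cube spectrum over each disk.
#' This is the sampling unit of the screening statistics: with 4 classes,
#' 5 specimens and 4 spots it yields 80 spot spectra, i.e. 3,220 band values
#' per tissue type on the 161-band grid.
#'
#' @param cube A [reflectance_cube()].
#' @param region_mask Integer matrix of region indices (0 = background), as
#'   produced by [generate_scene()].
#' @param regions Data frame with `region_id`, `tissue`, `specimen_id`.
#' @param n_spots Spots per region.
#' @param spot_radius Disk radius in pixels.
#' @param seed Integer seed for spot placement.
#' @return Object of class `spectrum_samples`: list with `values`
#'   (samples x bands matrix), `wavelengths` and `meta` (data frame with
#'   `tissue`, `specimen_id`, `spot_id`, `region_id`).
#' @export
extract_sample_spectra <- function(cube, region_mask, regions, n_spots = 4,
                                   spot_radius = 2, seed = 1L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$data)
  stopifnot(all(dim(region_mask) == d[1:2]))
  offs <- expand.grid(dy = -spot_radius:spot_radius, dx = -spot_radius:spot_radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= spot_radius^2, ]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  values <- NULL
  meta <- NULL
  npx <- d[1] * d[2]
  band_off <- (seq_len(d[3]) - 1L) * npx
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    inreg <- region_mask == rid
    # candidate centers: disk fully inside the region
    cand <- inreg
    for (k in seq_len(nrow(offs))) {
      sh <- shift_logical(inreg, offs$dy[k], offs$dx[k])
      cand <- cand & sh
    }
    cand_idx <- which(cand)
    fail <- function() {
      stop("region ", rid, " (", regions$tissue[i], ", specimen ",
           regions$specimen_id[i], ") is too small for ", n_spots,
           " spots of radius ", spot_radius)
    }
    if (length(cand_idx) < n_spots) fail()
    centers <- integer(0)
    crow <- integer(0); ccol <- integer(0)
    tries <- 0
    while (length(centers) < n_spots) {
      tries <- tries + 1
      if (tries > 500 * n_spots) fail()
      pick <- cand_idx[sample.int(length(cand_idx), 1)]
      pr <- (pick - 1) %% d[1] + 1
      pc <- (pick - 1) %/% d[1] + 1
      if (length(centers) == 0 ||
          all(sqrt((crow - pr)^2 + (ccol - pc)^2) >= 2 * spot_radius)) {
        centers <- c(centers, pick)
        crow <- c(crow, pr); ccol <- c(ccol, pc)
      }
    }
    for (s in seq_len(n_spots)) {
      rr <- crow[s] + offs$dy
      cc <- ccol[s] + offs$dx
      pix <- (cc - 1) * d[1] + rr
      spec <- colMeans(matrix(cube$data[outer(pix, band_off, "+")],
                              nrow = length(pix)))
      values <- rbind(values, spec)
      meta <- rbind(meta, data.frame(tissue = regions$tissue[i],
                                     specimen_id = regions$specimen_id[i],
                                     spot_id = s, region_id = rid,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(values) <- NULL
  structure(list(values = values, wavelengths = cube$wavelengths, meta = meta),
            class = "spectrum_samples")
}

shift_logical <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rsrc <- seq_len(h) + dy
  csrc <- seq_len(w) + dx
  rok <- rsrc >= 1 & rsrc <= h
  cok <- csrc >= 1 & csrc <= w
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

#' Select the value matrix of one tissue group
#'
#' @param samples A `spectrum_samples` object.
#' @param tissue Tissue class to select.
#' @return Matrix (samples x bands).
#' @export
samples_for_tissue <- function(samples, tissue) {
  stopifnot(inherits(samples, "spectrum_samples"))
  sel <- samples$meta$tissue == tissue
  if (!any(sel)) stop("no samples of tissue ", tissue)
  samples$values[sel, , drop = FALSE]
}

#' Quartile descriptives using the weighted-average-at-(n+1)p rule
#'
#' Quartiles follow the SPSS convention (R's `quantile` type 6):
#' the p-quantile interpolates at position (n+1)p.
#'
#' @param x Numeric values (n >= 2).
#' @return List with `median`, `q1`, `q3`, `iqr`.
#' @export
descriptive_stats <- function(x) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Per-band group mean with t-based confidence half-width
#'
#' @param mat Matrix (samples x bands), n >= 2.
#' @param level Confidence level (default 0.95).
#' @return List with `mean` and `half_width` per band
#'   (mean +/- t(n-1, 1-(1-level)/2) * sd / sqrt(n)).
#' @export
group_mean_ci <- function(mat, level = 0.95) {
  n <- nrow(mat)
  if (is.null(n) || n < 2) stop("confidence interval requires n >= 2")
  m <- colMeans(mat)
  s <- apply(mat, 2, stats::sd)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = m, half_width = tq * s / sqrt(n))
}

#' Mann-Whitney U test per wavelength band
#'
#' Compares two groups of spot spectra band by band with the two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. P-values come from the exact
#' permutation distribution when both groups have at most `exact_max_n`
#' observations and there are no ties; otherwise from the normal
#' approximation with tie correction and continuity correction. The U
#' statistic is reported for group A. Per-band descriptives (SPSS-rule
#' quartiles, IQR, mean with 95% CI half-width) are included so the table
#' carries everything needed for range consolidation and CI curves.
#'
#' @param a,b Matrices (samples x bands) for the two groups; or numeric
#'   vectors for a single band.
#' @param wavelengths Wavelength axis (nm); defaults to band index.
#' @param exact_max_n Largest per-group n for which the exact distribution
#'   is used (default 8).
#' @param adjust P-value adjustment across bands passed to
#'   [stats::p.adjust()]; the default `"none"` reports uncorrected p-values
#'   (a `p_adjusted` column is added for any other method).
#' @param descriptives When `FALSE`, only `u` and `p` are computed (faster
#'   for large simulations).
#' @return A `band_table` data frame: one row per wavelength with `u`, `p`,
#'   group sizes, medians, quartiles, IQRs, means and CI half-widths.
#' @export
mann_whitney_per_band <- function(a, b, wavelengths = NULL, exact_max_n = 8,
                                  adjust = "none", descriptives = TRUE) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  if (ncol(a) != ncol(b)) stop("groups are on different wavelength grids")
  if (nrow(a) < 2 || nrow(b) < 2) stop("each group needs at least 2 samples")
  nb <- ncol(a)
  if (is.null(wavelengths)) wavelengths <- seq_len(nb)
  stopifnot(length(wavelengths) == nb)
  rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    x <- a[, k]; y <- b[, k]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && ((length(x) <= exact_max_n && length(y) <= exact_max_n) ||
                         length(x) + length(y) <= 12)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    if (descriptives) {
      da <- descriptive_stats(x); db <- descriptive_stats(y)
      rows[[k]] <- data.frame(
        wavelength = wavelengths[k],
        u = unname(wt$statistic), p = wt$p.value,
        n1 = length(x), n2 = length(y),
        median_a = da$median, q1_a = da$q1, q3_a = da$q3, iqr_a = da$iqr,
        median_b = db$median, q1_b = db$q1, q3_b = db$q3, iqr_b = db$iqr,
        mean_a = mean(x), ci_a = ci_half(x),
        mean_b = mean(y), ci_b = ci_half(y)
      )
    } else {
      rows[[k]] <- data.frame(
        wavelength = wavelengths[k],
        u = unname(wt$statistic), p = wt$p.value,
        n1 = length(x), n2 = length(y)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  }
  class(out) <- c("band_table", "data.frame")
  attr(out, "alpha_levels") <- c(0.05, 0.001)
  out
}

ci_half <- function(x, level = 0.95) {
  n <- length(x)
  stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
}

#' Shapiro-Wilk normality screen per band
#'
#' Tests each group's per-band distribution for normality. Bands where a
#' group is constant are flagged non-testable and excluded from the normal
#' ranges. Bands where both groups pass at `alpha` are consolidated into
#' contiguous normal ranges (same run logic as the significance ranges).
#'
#' @param a,b Matrices (samples x bands); group sizes must be >= 3.
#' @param wavelengths Wavelength axis (nm).
#' @param alpha Normality rejection level (default 0.05).
#' @param min_run Minimum run length (bands) for a reported range.
#' @return List with `p_a`, `p_b` (per-band p-values, NA when non-testable),
#'   `testable` (logical) and `normal_ranges` (data frame of contiguous
#'   intervals where both groups pass).
#' @export
shapiro_wilk_per_band <- function(a, b, wavelengths = NULL, alpha = 0.05,
                                  min_run = 2) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  if (ncol(a) != ncol(b)) stop("groups are on different wavelength grids")
  if (nrow(a) < 3 || nrow(b) < 3) stop("Shapiro-Wilk needs group sizes >= 3")
  nb <- ncol(a)
  if (is.null(wavelengths)) wavelengths <- seq_len(nb)
  sw <- function(x) {
    if (diff(range(x)) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }
  p_a <- apply(a, 2, sw)
  p_b <- apply(b, 2, sw)
  testable <- !is.na(p_a) & !is.na(p_b)
  normal <- testable & p_a >= alpha & p_b >= alpha
  ranges <- runs_to_ranges(normal, wavelengths, min_run)
  ranges$alpha <- NULL
  list(p_a = p_a, p_b = p_b, testable = testable, normal_ranges = ranges)
}

runs_to_ranges <- function(flag, wavelengths, min_run = 1) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(lambda_start = wavelengths[starts[keep]],
             lambda_end = wavelengths[ends[keep]],
             n_bands = r$lengths[keep],
             alpha = rep(NA_real_, sum(keep)))
}

#' Consolidate per-band p-values into significant wavelength ranges
#'
#' Reports maximal runs of consecutive measured bands with p below each
#' alpha level, as closed intervals \[first wavelength, last wavelength\].
#' A run already significant at the stricter level is reported at that level
#' only, not duplicated at the looser one. Runs shorter than `min_run` bands
#' are dropped (isolated single-band blips at 2 nm resolution are treated as
#' noise).
#'
#' @param band_table A `band_table` (needs `wavelength` and `p` columns), or
#'   any data frame with those columns.
#' @param alpha_levels Significance levels, loosest first (default 0.05 and
#'   0.001).
#' @param min_run Minimum run length in bands (default 2).
#' @return A `significant_ranges` data frame with `lambda_start`,
#'   `lambda_end`, `n_bands`, `alpha`, sorted by start wavelength; intervals
#'   are non-overlapping within each alpha.
#' @export
consolidate_ranges <- function(band_table, alpha_levels = c(0.05, 0.001),
                               min_run = 2) {
  stopifnot(all(c("wavelength", "p") %in% names(band_table)))
  p <- band_table$p
  wl <- band_table$wavelength
  alpha_levels <- sort(alpha_levels, decreasing = TRUE)
  claimed <- rep(FALSE, length(p))
  out <- NULL
  # stricter levels claim their bands first so runs are not duplicated
  for (alpha in rev(alpha_levels)) {
    sig <- !is.na(p) & p < alpha & !claimed
    rg <- runs_to_ranges(sig, wl, min_run)
    if (nrow(rg) > 0) {
      rg$alpha <- alpha
      out <- rbind(out, rg)
      for (i in seq_len(nrow(rg))) {
        claimed <- claimed | (wl >= rg$lambda_start[i] & wl <= rg$lambda_end[i])
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(lambda_start = numeric(0), lambda_end = numeric(0),
                      n_bands = integer(0), alpha = numeric(0))
  }
  out <- out[order(out$lambda_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("significant_ranges", "data.frame")
  out
}

#' Jaccard overlap between reported ranges and a target interval
#'
#' Measures, on a wavelength grid, how well a set of consolidated ranges
#' recovers a target interval: |covered bands in interval| / |covered bands
#' union interval bands|.
#'
#' @param ranges A `significant_ranges` data frame (or any with
#'   `lambda_start`, `lambda_end`).
#' @param interval `c(lo, hi)` target interval in nm.
#' @param wavelengths The measured wavelength grid.
#' @return Jaccard index in \[0, 1\].
#' @export
interval_jaccard <- function(ranges, interval, wavelengths) {
  covered <- rep(FALSE, length(wavelengths))
  for (i in seq_len(nrow(ranges))) {
    covered <- covered |
      (wavelengths >= ranges$lambda_start[i] & wavelengths <= ranges$lambda_end[i])
  }
  target <- wavelengths >= interval[1] & wavelengths <= interval[2]
  u <- sum(covered | target)
  if (u == 0) return(1)
  sum(covered & target) / u
}
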