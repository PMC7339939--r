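#' Savitzky-Golay spectral smoothing
#'
#' Local least-squares polynomial smoother: each value is replaced by the
#' centered polynomial fit over a sliding window, which reproduces
#' polynomials up to the fit order exactly. Edges are handled by evaluating
#' the terminal-window polynomial fits at the edge positions.
#'
#' @param spectrum Numeric vector, length >= `window`.
#' @param window Odd window length in bands (default 11).
#' @param polyorder Polynomial order, < `window` (default 3).
#' @return Smoothed spectrum, same length.
#' @export
savitzky_golay <- function(spectrum, window = 11, polyorder = 3) {
  if (window %% 2 == 0 || window < 1) stop("window must be odd and positive")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (length(spectrum) < window) {
    stop("spectrum shorter (", length(spectrum), ") than window (", window, ")")
  }
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

#' Inter-band affinity matrix
#'
#' Pairwise similarity between band images: entry (i, j) is the Pearson
#' correlation between band i and band j over the labelled pixels (or over
#' the rows of a plain observation matrix). The per-band similarity
#' coefficient used for pruning is the mean off-diagonal affinity of the
#' band. Constant (degenerate) bands get affinity 1 to every band and are
#' flagged.
#'
#' @param x Matrix (observations x bands), or a [reflectance_cube()] (then
#'   `mask` selects labelled pixels).
#' @param mask Optional label matrix; pixels with `mask > 0` are used.
#' @return Object of class `affinity_matrix`: symmetric matrix with unit
#'   diagonal, attribute `degenerate` flags constant bands.
#' @export
band_affinity <- function(x, mask = NULL) {
  if (inherits(x, "reflectance_cube")) {
    d <- dim(x$data)
    m <- matrix(x$data, d[1] * d[2], d[3])
    if (!is.null(mask)) m <- m[as.vector(mask > 0), , drop = FALSE]
    wl <- x$wavelengths
    x <- m
  } else {
    wl <- NULL
  }
  if (ncol(x) < 2) stop("affinity needs at least 2 bands")
  degenerate <- apply(x, 2, function(col) diff(range(col)) == 0)
  aff <- suppressWarnings(stats::cor(x))
  aff[degenerate, ] <- 1
  aff[, degenerate] <- 1
  diag(aff) <- 1
  structure(aff, degenerate = degenerate, wavelengths = wl,
            class = c("affinity_matrix", "matrix", "array"))
}

#' Prune the bands with the highest similarity coefficients
#'
#' Bands are ranked by mean off-diagonal affinity (descending); the top
#' `1 - keep_fraction` share is excluded to increase the visibility of
#' spectral differences and reduce dimensionality. Ties are broken toward
#' keeping the lower wavelength.
#'
#' @param affinity An [band_affinity()] matrix.
#' @param keep_fraction Fraction of bands to retain, in (0, 1\];
#'   `ceiling(keep_fraction * B)` bands are kept.
#' @param wavelengths Optional wavelength axis for labelling the output.
#' @return List with `kept` (band indices, ascending), `excluded`,
#'   `similarity` (per-band mean off-diagonal affinity) and
#'   `kept_wavelengths` when wavelengths are known.
#' @export
prune_similar_bands <- function(affinity, keep_fraction = 0.75,
                                wavelengths = NULL) {
  if (!is.matrix(affinity) || nrow(affinity) != ncol(affinity)) {
    stop("affinity must be a square matrix")
  }
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  if (is.null(wavelengths)) wavelengths <- attr(affinity, "wavelengths")
  B <- ncol(affinity)
  sim <- (rowSums(affinity) - diag(affinity)) / (B - 1)
  n_keep <- ceiling(keep_fraction * B)
  ord <- order(sim, seq_len(B))  # ascending similarity; ties keep lower wavelength
  kept <- sort(ord[seq_len(n_keep)])
  out <- list(kept = kept, excluded = sort(setdiff(seq_len(B), kept)),
              similarity = sim)
  if (!is.null(wavelengths)) out$kept_wavelengths <- wavelengths[kept]
  out
}

#' Per-wavelength divergence between class mean spectra
#'
#' Compares class mean spectra wavelength by wavelength: the score at each
#' band is the absolute mean difference, so it highlights which bands
#' separate the classes best. With more than two classes the scores are
#' summed over all class pairs.
#'
#' @param means A list of >= 2 class mean vectors, or a matrix with one row
#'   per class.
#' @return Non-negative divergence score per band.
#' @export
divergence_per_band <- function(means) {
  if (is.matrix(means)) means <- asplit(means, 1)
  if (length(means) < 2) stop("divergence needs at least 2 class means")
  len <- vapply(means, length, integer(1))
  if (any(len != len[1])) stop("class means are on different wavelength grids")
  score <- numeric(len[1])
  nm <- length(means)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      score <- score + abs(means[[i]] - means[[j]])
    }
  }
  as.numeric(score)
}

#' Exclude outlier samples by robust z-score of spectral area
#'
#' The divergence-based selection is sensitive to anomalous samples (e.g.
#' plaque formation), so per tissue class, samples whose spectral area (sum
#' of reflectance over bands) has a modified z-score beyond `threshold_mad`
#' are excluded. The modified z-score is 0.6745 (x - median) / MAD; when the
#' MAD is zero it falls back to the mean absolute deviation
#' (x - median) / (1.253314 madAD), the Iglewicz-Hoaglin convention.
#'
#' @param samples A `spectrum_samples` object.
#' @param threshold_mad Exclusion threshold on |modified z| (default 3.5).
#' @return List with `kept` (a `spectrum_samples` object) and `excluded`
#'   (data frame of dropped samples with their areas and scores).
#' @export
exclude_outlier_samples <- function(samples, threshold_mad = 3.5) {
  stopifnot(inherits(samples, "spectrum_samples"))
  area <- rowSums(samples$values)
  drop <- rep(FALSE, length(area))
  score <- rep(0, length(area))
  for (cl in unique(samples$meta$tissue)) {
    sel <- which(samples$meta$tissue == cl)
    if (length(sel) < 3) {
      warning("class ", cl, " has fewer than 3 samples; no exclusion applied")
      next
    }
    a <- area[sel]
    med <- stats::median(a)
    mad_ <- stats::median(abs(a - med))
    z <- if (mad_ > 0) {
      0.6745 * (a - med) / mad_
    } else {
      mean_ad <- mean(abs(a - med))
      if (mean_ad > 0) (a - med) / (1.253314 * mean_ad) else rep(0, length(a))
    }
    score[sel] <- z
    drop[sel] <- abs(z) > threshold_mad
  }
  excluded <- cbind(samples$meta[drop, , drop = FALSE],
                    area = area[drop], score = score[drop])
  rownames(excluded) <- NULL
  kept <- structure(list(values = samples$values[!drop, , drop = FALSE],
                         wavelengths = samples$wavelengths,
                         meta = samples$meta[!drop, , drop = FALSE]),
                    class = "spectrum_samples")
  list(kept = kept, excluded = excluded)
}

#' Select an optimal band subset for segmentation
#'
#' Pipeline: Savitzky-Golay smoothing of the class mean spectra, affinity
#' pruning of the most mutually similar bands, then per-wavelength
#' divergence ranking (summed over all class pairs) on the retained bands;
#' the top `n_select` bands by divergence are returned, ties broken toward
#' the lower wavelength. Deterministic for a fixed input.
#'
#' @param cube A [reflectance_cube()].
#' @param mask Integer class label matrix (0 = background); >= 2 labelled
#'   classes required.
#' @param n_select Number of bands to select (default 68, the pipeline's
#'   operating point out of 161).
#' @param keep_fraction Fraction retained by affinity pruning (default 0.75).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters for the class
#'   means; `sg_window = NULL` disables smoothing.
#' @return Object of class `band_subset`: data frame with `wavelength`,
#'   `band_index`, `score` in rank order, with a `provenance` attribute.
#' @export
select_optimal_bands <- function(cube, mask, n_select = 68,
                                 keep_fraction = 0.75,
                                 sg_window = 11, sg_polyorder = 3) {
  stopifnot(inherits(cube, "reflectance_cube"))
  classes <- sort(unique(mask[mask > 0]))
  if (length(classes) < 2) stop("band selection needs at least 2 labelled classes")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  means <- lapply(classes, function(cl) colMeans(flat[as.vector(mask == cl), , drop = FALSE]))
  if (!is.null(sg_window)) {
    means <- lapply(means, savitzky_golay, window = sg_window,
                    polyorder = sg_polyorder)
  }
  aff <- band_affinity(cube, mask)
  pruned <- prune_similar_bands(aff, keep_fraction, cube$wavelengths)
  if (n_select > length(pruned$kept)) {
    stop("n_select (", n_select, ") exceeds the ", length(pruned$kept),
         " bands retained by affinity pruning; increase keep_fraction")
  }
  score <- divergence_per_band(means)
  kept <- pruned$kept
  ord <- kept[order(-score[kept], kept)]  # divergence desc, ties to lower wavelength
  sel <- ord[seq_len(n_select)]
  out <- data.frame(wavelength = cube$wavelengths[sel], band_index = sel,
                    score = score[sel])
  class(out) <- c("band_subset", "data.frame")
  attr(out, "provenance") <- list(
    pruned_by_affinity = cube$wavelengths[pruned$excluded],
    ranked_by_divergence = TRUE,
    keep_fraction = keep_fraction, n_select = n_select,
    sg_window = sg_window, sg_polyorder = sg_polyorder,
    zero_ranking = all(score[kept] == 0)
  )
  out
}

#' Serialize a band subset to JSON
#'
#' @param subset A `band_subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_subset <- function(subset, path) {
  prov <- attr(subset, "provenance")
  jsonlite::write_json(
    list(wavelengths = subset$wavelength, band_index = subset$band_index,
         score = subset$score, provenance = prov),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
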