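#' Construct a reflectance cube
#'
#' A 3D array (rows x cols x bands) of unitless reflectance with its
#' wavelength axis.
#'
#' @param data 3D numeric array.
#' @param wavelengths Wavelengths (nm), strictly increasing, one per band.
#' @return Object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(data, wavelengths) {
  stopifnot(length(dim(data)) == 3)
  if (length(wavelengths) != dim(data)[3]) {
    stop("wavelengths length (", length(wavelengths),
         ") does not match band count (", dim(data)[3], ")")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("reflectance_cube: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Restrict a cube to a band subset
#'
#' @param cube A [reflectance_cube()].
#' @param wavelengths Wavelengths to keep (must all be on the cube grid);
#'   kept in the order given.
#' @return A `reflectance_cube` with only the requested bands.
#' @export
subset_bands <- function(cube, wavelengths) {
  idx <- match(wavelengths, cube$wavelengths)
  if (anyNA(idx)) {
    stop("wavelengths not on the cube grid: ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  }
  structure(list(data = cube$data[, , idx, drop = FALSE],
                 wavelengths = as.numeric(wavelengths)),
            class = "reflectance_cube")
}

read_gray_frame <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported frame format: ", path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]  # collapse grayscale-as-RGB
  img
}

#' Read a narrow-band frame stack
#'
#' Assembles per-band grayscale detector frames into a raw stack ordered by
#' ascending wavelength, regardless of the order in which the files are
#' listed. Input is either a multi-page TIFF (with `wavelengths` giving the
#' page order) or a directory/vector of per-band PNG/TIFF files with a
#' manifest mapping each file to its wavelength.
#'
#' @param path Path to a multi-page TIFF, or a directory of frames, or a
#'   character vector of frame paths.
#' @param manifest Data frame with columns `file` and `wavelength` (nm); not
#'   needed for a multi-page TIFF.
#' @param wavelengths For a multi-page TIFF: wavelengths in page order.
#' @param role One of `"SAMPLE"`, `"WHITE"`, `"DARK"`.
#' @return Object of class `raw_frame_stack`: list with `frames` (3D array,
#'   rows x cols x bands), `wavelengths`, `role`.
#' @export
read_frame_stack <- function(path, manifest = NULL, wavelengths = NULL,
                             role = c("SAMPLE", "WHITE", "DARK")) {
  role <- match.arg(role)
  if (length(path) == 1 && grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.null(wavelengths)) stop("wavelengths required for a multi-page TIFF")
    if (length(pages) != length(wavelengths)) {
      stop("page count (", length(pages), ") does not match wavelengths (",
           length(wavelengths), ")")
    }
    frames <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    wl <- as.numeric(wavelengths)
  } else {
    files <- if (length(path) == 1 && dir.exists(path)) {
      file.path(path, manifest$file)
    } else if (!is.null(manifest)) {
      manifest$file
    } else {
      as.character(path)
    }
    if (is.null(manifest)) stop("a manifest mapping files to wavelengths is required")
    if (length(files) != nrow(manifest)) stop("manifest/file count mismatch")
    missing <- !file.exists(files)
    if (any(missing)) {
      stop("missing band frame(s): ", paste(basename(files[missing]), collapse = ", "))
    }
    frames <- lapply(files, read_gray_frame)
    wl <- as.numeric(manifest$wavelength)
  }
  if (anyDuplicated(wl)) {
    stop("duplicate wavelength(s): ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "))
  }
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent frame dimensions across bands")
  }
  ord <- order(wl)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(frames)))
  for (k in seq_along(ord)) arr[, , k] <- frames[[ord[k]]]
  if (any(arr < 0)) stop("negative detector counts")
  structure(list(frames = arr, wavelengths = wl[ord], role = role),
            class = "raw_frame_stack")
}

#' Calibrate a raw stack to reflectance with white and dark references
#'
#' Computes per band, per pixel, R = (I - D) / (W - D), where I is the sample
#' stack and W, D the white and dark reference stacks acquired with identical
#' exposure times. Pixels where W - D is at or below a small epsilon (1e-6 of
#' the white dynamic range) are set to 0 and tallied; output is clipped to
#' `[0, clip_max]` (reflectance above 1 is retained up to `clip_max` so that
#' specular grain survives calibration).
#'
#' @param sample,white,dark `raw_frame_stack` objects sharing dimensions and
#'   wavelengths.
#' @param clip_max Upper clip for reflectance (default 2).
#' @return A [reflectance_cube()] with attributes `n_invalid` (invalid-pixel
#'   tally) and `invalid_per_band`.
#' @export
calibrate_reflectance <- function(sample, white, dark, clip_max = 2) {
  for (s in list(sample, white, dark)) stopifnot(inherits(s, "raw_frame_stack"))
  if (!isTRUE(all.equal(sample$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(sample$wavelengths, dark$wavelengths))) {
    stop("wavelength mismatch between sample and reference stacks")
  }
  if (!identical(dim(sample$frames), dim(white$frames)) ||
      !identical(dim(sample$frames), dim(dark$frames))) {
    stop("dimension mismatch between sample and reference stacks")
  }
  denom <- white$frames - dark$frames
  eps <- 1e-6 * diff(range(white$frames))
  if (eps == 0) eps <- 1e-12
  invalid <- denom <= eps
  r <- (sample$frames - dark$frames) / denom
  r[invalid] <- 0
  r <- pmin(pmax(r, 0), clip_max)
  dim(r) <- dim(sample$frames)
  nb <- dim(r)[3]
  inv_band <- vapply(seq_len(nb), function(k) sum(invalid[, , k]), integer(1))
  all_bad <- inv_band == prod(dim(r)[1:2])
  if (any(all_bad)) {
    warning("band(s) with no valid reference signal retained as zeros: ",
            paste(sample$wavelengths[all_bad], collapse = ", "), " nm")
  }
  cube <- reflectance_cube(r, sample$wavelengths)
  attr(cube, "n_invalid") <- sum(inv_band)
  attr(cube, "invalid_per_band") <- inv_band
  cube
}

#' Write / read a reflectance cube (binary container + JSON sidecar)
#'
#' The cube is stored as little-endian doubles in `<path>` with a JSON
#' sidecar `<path>.json` carrying shape, wavelengths and dtype; the
#' round-trip is lossless.
#'
#' @param cube A [reflectance_cube()].
#' @param path Output path for the binary payload.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "reflectance_cube"))
  sidecar <- list(shape = dim(cube$data), dtype = "float64",
                  wavelengths = cube$wavelengths)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  shape <- as.integer(sc$shape)
  if (length(shape) != 3) stop("sidecar shape must have 3 dimensions")
  n <- prod(shape)
  if (length(sc$wavelengths) != shape[3]) {
    stop("sidecar wavelengths length (", length(sc$wavelengths),
         ") does not match band count (", shape[3], ")")
  }
  expected_bytes <- n * 8
  if (file.info(path)$size != expected_bytes) {
    stop("payload size does not match sidecar shape")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  reflectance_cube(array(vals, shape), sc$wavelengths)
}
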