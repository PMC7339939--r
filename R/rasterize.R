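#' Even-odd point-in-polygon test at pixel centers
#'
#' Coordinate convention: x = column, y = row, 0-based, pixel centers at
#' integer coordinates (the VGG Image Annotator export convention). Points
#' exactly on a polygon edge or vertex count as inside.
#'
#' @param poly Numeric matrix with columns x, y (>= 3 vertices).
#' @param image_shape `c(rows, cols)`.
#' @return Logical matrix (rows x cols), TRUE where the pixel center is
#'   inside the polygon under the even-odd rule.
#' @keywords internal
polygon_pixels <- function(poly, image_shape) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  if (nrow(poly) < 3) stop("malformed polygon: fewer than 3 vertices")
  h <- image_shape[1]; w <- image_shape[2]
  px <- rep(0:(w - 1), each = h)   # column-major over (row, col)
  py <- rep(0:(h - 1), times = w)
  inside <- rep(FALSE, h * w)
  boundary <- rep(FALSE, h * w)
  n <- nrow(poly)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    # even-odd ray crossing (ray toward +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xin <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xin))
    }
    # on-segment test (boundary pixels are inside)
    dx <- x2 - x1; dy <- y2 - y1
    seg2 <- dx * dx + dy * dy
    if (seg2 < eps) {
      boundary <- boundary | (abs(px - x1) < eps & abs(py - y1) < eps)
    } else {
      t <- ((px - x1) * dx + (py - y1) * dy) / seg2
      projx <- x1 + t * dx; projy <- y1 + t * dy
      on_seg <- t >= -eps & t <= 1 + eps &
        abs(px - projx) < eps & abs(py - projy) < eps
      boundary <- boundary | on_seg
    }
  }
  matrix(inside | boundary, nrow = h, ncol = w)
}

#' Rasterize labelled polygons into an integer label mask
#'
#' Polygons are filled with the even-odd rule at pixel centers; pixel centers
#' on a boundary are inside. When regions overlap, later regions overwrite
#' earlier ones and a warning names the colliding regions (unless
#' `on_overlap = "error"`, in which case overlap is an error).
#'
#' @param annotations An annotation set: list of regions, each a list with
#'   `region_label` (class string) and `polygon` (matrix of x, y vertices).
#' @param image_shape `c(rows, cols)`.
#' @param class_palette Character vector of allowed class labels; label k in
#'   the mask corresponds to `class_palette[k]`.
#' @param on_overlap `"warn"` (last region wins, warning) or `"error"`.
#' @return Integer matrix (rows x cols), 0 = unlabelled/background.
#' @export
rasterize_annotations <- function(annotations, image_shape,
                                  class_palette = tissue_classes(),
                                  on_overlap = c("warn", "error")) {
  on_overlap <- match.arg(on_overlap)
  mask <- matrix(0L, image_shape[1], image_shape[2])
  owner <- matrix(0L, image_shape[1], image_shape[2])
  for (k in seq_along(annotations)) {
    reg <- annotations[[k]]
    lab <- match(reg$region_label, class_palette)
    if (is.na(lab)) {
      stop("unknown class label '", reg$region_label, "'; allowed: ",
           paste(class_palette, collapse = ", "))
    }
    poly <- reg$polygon
    if (any(poly[, 1] < 0 | poly[, 1] > image_shape[2] - 1 |
            poly[, 2] < 0 | poly[, 2] > image_shape[1] - 1)) {
      stop("polygon of region ", k, " has vertices outside the image bounds")
    }
    inside <- polygon_pixels(poly, image_shape)
    clash <- inside & owner > 0L
    if (any(clash)) {
      msg <- paste0("regions ", paste(unique(owner[clash]), collapse = ","),
                    " and ", k, " overlap on ", sum(clash), " pixel(s)")
      if (on_overlap == "error") stop(msg)
      warning(msg, "; later region overwrites")
    }
    mask[inside] <- lab
    owner[inside] <- k
  }
  attr(mask, "region_owner") <- owner
  mask
}
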