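#' Write an annotation set as VGG Image Annotator (VIA v2) JSON
#'
#' Emits the VIA v2 project-export dialect: one entry per image keyed by
#' `filename + size`, with polygon `shape_attributes` (`all_points_x`,
#' `all_points_y`) and the tissue class in `region_attributes$tissue`
#' (plus `specimen` when present).
#'
#' @param annotations Annotation set: list of regions, each with
#'   `region_label`, `polygon` (matrix x, y) and optionally `specimen_id`.
#' @param image_shape `c(rows, cols)`.
#' @param path Optional file to write; when `NULL` the JSON text is returned.
#' @param filename Image filename recorded in the export.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_via_annotations <- function(annotations, image_shape, path = NULL,
                                  filename = "scene.png") {
  regions <- lapply(annotations, function(reg) {
    ra <- list(tissue = reg$region_label)
    if (!is.null(reg$specimen_id)) ra$specimen <- reg$specimen_id
    list(
      shape_attributes = list(
        name = "polygon",
        all_points_x = as.numeric(reg$polygon[, 1]),
        all_points_y = as.numeric(reg$polygon[, 2])
      ),
      region_attributes = ra
    )
  })
  size <- image_shape[1] * image_shape[2]
  doc <- list()
  doc[[paste0(filename, size)]] <- list(
    filename = filename, size = size,
    regions = regions, file_attributes = structure(list(), names = character())
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read VIA v2 polygon annotations and rasterize them to a label mask
#'
#' @param json_text VIA v2 export JSON text, or a path to a `.json` file.
#' @param image_shape `c(rows, cols)` of the annotated image.
#' @param class_palette Allowed class labels; mask label k corresponds to
#'   `class_palette[k]`.
#' @return List with `annotations` (the annotation set) and `mask`
#'   (integer label matrix from [rasterize_annotations()]).
#' @export
read_via_annotations <- function(json_text, image_shape,
                                 class_palette = tissue_classes()) {
  if (length(json_text) == 1 && !grepl("[{]", json_text) && file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  if (length(doc) == 0) {
    return(list(annotations = list(),
                mask = matrix(0L, image_shape[1], image_shape[2])))
  }
  entry <- doc[[1]]
  annotations <- lapply(entry$regions, function(r) {
    sa <- r$shape_attributes
    if (!identical(sa$name, "polygon")) {
      stop("unsupported region shape: ", sa$name)
    }
    xs <- unlist(sa$all_points_x)
    ys <- unlist(sa$all_points_y)
    if (length(xs) < 3) stop("malformed polygon: fewer than 3 vertices")
    lab <- r$region_attributes$tissue
    if (is.null(lab)) stop("region missing 'tissue' attribute")
    if (!lab %in% class_palette) {
      stop("unknown class label '", lab, "'; allowed: ",
           paste(class_palette, collapse = ", "))
    }
    out <- list(region_label = lab, polygon = cbind(x = xs, y = ys))
    if (!is.null(r$region_attributes$specimen)) {
      out$specimen_id <- r$region_attributes$specimen
    }
    out
  })
  mask <- rasterize_annotations(annotations, image_shape, class_palette)
  attr(mask, "region_owner") <- NULL
  list(annotations = annotations, mask = mask)
}
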