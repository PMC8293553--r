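#' Fill enclosed holes in a binary mask
#'
#' Any background region not connected to the image border (background uses
#' 4-connectivity, the dual of the 8-connected foreground) is turned into
#' foreground, so a ring-shaped detection is measured at its filled area.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return Logical matrix of the same size; always a superset of the input.
#' @export
fill_holes <- function(mask) {
  check_mask(mask)
  out <- fill_holes_cpp(mask)
  dimnames(out) <- dimnames(mask)
  out
}

#' Label connected foreground components
#'
#' Foreground connectivity is 8: diagonally touching blobs merge into one
#' component, which is why very close tubercles can be counted as a single
#' particle. Component ids follow the raster order (top-to-bottom, then
#' left-to-right) of each component's first pixel.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  label_components_cpp(mask)
}

#' Extract particles from a binary mask
#'
#' Connected components of the mask are measured (pixel area, area in mm²
#' through the scale calibration, binary centre of mass, bounding box) and
#' filtered to the inclusive area band `[min_mm2, max_mm2]`. Centroids are the
#' unweighted means of the component's 0-based pixel coordinates, reported in
#' millimetres relative to the mask (crop) origin.
#'
#' @param mask Logical matrix, typically the hole-filled threshold mask.
#' @param cal A [scale_calibration()].
#' @param size A [size_range()] in mm².
#' @param class_label Class tag given to every emitted particle.
#' @return A `particle_set` data frame with columns `particle_id`, `class`,
#'   `area_mm2`, `area_px`, `centroid_x_mm`, `centroid_y_mm`, `centroid_x_px`,
#'   `centroid_y_px`, `bbox_x`, `bbox_y`, `bbox_w`, `bbox_h`. Ids are assigned
#'   in raster order of each surviving component's first pixel.
#' @export
find_particles <- function(mask, cal, size, class_label = "tubercle") {
  check_mask(mask)
  stopifnot(inherits(cal, "scale_calibration"), inherits(size, "size_range"))
  lab <- label_components_cpp(mask)
  n <- attr(lab, "n_components")
  if (n == 0L) return(empty_particle_set())

  h <- nrow(lab)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  x0 <- (idx - 1L) %/% h   # 0-based column
  y0 <- (idx - 1L) %% h    # 0-based row
  area_px <- tabulate(comp, nbins = n)
  sum_x <- as.vector(rowsum(x0, comp))
  sum_y <- as.vector(rowsum(y0, comp))
  bbx0 <- tapply_range(x0, comp, n, min)
  bby0 <- tapply_range(y0, comp, n, min)
  bbx1 <- tapply_range(x0, comp, n, max)
  bby1 <- tapply_range(y0, comp, n, max)

  area_mm2 <- area_px * cal$pixel_area_mm2
  keep <- which(area_mm2 >= size$min_mm2 & area_mm2 <= size$max_mm2)
  if (length(keep) == 0L) return(empty_particle_set())

  cx_px <- sum_x[keep] / area_px[keep]
  cy_px <- sum_y[keep] / area_px[keep]
  particle_set(data.frame(
    particle_id = seq_along(keep),
    class = class_label,
    area_mm2 = area_mm2[keep],
    area_px = as.integer(area_px[keep]),
    centroid_x_mm = cx_px / cal$px_per_mm,
    centroid_y_mm = cy_px / cal$px_per_mm,
    centroid_x_px = cx_px,
    centroid_y_px = cy_px,
    bbox_x = as.integer(bbx0[keep]),
    bbox_y = as.integer(bby0[keep]),
    bbox_w = as.integer(bbx1[keep] - bbx0[keep] + 1L),
    bbox_h = as.integer(bby1[keep] - bby0[keep] + 1L),
    stringsAsFactors = FALSE
  ))
}

tapply_range <- function(v, g, n, f) {
  out <- rep(NA_integer_, n)
  agg <- vapply(split(v, g), f, numeric(1))
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

particle_set <- function(df, image_id = NA_character_) {
  structure(df, class = c("particle_set", "data.frame"), image_id = image_id)
}

empty_particle_set <- function(image_id = NA_character_) {
  particle_set(data.frame(
    particle_id = integer(), class = character(), area_mm2 = numeric(),
    area_px = integer(), centroid_x_mm = numeric(), centroid_y_mm = numeric(),
    centroid_x_px = numeric(), centroid_y_px = numeric(),
    bbox_x = integer(), bbox_y = integer(), bbox_w = integer(),
    bbox_h = integer(), stringsAsFactors = FALSE
  ), image_id = image_id)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_rz("expected a logical matrix mask", class = "mask_format")
  }
  if (anyNA(mask)) stop_rz("mask contains NA", class = "mask_format")
  invisible(TRUE)
}
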