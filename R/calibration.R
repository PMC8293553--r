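#' Calibrate the pixel-to-millimetre scale
#'
#' Converts a ruler measurement (a line of known physical length drawn on the
#' image) into a scale calibration. All particle areas and centroid positions
#' downstream are reported in millimetres via this factor, so counting is
#' independent of image resolution.
#'
#' @param line_length_px Length of the drawn calibration line, in pixels.
#' @param known_length_mm Physical length of the same line, in millimetres.
#' @return A `scale_calibration` object with fields `px_per_mm` and
#'   `pixel_area_mm2` (the area of one pixel, `(1/px_per_mm)^2`).
#' @examples
#' cal <- calibrate_scale(1100, 50)  # 1100 px span a 50 mm ruler
#' cal$px_per_mm                     # 22
#' @export
calibrate_scale <- function(line_length_px, known_length_mm) {
  if (!is.numeric(line_length_px) || length(line_length_px) != 1L ||
      !is.finite(line_length_px) || line_length_px <= 0 ||
      !is.numeric(known_length_mm) || length(known_length_mm) != 1L ||
      !is.finite(known_length_mm) || known_length_mm <= 0) {
    stop_rz("scale calibration needs strictly positive line_length_px and known_length_mm",
            class = "invalid_calibration")
  }
  scale_calibration(line_length_px / known_length_mm)
}

#' Construct a scale calibration from a known pixels-per-mm factor
#'
#' @param px_per_mm Pixels per millimetre; must be a positive finite scalar.
#' @return A `scale_calibration` object.
#' @export
scale_calibration <- function(px_per_mm) {
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L ||
      !is.finite(px_per_mm) || px_per_mm <= 0) {
    stop_rz("px_per_mm must be a positive finite number", class = "invalid_calibration")
  }
  structure(
    list(px_per_mm = as.numeric(px_per_mm),
         pixel_area_mm2 = (1 / as.numeric(px_per_mm))^2),
    class = "scale_calibration"
  )
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("Scale calibration: %.6g px/mm (pixel area %.6g mm^2)\n",
              x$px_per_mm, x$pixel_area_mm2))
  invisible(x)
}

#' Axis-aligned crop rectangle
#'
#' Coordinates are 0-based with the origin at the top-left corner, x running
#' rightward and y downward, matching the convention of the desktop imaging
#' tools this pipeline mirrors.
#'
#' @param x,y Top-left corner of the rectangle, in pixels (0-based).
#' @param width,height Rectangle size in pixels; both strictly positive.
#' @return A `crop_rect` object.
#' @export
crop_rect <- function(x, y, width, height) {
  v <- c(x = x, y = y, width = width, height = height)
  if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)) ||
      any(v != round(v))) {
    stop_rz("crop rectangle fields must be finite integers", class = "invalid_crop")
  }
  if (x < 0 || y < 0) stop_rz("crop origin must be non-negative", class = "invalid_crop")
  if (width <= 0 || height <= 0) {
    stop_rz("crop width and height must be positive", class = "invalid_crop")
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "crop_rect")
}

#' Crop an RGB image to a rectangle
#'
#' @param image An RGB image array of dimension height x width x 3.
#' @param rect A [crop_rect()]; must lie entirely within the image.
#' @return The cropped image; pixel (0,0) of the output is pixel
#'   (`rect$x`, `rect$y`) of the input.
#' @export
crop_image <- function(image, rect) {
  check_rgb_image(image)
  stopifnot(inherits(rect, "crop_rect"))
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (rect$x + rect$width > w) {
    stop_rz("crop rectangle exceeds the right image edge (x + width = %d > %d)",
            rect$x + rect$width, w, class = "crop_bounds")
  }
  if (rect$y + rect$height > h) {
    stop_rz("crop rectangle exceeds the bottom image edge (y + height = %d > %d)",
            rect$y + rect$height, h, class = "crop_bounds")
  }
  image[(rect$y + 1L):(rect$y + rect$height),
        (rect$x + 1L):(rect$x + rect$width), , drop = FALSE]
}

#' HSB colour band
#'
#' Inclusive per-channel bounds on 8-bit hue, saturation and brightness
#' (each 0-255). Hue is circular: `h_min > h_max` denotes a band that wraps
#' through 255 -> 0, so red-centred bands remain expressible. Saturation and
#' brightness bounds must be ordered.
#'
#' @param h_min,h_max,s_min,s_max,b_min,b_max Integers in \[0, 255\].
#' @return An `hsb_range` object.
#' @examples
#' hsb_range(0, 55, 102, 255, 95, 255)  # the orange-tubercle band
#' @export
hsb_range <- function(h_min, h_max, s_min, s_max, b_min, b_max) {
  v <- c(h_min, h_max, s_min, s_max, b_min, b_max)
  if (!is.numeric(v) || length(v) != 6L || any(!is.finite(v)) ||
      any(v != round(v)) || any(v < 0) || any(v > 255)) {
    stop_rz("HSB band bounds must be integers in [0, 255]", class = "invalid_band")
  }
  if (s_min > s_max) stop_rz("s_min must not exceed s_max", class = "invalid_band")
  if (b_min > b_max) stop_rz("b_min must not exceed b_max", class = "invalid_band")
  structure(list(h_min = as.integer(h_min), h_max = as.integer(h_max),
                 s_min = as.integer(s_min), s_max = as.integer(s_max),
                 b_min = as.integer(b_min), b_max = as.integer(b_max)),
            class = "hsb_range")
}

#' Particle size filter in square millimetres
#'
#' Both bounds are inclusive: a particle of exactly `min_mm2` or `max_mm2`
#' is kept.
#'
#' @param min_mm2 Smallest accepted particle area (>= 0).
#' @param max_mm2 Largest accepted particle area (> `min_mm2`).
#' @return A `size_range` object.
#' @export
size_range <- function(min_mm2, max_mm2) {
  if (!is.numeric(min_mm2) || !is.numeric(max_mm2) ||
      length(min_mm2) != 1L || length(max_mm2) != 1L ||
      !is.finite(min_mm2) || !is.finite(max_mm2) ||
      min_mm2 < 0 || max_mm2 <= min_mm2) {
    stop_rz("size range needs 0 <= min_mm2 < max_mm2", class = "invalid_size_range")
  }
  structure(list(min_mm2 = as.numeric(min_mm2), max_mm2 = as.numeric(max_mm2)),
            class = "size_range")
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop_rz("expected an RGB image array of dimension height x width x 3 (got %s)",
            paste(dim(image), collapse = " x "), class = "image_format")
  }
  nc <- dim(image)[3L]
  if (nc != 3L) {
    stop_rz(
      "expected 3 colour channels, got %d (%s)", nc,
      if (nc == 4L) "RGBA input: drop the alpha channel, e.g. read_image_rgb(drop_alpha = TRUE)"
      else "grayscale and other layouts are not supported",
      class = "image_format")
  }
  invisible(TRUE)
}
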