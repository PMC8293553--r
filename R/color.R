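#' Convert an 8-bit RGB image to 8-bit HSB channels
#'
#' Uses the standard hexcone model: hue in degrees \[0, 360) is mapped to
#' \[0, 255\] by `round(deg * 255 / 360)`, and saturation/brightness fractions
#' in \[0, 1\] are mapped by `round(frac * 255)`. Achromatic pixels (zero
#' saturation) get hue 0. The conversion is per-pixel deterministic.
#'
#' @param image RGB image array (height x width x 3) with values in \[0, 255\].
#' @return An integer array of the same dimensions holding H, S and B bytes.
#' @examples
#' px <- array(c(255, 128, 0), dim = c(1, 1, 3))
#' rgb_to_hsb(px)[1, 1, ]  # H = 21, S = 255, B = 255
#' @export
rgb_to_hsb <- function(image) {
  check_rgb_image(image)
  if (min(image) < 0 || max(image) > 255) {
    stop_rz("RGB channel values must lie in [0, 255]", class = "image_format")
  }
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1L]),
             as.vector(image[, , 2L]),
             as.vector(image[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0L, dim = d)
  out[, , 1L] <- as.integer(round(hsv[1L, ] * 255))
  out[, , 2L] <- as.integer(round(hsv[2L, ] * 255))
  out[, , 3L] <- as.integer(round(hsv[3L, ] * 255))
  out
}

#' Threshold an HSB image against a colour band
#'
#' A pixel is foreground iff its hue, saturation and brightness all fall
#' inclusively within the band; hue is tested with wraparound when
#' `h_min > h_max`. Widening any bound can only grow the mask.
#'
#' @param hsb An HSB byte array from [rgb_to_hsb()].
#' @param band An [hsb_range()].
#' @return A logical matrix (height x width): `TRUE` = foreground.
#' @export
threshold_hsb <- function(hsb, band) {
  check_rgb_image(hsb)
  stopifnot(inherits(band, "hsb_range"))
  d <- dim(hsb)
  h <- matrix(hsb[, , 1L], d[1L], d[2L])
  s <- matrix(hsb[, , 2L], d[1L], d[2L])
  b <- matrix(hsb[, , 3L], d[1L], d[2L])
  in_h <- if (band$h_min <= band$h_max) {
    h >= band$h_min & h <= band$h_max
  } else {
    h >= band$h_min | h <= band$h_max
  }
  in_h & s >= band$s_min & s <= band$s_max & b >= band$b_min & b <= band$b_max
}

# HSB bytes -> RGB bytes (hue byte spans the full circle). Used by the
# synthetic renderer to emit pixels with a known HSB signature.
hsb_bytes_to_rgb <- function(h, s, b) {
  hex <- grDevices::hsv(h = pmin(h / 255, 1), s = s / 255, v = b / 255)
  t(grDevices::col2rgb(hex))
}
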