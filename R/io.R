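#' Read an 8-bit RGB image from PNG, TIFF or JPEG
#'
#' @param path Image file path; format is chosen by extension.
#' @param drop_alpha If `TRUE`, an RGBA image has its alpha channel silently
#'   dropped; otherwise 4-channel input is rejected.
#' @return Numeric array (height x width x 3) with values in \[0, 255\].
#' @export
read_image_rgb <- function(path, drop_alpha = FALSE) {
  if (!file.exists(path)) stop_rz("image file not found: %s", path, class = "io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_rz("unsupported image format '.%s' (use PNG, TIFF or JPEG): %s",
            ext, path, class = "image_format")
  )
  if (length(dim(img)) == 2L) {
    stop_rz("grayscale image not supported (expected RGB): %s", path,
            class = "image_format")
  }
  if (dim(img)[3L] == 4L) {
    if (!drop_alpha) {
      stop_rz("RGBA image: %s (pass drop_alpha = TRUE to discard the alpha channel)",
              path, class = "image_format")
    }
    img <- img[, , 1:3, drop = FALSE]
  }
  check_rgb_image(img)
  round(img * 255)
}

#' Write an 8-bit RGB image
#'
#' @param image RGB array (height x width x 3), values in \[0, 255\].
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(image, path) {
  check_rgb_image(image)
  scaled <- pmin(pmax(image, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop_rz("unsupported output format '.%s' (use PNG or TIFF)", ext,
            class = "image_format")
  )
  invisible(path)
}

image_extensions <- c("png", "tif", "tiff", "jpg", "jpeg")
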