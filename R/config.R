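#' Pipeline configuration
#'
#' Bundles every parameter of the counting macro: scale calibration, optional
#' crop rectangle, one HSB band per particle class, and the particle size
#' filter. The defaults are the published orange-tubercle settings: band
#' H 0-55, S 102-255, B 95-255 at 22 px/mm with particles of 0.05-20 mm².
#'
#' @param calibration A [scale_calibration()].
#' @param crop Optional [crop_rect()] applied before thresholding; `NULL`
#'   processes the full frame.
#' @param bands Named list of [hsb_range()] objects; must contain a band named
#'   `"tubercle"`. Add e.g. a `"necrotic"` band (brown, low brightness) for a
#'   second counting of necrotic tubercles.
#' @param size A [size_range()] in mm².
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(calibration = scale_calibration(22),
                            crop = NULL,
                            bands = list(tubercle = hsb_range(0, 55, 102, 255, 95, 255)),
                            size = size_range(0.05, 20)) {
  stopifnot(inherits(calibration, "scale_calibration"),
            is.null(crop) || inherits(crop, "crop_rect"),
            inherits(size, "size_range"))
  if (!is.list(bands) || is.null(names(bands)) || !"tubercle" %in% names(bands)) {
    stop_rz("config key bands.tubercle is required", class = "config_error")
  }
  for (nm in names(bands)) {
    if (!inherits(bands[[nm]], "hsb_range")) {
      stop_rz("config key bands.%s is not a valid HSB band", nm, class = "config_error")
    }
  }
  structure(list(calibration = calibration, crop = crop, bands = bands,
                 size = size),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("Pipeline config: %.4g px/mm; size %.3g-%.3g mm^2; %s crop\n",
              x$calibration$px_per_mm, x$size$min_mm2, x$size$max_mm2,
              if (is.null(x$crop)) "no" else
                sprintf("(%d,%d,%d,%d)", x$crop$x, x$crop$y, x$crop$width, x$crop$height)))
  for (nm in names(x$bands)) {
    b <- x$bands[[nm]]
    cat(sprintf("  band %-10s H %d-%d  S %d-%d  B %d-%d\n", nm,
                b$h_min, b$h_max, b$s_min, b$s_max, b$b_min, b$b_max))
  }
  invisible(x)
}

#' Count tubercles on one image
#'
#' Runs the full measurement chain: crop to the region of interest, convert to
#' HSB, threshold each configured colour band, fill mask holes, and extract
#' particles within the size filter. With the default single band this yields
#' the automatic tubercle count; an optional `"necrotic"` band adds a second
#' count of brown tubercles reported under its own class.
#'
#' @param image RGB array (height x width x 3), values in \[0, 255\].
#' @param config A [pipeline_config()].
#' @param image_id Identifier attached to the result (used in error messages
#'   and summary tables).
#' @return A `particle_set` data frame (see [find_particles()]) with one row
#'   per detected particle, class given by the band that produced it, ids
#'   sequential across bands, and attributes `image_id` and `counts` (named
#'   integer vector of particles per class).
#' @export
count_tubercles <- function(image, config, image_id = NA_character_) {
  stopifnot(inherits(config, "pipeline_config"))
  cropped <- tryCatch(
    if (is.null(config$crop)) { check_rgb_image(image); image }
    else crop_image(image, config$crop),
    error = function(e) {
      stop_rz("image %s: %s", image_id, conditionMessage(e),
              class = class(e)[1L])
    })
  hsb <- rgb_to_hsb(cropped)
  sets <- lapply(names(config$bands), function(nm) {
    mask <- threshold_hsb(hsb, config$bands[[nm]])
    filled <- fill_holes(mask)
    find_particles(filled, config$calibration, config$size, class_label = nm)
  })
  df <- do.call(rbind, lapply(sets, as.data.frame))
  if (nrow(df) > 0L) df$particle_id <- seq_len(nrow(df))
  if (!is.null(config$crop)) {
    df$centroid_x_px <- df$centroid_x_px + config$crop$x
    df$centroid_y_px <- df$centroid_y_px + config$crop$y
  }
  res <- particle_set(df, image_id = image_id)
  attr(res, "counts") <- particle_counts(res)
  attr(res, "px_per_mm") <- config$calibration$px_per_mm
  res
}

particle_counts <- function(ps) {
  classes <- unique(c("tubercle", ps$class))
  setNames(vapply(classes, function(cl) sum(ps$class == cl), integer(1)), classes)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Expected keys: `scale` (either `{px_per_mm}` or `{line_px, known_mm}`),
#' optional `crop: [x, y, w, h]`, `bands` (named, each `{h: [lo,hi],
#' s: [lo,hi], b: [lo,hi]}`, at least `tubercle`), and `size_mm2: [min, max]`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_rz("config file not found: %s", path, class = "config_error")
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config_from_list(raw)
}

pipeline_config_from_list <- function(raw) {
  need <- function(key, x) {
    if (is.null(x)) stop_rz("config key %s is missing", key, class = "config_error")
    x
  }
  sc <- need("scale", raw$scale)
  calibration <- if (!is.null(sc$px_per_mm)) {
    scale_calibration(sc$px_per_mm)
  } else {
    calibrate_scale(need("scale.line_px", sc$line_px),
                    need("scale.known_mm", sc$known_mm))
  }
  crop <- NULL
  if (!is.null(raw$crop)) {
    cr <- unlist(raw$crop)
    if (length(cr) != 4L) stop_rz("config key crop must be [x, y, w, h]", class = "config_error")
    crop <- crop_rect(cr[1L], cr[2L], cr[3L], cr[4L])
  }
  bands_raw <- need("bands", raw$bands)
  if (is.null(bands_raw$tubercle)) {
    stop_rz("config key bands.tubercle is missing", class = "config_error")
  }
  bands <- lapply(names(bands_raw), function(nm) {
    b <- bands_raw[[nm]]
    key <- paste0("bands.", nm)
    h <- unlist(need(paste0(key, ".h"), b$h))
    s <- unlist(need(paste0(key, ".s"), b$s))
    v <- unlist(need(paste0(key, ".b"), b$b))
    if (length(h) != 2L || length(s) != 2L || length(v) != 2L) {
      stop_rz("config key %s channels must each be [lo, hi]", key, class = "config_error")
    }
    hsb_range(h[1L], h[2L], s[1L], s[2L], v[1L], v[2L])
  })
  names(bands) <- names(bands_raw)
  sz <- unlist(need("size_mm2", raw$size_mm2))
  if (length(sz) != 2L) stop_rz("config key size_mm2 must be [min, max]", class = "config_error")
  pipeline_config(calibration = calibration, crop = crop, bands = bands,
                  size = size_range(sz[1L], sz[2L]))
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_pipeline_config()].
#'
#' @param config A [pipeline_config()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- list(scale = list(px_per_mm = config$calibration$px_per_mm))
  if (!is.null(config$crop)) {
    raw$crop <- c(config$crop$x, config$crop$y, config$crop$width, config$crop$height)
  }
  raw$bands <- lapply(config$bands, function(b) {
    list(h = c(b$h_min, b$h_max), s = c(b$s_min, b$s_max), b = c(b$b_min, b$b_max))
  })
  raw$size_mm2 <- c(config$size$min_mm2, config$size$max_mm2)
  yaml::write_yaml(raw, path)
  invisible(path)
}
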