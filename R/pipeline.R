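#' Process a directory of rhizotron images
#'
#' The batch (automatic-macro) workflow: every image in `input_dir` is counted
#' with [count_tubercles()] under one shared configuration, a particle table
#' is written per image, and a summary table with one row per image is
#' returned and written. Images are processed in lexicographic filename order;
#' an unreadable file is logged and skipped rather than aborting the batch,
#' because phenotyping runs unattended.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Directory containing PNG/TIFF/JPEG images.
#' @param output_dir Directory for result CSVs; created if needed. `NULL`
#'   skips writing.
#' @param pattern Filename regex for image discovery (defaults to the
#'   supported extensions).
#' @return A `summary_table` data frame with columns `image_id`,
#'   `tubercle_count`, `necrotic_count`, `corrected`, carrying attributes
#'   `failures` (data frame of skipped files and reasons) and
#'   `particle_sets` (named list of per-image `particle_set` objects).
#' @export
process_directory <- function(config, input_dir, output_dir = NULL,
                              pattern = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(input_dir)) {
    stop_rz("input directory not found: %s", input_dir, class = "io_error")
  }
  pattern <- pattern %||% paste0("\\.(", paste(image_extensions, collapse = "|"), ")$")
  files <- sort(list.files(input_dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    warning(sprintf("no images matched in %s", input_dir))
  }
  ids <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(ids)) {
    stop_rz("duplicate image ids (filename stems): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "io_error")
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  sets <- list()
  failures <- data.frame(image_id = character(), file = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(files)) {
    res <- tryCatch({
      img <- read_image_rgb(files[i])
      count_tubercles(img, config, image_id = ids[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("skipping %s: %s", files[i], conditionMessage(res)))
      failures <- rbind(failures, data.frame(
        image_id = ids[i], file = files[i],
        reason = conditionMessage(res), stringsAsFactors = FALSE))
      next
    }
    sets[[ids[i]]] <- res
    if (!is.null(output_dir)) {
      write_particle_csv(res, file.path(output_dir, paste0(ids[i], "_particles.csv")))
    }
  }
  summary <- summarize_runs(sets)
  attr(summary, "failures") <- failures
  attr(summary, "particle_sets") <- sets
  if (!is.null(output_dir)) {
    write_summary_csv(summary, file.path(output_dir, "summary.csv"))
  }
  summary
}

#' Summarize per-image particle sets into a count table
#'
#' @param particle_sets Named list of `particle_set` objects (names are image
#'   ids; unnamed entries use their `image_id` attribute).
#' @return A `summary_table` data frame: `image_id`, `tubercle_count` (classes
#'   `tubercle` + `manual_added`), `necrotic_count`, `corrected`. Rows follow
#'   the list order; duplicate image ids are an error.
#' @export
summarize_runs <- function(particle_sets) {
  ids <- names(particle_sets) %||% rep(NA_character_, length(particle_sets))
  rows <- lapply(seq_along(particle_sets), function(i) {
    ps <- particle_sets[[i]]
    id <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i] else attr(ps, "image_id")
    data.frame(
      image_id = id,
      tubercle_count = sum(ps$class %in% c("tubercle", "manual_added")),
      necrotic_count = sum(ps$class == "necrotic"),
      corrected = isTRUE(attr(ps, "corrected")),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), tubercle_count = integer(),
               necrotic_count = integer(), corrected = logical(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(out$image_id)) {
    stop_rz("duplicate image_id in summary: %s",
            paste(unique(out$image_id[duplicated(out$image_id)]), collapse = ", "),
            class = "summary_error")
  }
  structure(out, class = c("summary_table", "data.frame"))
}

#' Apply manual add/delete corrections to a particle set
#'
#' Mirrors the semiautomatic workflow: each delete point removes at most one
#' particle — the one whose bounding box contains the point (nearest centroid
#' breaks ties) or, failing that, the particle with the nearest centroid
#' within `tolerance_mm`; a point matching nothing raises a warning and
#' changes nothing. Each add point appends a `manual_added` particle carrying
#' no measured area (a count correction, not a segmentation edit).
#'
#' @param particles A `particle_set` (e.g. from [count_tubercles()]).
#' @param corrections A [correction_set()]; its `image_id` must match the
#'   particle set's (when both are known).
#' @param tolerance_mm Maximum centroid distance for a delete point that falls
#'   outside every bounding box.
#' @return The corrected `particle_set`, with attribute `corrected = TRUE`.
#' @export
apply_corrections <- function(particles, corrections, tolerance_mm = 2) {
  stopifnot(inherits(particles, "particle_set"),
            inherits(corrections, "correction_set"))
  pid <- attr(particles, "image_id")
  if (!is.na(pid) && !is.na(corrections$image_id) &&
      pid != corrections$image_id) {
    stop_rz("corrections are for image '%s' but particles are from '%s'",
            corrections$image_id, pid, class = "correction_error")
  }
  df <- as.data.frame(particles)
  del <- corrections$delete_points
  for (i in seq_len(nrow(del))) {
    if (nrow(df) == 0L) {
      warning(sprintf("delete point (%.3g, %.3g) matched no particle",
                      del$x_mm[i], del$y_mm[i]))
      next
    }
    px_per_mm <- attr(particles, "px_per_mm") %||% NA_real_
    d <- sqrt((df$centroid_x_mm - del$x_mm[i])^2 +
              (df$centroid_y_mm - del$y_mm[i])^2)
    hit <- if (!is.na(px_per_mm)) {
      x_px <- del$x_mm[i] * px_per_mm
      y_px <- del$y_mm[i] * px_per_mm
      which(x_px >= df$bbox_x & x_px < df$bbox_x + df$bbox_w &
            y_px >= df$bbox_y & y_px < df$bbox_y + df$bbox_h)
    } else integer()
    target <- if (length(hit)) hit[which.min(d[hit])]
              else if (min(d) <= tolerance_mm) which.min(d)
              else integer()
    if (length(target) == 0L) {
      warning(sprintf("delete point (%.3g, %.3g) matched no particle",
                      del$x_mm[i], del$y_mm[i]))
      next
    }
    df <- df[-target, , drop = FALSE]
  }
  add <- corrections$add_points
  if (nrow(add) > 0L) {
    # match whatever columns the particle table carries (an in-memory set has
    # pixel centroids, one re-read from CSV does not)
    added <- df[rep(NA_integer_, nrow(add)), , drop = FALSE]
    added$class <- "manual_added"
    added$area_px <- 0L
    added$centroid_x_mm <- add$x_mm
    added$centroid_y_mm <- add$y_mm
    df <- rbind(df, added)
  }
  if (nrow(df) > 0L) df$particle_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  out <- particle_set(df, image_id = pid)
  attr(out, "px_per_mm") <- attr(particles, "px_per_mm")
  attr(out, "counts") <- particle_counts(out)
  attr(out, "corrected") <- TRUE
  out
}

#' Manual correction set for one image
#'
#' @param image_id Image the corrections belong to.
#' @param add_points,delete_points Data frames with columns `x_mm`, `y_mm`
#'   (positions in the cropped frame, millimetres).
#' @return A `correction_set` object.
#' @export
correction_set <- function(image_id,
                           add_points = data.frame(x_mm = numeric(), y_mm = numeric()),
                           delete_points = data.frame(x_mm = numeric(), y_mm = numeric())) {
  for (p in list(add_points, delete_points)) {
    stopifnot(is.data.frame(p), all(c("x_mm", "y_mm") %in% names(p)))
    if (nrow(p) && any(!is.finite(p$x_mm) | !is.finite(p$y_mm))) {
      stop_rz("correction points must be finite", class = "correction_error")
    }
  }
  structure(list(image_id = image_id,
                 add_points = add_points[, c("x_mm", "y_mm"), drop = FALSE],
                 delete_points = delete_points[, c("x_mm", "y_mm"), drop = FALSE]),
            class = "correction_set")
}

#' Read correction sets from CSV
#'
#' Expected columns: `image_id,action,x_mm,y_mm` with action `add` or
#' `delete`.
#'
#' @param path CSV file path.
#' @return Named list of [correction_set()] objects, one per image id.
#' @export
read_corrections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "action", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop_rz("corrections file must have columns %s", paste(need, collapse = ","),
            class = "correction_error")
  }
  bad <- setdiff(unique(df$action), c("add", "delete"))
  if (length(bad)) {
    stop_rz("unknown correction action(s): %s", paste(bad, collapse = ", "),
            class = "correction_error")
  }
  lapply(split(df, df$image_id), function(d) {
    correction_set(
      image_id = d$image_id[1L],
      add_points = d[d$action == "add", c("x_mm", "y_mm"), drop = FALSE],
      delete_points = d[d$action == "delete", c("x_mm", "y_mm"), drop = FALSE])
  })
}

particle_csv_columns <- c("particle_id", "class", "area_mm2", "area_px",
                          "centroid_x_mm", "centroid_y_mm",
                          "bbox_x", "bbox_y", "bbox_w", "bbox_h")

#' Write a per-image particle table to CSV
#'
#' Floating-point columns are rounded to 6 decimals so repeated runs are
#' byte-identical across platforms.
#'
#' @param particles A `particle_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_csv <- function(particles, path) {
  df <- as.data.frame(particles)[, particle_csv_columns, drop = FALSE]
  for (cc in c("area_mm2", "centroid_x_mm", "centroid_y_mm")) {
    df[[cc]] <- round(df[[cc]], 6)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a particle table written by [write_particle_csv()]
#'
#' @param path CSV path; the image id is taken from the filename stem
#'   (dropping a `_particles` suffix).
#' @return A `particle_set`.
#' @export
read_particle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(particle_csv_columns %in% names(df))) {
    stop_rz("not a particle table (missing columns): %s", path, class = "io_error")
  }
  id <- sub("_particles$", "", tools::file_path_sans_ext(basename(path)))
  particle_set(df, image_id = id)
}

write_summary_csv <- function(summary, path) {
  df <- as.data.frame(summary)
  df$corrected <- tolower(as.character(df$corrected))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a summary table written by [process_directory()]
#'
#' @param path CSV path.
#' @return A `summary_table` data frame.
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$corrected <- df$corrected %in% c("true", "TRUE", TRUE)
  structure(df, class = c("summary_table", "data.frame"))
}
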