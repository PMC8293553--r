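#' Match automatic detections to reference annotations
#'
#' One-to-one greedy matching by ascending centroid distance: candidate pairs
#' within `tolerance_mm` are sorted by distance (ties broken by lower
#' automatic id, then lower truth id) and accepted while both members are
#' still unmatched. Matched pairs are true positives; unmatched reference
#' objects are false negatives, unmatched detections false positives. The
#' distance rule stands in for a visual side-by-side comparison and is
#' reported as such.
#'
#' @param auto A `particle_set`, or any data frame with `centroid_x_mm`,
#'   `centroid_y_mm` (or `x_mm`, `y_mm`) columns.
#' @param truth Ground-truth data frame with `x_mm`, `y_mm` and optionally
#'   `truth_id`, `image_id`, `class` columns. All classes are used as
#'   reference (a manual counter also counts pale and necrotic tubercles).
#' @param tolerance_mm Maximum accepted centroid distance (default 2 mm,
#'   about one tubercle radius at the published scale).
#' @param classes Which detection classes count as automatic detections.
#' @return A `match_result` list: `tp`, `fp`, `fn`, `recall`, `precision`
#'   (NaN when the denominator is empty), and `pairs` (data frame `auto_id`,
#'   `truth_id`, `distance_mm`).
#' @export
match_particles <- function(auto, truth, tolerance_mm = 2,
                            classes = c("tubercle", "manual_added")) {
  stopifnot(is.numeric(tolerance_mm), tolerance_mm > 0)
  aid <- attr(auto, "image_id")
  tid <- unique(truth$image_id)
  if (!is.null(aid) && !is.na(aid) && length(tid) == 1L && !is.na(tid) &&
      aid != tid) {
    stop_rz("detections are from image '%s' but truth is for '%s'", aid, tid,
            class = "evaluation_error")
  }
  if (length(tid) > 1L) {
    stop_rz("truth table spans several images (%s); match one image at a time",
            paste(tid, collapse = ", "), class = "evaluation_error")
  }
  a <- as.data.frame(auto)
  if ("class" %in% names(a)) a <- a[a$class %in% classes, , drop = FALSE]
  ax <- a$centroid_x_mm %||% a$x_mm
  ay <- a$centroid_y_mm %||% a$y_mm
  a_id <- a$particle_id %||% seq_along(ax)
  t_id <- truth$truth_id %||% seq_len(nrow(truth))
  n_a <- length(ax); n_t <- nrow(truth)

  pairs <- data.frame(auto_id = integer(), truth_id = integer(),
                      distance_mm = numeric())
  if (n_a > 0L && n_t > 0L) {
    dmat <- sqrt(outer(ax, truth$x_mm, "-")^2 + outer(ay, truth$y_mm, "-")^2)
    cand <- which(dmat <= tolerance_mm, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ord <- order(dmat[cand], a_id[cand[, 1L]], t_id[cand[, 2L]])
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(n_a); used_t <- logical(n_t)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!used_a[i] && !used_t[j]) {
          used_a[i] <- used_t[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(auto_id = a_id[cand[, 1L]],
                          truth_id = t_id[cand[, 2L]],
                          distance_mm = dmat[cand])
    }
  }
  tp <- nrow(pairs)
  structure(list(
    tp = tp, fp = n_a - tp, fn = n_t - tp,
    recall = if (n_t > 0L) tp / n_t else NaN,
    precision = if (n_a > 0L) tp / n_a else NaN,
    pairs = pairs, tolerance_mm = tolerance_mm,
    image_id = aid %||% tid %||% NA_character_
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match result: TP %d  FP %d  FN %d  recall %.3f  precision %.3f (tol %.2g mm)\n",
              x$tp, x$fp, x$fn, x$recall, x$precision, x$tolerance_mm))
  invisible(x)
}

#' Count-level agreement between reference and automatic counts
#'
#' Computes the Pearson product-moment correlation of the paired per-image
#' counts and the least-squares slope of the trend line through the origin,
#' `b = sum(x*y) / sum(x^2)` with the reference count as x.
#'
#' @param paired_counts Data frame with columns `reference` and `automatic`
#'   (one row per image), or a two-column matrix in that order.
#' @return An `agreement_stats` list: `n_images`, `pearson_r` (NA when either
#'   vector is constant or n < 2), `slope_origin` (NA when all reference
#'   counts are zero), and `counts` (the paired table).
#' @export
agreement_stats <- function(paired_counts) {
  pc <- as.data.frame(paired_counts)
  if (!all(c("reference", "automatic") %in% names(pc))) {
    if (ncol(pc) >= 2L) names(pc)[1:2] <- c("reference", "automatic")
    else stop_rz("paired_counts needs columns reference and automatic",
                 class = "evaluation_error")
  }
  x <- as.numeric(pc$reference); y <- as.numeric(pc$automatic)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_rz("counts must be finite", class = "evaluation_error")
  }
  n <- length(x)
  r <- if (n >= 2L && sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  slope <- if (sum(x^2) > 0) sum(x * y) / sum(x^2) else NA_real_
  structure(list(n_images = n, pearson_r = r, slope_origin = slope,
                 counts = pc[, c("reference", "automatic")]),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Count agreement over %d images: r = %.4f, trend y = %.3fx\n",
              x$n_images, x$pearson_r, x$slope_origin))
  invisible(x)
}

#' Evaluate a whole run against ground truth
#'
#' Per image: object-level matching within `tolerance_mm` ([match_particles()]).
#' Pooled: count agreement ([agreement_stats()]) between the reference count
#' (number of ground-truth objects, all classes) and the automatic tubercle
#' count, plus mean and sample standard deviation of per-image recall and
#' precision. Images lacking ground truth (or truth lacking detections) are
#' excluded and listed.
#'
#' @param particle_sets Named list of per-image `particle_set` objects (names
#'   are image ids), e.g. the `particle_sets` attribute of
#'   [process_directory()]'s summary.
#' @param truth Ground-truth data frame for all images: columns `image_id`,
#'   `truth_id`, `x_mm`, `y_mm`, `radius_mm`, `class`. Images with zero truth
#'   objects must still appear (with zero rows they cannot; pass them via
#'   `empty_truth_ids`) — simplest is a truth table from
#'   [generate_experiment()], which lists every image in its manifest.
#' @param tolerance_mm Matching tolerance in millimetres.
#' @param empty_truth_ids Image ids known to contain zero reference objects
#'   (e.g. resistant rhizotrons) that therefore have no rows in `truth`.
#' @return An `evaluation_report` list: `per_image` data frame (`image_id`,
#'   `n_truth`, `n_auto`, `tp`, `fp`, `fn`, `recall`, `precision`), `pooled`
#'   [agreement_stats()], `recall_mean`, `recall_sd`, `precision_mean`,
#'   `precision_sd` (over images where defined, with `n_recall`/
#'   `n_precision`), `tolerance_mm`, `excluded` (ids without truth), and
#'   `match_rule` (a note that matching is centroid-distance based).
#' @export
evaluate_experiment <- function(particle_sets, truth, tolerance_mm = 2,
                                empty_truth_ids = character()) {
  ids <- names(particle_sets)
  truth_ids <- union(unique(truth$image_id), empty_truth_ids)
  excluded <- setdiff(ids, truth_ids)
  if (length(excluded)) {
    message(sprintf("no ground truth for image(s): %s — excluded",
                    paste(excluded, collapse = ", ")))
  }
  use <- intersect(ids, truth_ids)
  rows <- lapply(use, function(id) {
    tr <- truth[truth$image_id == id, , drop = FALSE]
    m <- match_particles(particle_sets[[id]], tr, tolerance_mm = tolerance_mm)
    data.frame(image_id = id, n_truth = nrow(tr),
               n_auto = m$tp + m$fp, tp = m$tp, fp = m$fp, fn = m$fn,
               recall = m$recall, precision = m$precision,
               stringsAsFactors = FALSE)
  })
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), n_truth = integer(), n_auto = integer(),
               tp = integer(), fp = integer(), fn = integer(),
               recall = numeric(), precision = numeric())
  assemble_report(per_image, tolerance_mm, excluded)
}

assemble_report <- function(per_image, tolerance_mm, excluded = character()) {
  rec <- per_image$recall[is.finite(per_image$recall)]
  prec <- per_image$precision[is.finite(per_image$precision)]
  structure(list(
    per_image = per_image,
    pooled = agreement_stats(data.frame(reference = per_image$n_truth,
                                        automatic = per_image$n_auto)),
    recall_mean = mean(rec), recall_sd = sd(rec), n_recall = length(rec),
    precision_mean = mean(prec), precision_sd = sd(prec),
    n_precision = length(prec),
    tolerance_mm = tolerance_mm, excluded = excluded,
    match_rule = sprintf(
      "centroid distance <= %.3g mm, greedy nearest-first one-to-one; a stand-in for visual matching",
      tolerance_mm)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d images: recall %.1f%% +/- %.1f%%, precision %.1f%% +/- %.1f%%\n",
    nrow(x$per_image), 100 * x$recall_mean, 100 * (x$recall_sd %||% NA),
    100 * x$precision_mean, 100 * (x$precision_sd %||% NA)))
  print(x$pooled)
  invisible(x)
}

#' Write an evaluation report to JSON (+ paired-count CSV)
#'
#' @param report An `evaluation_report` from [evaluate_experiment()].
#' @param path Output `.json` path; a sibling `<stem>_counts.csv` with the
#'   paired per-image counts is written alongside for plotting.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    n_images = nrow(report$per_image),
    tolerance_mm = report$tolerance_mm,
    match_rule = report$match_rule,
    pooled = list(pearson_r = report$pooled$pearson_r,
                  slope_origin = report$pooled$slope_origin,
                  n_images = report$pooled$n_images),
    recall = list(mean = report$recall_mean, sd = report$recall_sd,
                  n = report$n_recall),
    precision = list(mean = report$precision_mean, sd = report$precision_sd,
                     n = report$n_precision),
    excluded = report$excluded,
    per_image = report$per_image
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                       na = "null", pretty = TRUE)
  counts <- cbind(image_id = report$per_image$image_id,
                  report$pooled$counts)
  utils::write.csv(counts,
                   file.path(dirname(path),
                             paste0(tools::file_path_sans_ext(basename(path)),
                                    "_counts.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth annotation table
#'
#' Expected columns: `image_id,truth_id,x_mm,y_mm,radius_mm,class` with class
#' in tubercle/pale/necrotic.
#'
#' @param path CSV path.
#' @return The ground-truth data frame.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "truth_id", "x_mm", "y_mm", "radius_mm", "class")
  if (!all(need %in% names(df))) {
    stop_rz("ground truth must have columns %s", paste(need, collapse = ","),
            class = "io_error")
  }
  df
}
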