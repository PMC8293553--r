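#' Parameters for one synthetic rhizotron scene
#'
#' Describes a rhizotron-like image: near-white glass-fibre paper background,
#' white low-saturation roots, orange tubercles whose HSB signature sits
#' inside the default detection band, plus the documented confounds — pale
#' tubercles (saturation below the band), brown necrotic tubercles
#' (brightness below the band), touching tubercle clusters that merge into
#' one particle, and in-band distractor blobs (rockwool speckles, stem base)
#' that are not in the ground truth. The default canvas equals the published
#' crop (2634 x 1824 px at 22 px/mm) so real-image configurations transfer
#' unchanged.
#'
#' @param canvas_px Canvas size `c(width, height)` in pixels.
#' @param px_per_mm Scale of the rendered scene.
#' @param n_tubercles Number of ground-truth tubercles (all classes).
#' @param radius_range_mm Tubercle equivalent-radius range; the default
#'   0.15-2.5 mm spans areas of about 0.07-19.6 mm², inside the 0.05-20 mm²
#'   particle filter.
#' @param pale_frac Fraction of tubercles rendered pale (saturation drawn in
#'   30-95, below the band's 102 cutoff).
#' @param necrotic_frac Fraction rendered necrotic (brightness 30-90, below
#'   the band's 95 cutoff; hue 8-30).
#' @param cluster_frac Fraction of tubercles placed in touching pairs (centre
#'   spacing 0.8 x the sum of radii, so their masks merge).
#' @param n_distractors Number of in-band rockwool speckle blobs rendered in
#'   the bottom strip; they cause false positives and are not in the truth.
#' @param stem_base If `TRUE`, adds one elongated in-band blob at the top
#'   centre (a stem-base false positive).
#' @param noise_sd Standard deviation of the additive background noise
#'   (8-bit counts).
#' @param n_roots Number of root polylines.
#' @param seed Integer seed; the scene is bit-reproducible given the seed.
#' @return A `scene_params` object.
#' @export
scene_params <- function(canvas_px = c(2634L, 1824L),
                         px_per_mm = 22,
                         n_tubercles = 30L,
                         radius_range_mm = c(0.15, 2.5),
                         pale_frac = 0,
                         necrotic_frac = 0,
                         cluster_frac = 0,
                         n_distractors = 0L,
                         stem_base = FALSE,
                         noise_sd = 2.5,
                         n_roots = 12L,
                         seed = NULL) {
  stopifnot(length(canvas_px) == 2L, all(canvas_px >= 64),
            px_per_mm > 0, n_tubercles >= 0,
            length(radius_range_mm) == 2L, all(radius_range_mm > 0),
            radius_range_mm[1L] < radius_range_mm[2L],
            n_distractors >= 0, noise_sd >= 0, n_roots >= 1)
  fr <- c(pale_frac, necrotic_frac, cluster_frac)
  if (any(fr < 0) || any(fr > 1) || pale_frac + necrotic_frac > 1) {
    stop_rz("class fractions must lie in [0,1] and pale + necrotic <= 1",
            class = "invalid_scene")
  }
  structure(list(canvas_px = as.integer(canvas_px), px_per_mm = px_per_mm,
                 n_tubercles = as.integer(n_tubercles),
                 radius_range_mm = radius_range_mm,
                 pale_frac = pale_frac, necrotic_frac = necrotic_frac,
                 cluster_frac = cluster_frac,
                 n_distractors = as.integer(n_distractors),
                 stem_base = isTRUE(stem_base),
                 noise_sd = noise_sd, n_roots = as.integer(n_roots),
                 seed = seed),
            class = "scene_params")
}

# Per-class HSB byte models. Tubercle colours are drawn strictly inside the
# published band; pale fails its saturation gate and necrotic its brightness
# gate at the core, so each class is missed for the documented reason and not
# by rendering accident.
draw_class_hsb <- function(class) {
  switch(class,
    tubercle = c(h = runif(1, 5, 40), s = runif(1, 150, 255), b = runif(1, 110, 240)),
    pale = c(h = runif(1, 5, 40), s = runif(1, 30, 95), b = runif(1, 110, 240)),
    necrotic = c(h = runif(1, 8, 30), s = runif(1, 120, 200), b = runif(1, 30, 90)),
    stop_rz("unknown tubercle class '%s'", class, class = "invalid_scene"))
}

# Patch geometry for alpha-blending an ellipse. Coordinates are 0-based
# pixel positions. `soft` gives a ~1 px anti-aliasing ramp centred on the
# boundary (alpha 0.5 on the nominal outline), so the thresholded area of an
# in-band ellipse tracks pi*a*b within a fraction of a pixel; hard edges are
# used for out-of-band classes so no blended rim can re-enter the band.
# Returns row/col indices and the alpha matrix; the caller blends in place
# (sub-assigning here would copy the full canvas on every stamp).
ellipse_patch <- function(cx, cy, a_px, b_px, theta, w, h, soft = TRUE) {
  r_out <- max(a_px, b_px) + 2
  xs <- max(0, floor(cx - r_out)):min(w - 1, ceiling(cx + r_out))
  ys <- max(0, floor(cy - r_out)):min(h - 1, ceiling(cy + r_out))
  if (!length(xs) || !length(ys)) return(NULL)
  dx <- xs - cx; dy <- ys - cy
  u <- outer(dy * sin(theta), dx * cos(theta), "+")
  v <- outer(dy * cos(theta), -dx * sin(theta), "+")
  dn <- sqrt((u / a_px)^2 + (v / b_px)^2)
  r_eff <- sqrt(a_px * b_px)
  alpha <- if (soft) pmin(pmax((1 - dn) * r_eff + 0.5, 0), 1) else (dn <= 1) * 1
  if (all(alpha == 0)) return(NULL)
  list(ri = ys + 1L, ci = xs + 1L, alpha = alpha)
}

# Patch geometry for one thick line segment of a root polyline.
segment_patch <- function(x1, y1, x2, y2, half_w, w, h) {
  xs <- max(0, floor(min(x1, x2) - half_w)):min(w - 1, ceiling(max(x1, x2) + half_w))
  ys <- max(0, floor(min(y1, y2) - half_w)):min(h - 1, ceiling(max(y1, y2) + half_w))
  if (!length(xs) || !length(ys)) return(NULL)
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  dx <- xs - x1; dy <- ys - y1
  tt <- if (len2 == 0) matrix(0, length(ys), length(xs)) else
    pmin(pmax(outer(dy * vy, dx * vx, "+") / len2, 0), 1)
  ex <- sweep(tt * vx, 2L, dx, "-")
  ey <- tt * vy - dy
  hit <- sqrt(ex^2 + ey^2) <= half_w
  if (!any(hit)) return(NULL)
  list(ri = ys + 1L, ci = xs + 1L, hit = hit)
}

#' Generate one synthetic rhizotron image with exact ground truth
#'
#' Renders background, rockwool strip, roots, tubercles of all configured
#' classes, and distractors, in that order, and records every tubercle (all
#' classes) in the ground truth; distractor blobs are deliberately absent
#' from the truth. Deterministic given `params$seed`.
#'
#' Placement draws tubercle centres from points on the root polylines with a
#' minimum centre separation of `r_i + r_j + 2.2 mm` between distinct
#' objects, except for clustered pairs which are placed touching. Placement
#' failing after bounded retries (overfull canvas) is an error.
#'
#' @param params A [scene_params()].
#' @param image_id Identifier written into the ground-truth table.
#' @return A list with `image` (RGB array, 0-255), `truth` (data frame
#'   `image_id`, `truth_id`, `x_mm`, `y_mm`, `radius_mm`, `class`), and
#'   `params`.
#' @export
generate_rhizotron_image <- function(params, image_id = "synthetic") {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  w <- params$canvas_px[1L]; h <- params$canvas_px[2L]
  ppm <- params$px_per_mm
  noise <- params$noise_sd

  # channels kept as three plain matrices so patch sub-assignment stays
  # in place (a list- or function-mediated canvas would be copied per stamp)
  base <- c(246, 244, 240)
  Rm <- matrix(base[1L] + rnorm(h * w, 0, noise), nrow = h, ncol = w)
  Gm <- matrix(base[2L] + rnorm(h * w, 0, noise), nrow = h, ncol = w)
  Bm <- matrix(base[3L] + rnorm(h * w, 0, noise), nrow = h, ncol = w)

  # rockwool strip along the bottom: grey, noisy, low saturation
  y_rock <- floor(0.88 * h)
  if (y_rock < h) {
    rows <- (y_rock + 1L):h
    nr <- length(rows)
    Rm[rows, ] <- 185 + matrix(rnorm(nr * w, 0, 8), nrow = nr)
    Gm[rows, ] <- 185 + matrix(rnorm(nr * w, 0, 8), nrow = nr)
    Bm[rows, ] <- 185 + matrix(rnorm(nr * w, 0, 8), nrow = nr)
  }

  # roots: near-white polylines descending from the top
  root_pts <- list()
  half_w <- 0.5 * ppm
  y_top <- 0.02 * h; y_bot <- 0.80 * h
  n_seg <- 15L
  for (r in seq_len(params$n_roots)) {
    xv <- numeric(n_seg + 1L); yv <- seq(y_top, y_bot, length.out = n_seg + 1L)
    xv[1L] <- runif(1, 0.08 * w, 0.92 * w)
    for (s in 2:(n_seg + 1L)) {
      xv[s] <- min(max(xv[s - 1L] + rnorm(1, 0, 0.02 * w), 0.03 * w), 0.97 * w)
    }
    col <- pmin(pmax(c(233, 229, 222) + rnorm(3, 0, 3), 0), 255)
    for (s in seq_len(n_seg)) {
      p <- segment_patch(xv[s], yv[s], xv[s + 1L], yv[s + 1L], half_w, w, h)
      if (!is.null(p)) {
        Rm[p$ri, p$ci][p$hit] <- col[1L]
        Gm[p$ri, p$ci][p$hit] <- col[2L]
        Bm[p$ri, p$ci][p$hit] <- col[3L]
      }
    }
    # dense points for tubercle placement, keeping clear of the stem base
    tseq <- seq(0, 1, length.out = 40L)
    for (s in seq_len(n_seg)) {
      rx <- xv[s] + tseq * (xv[s + 1L] - xv[s])
      ry <- yv[s] + tseq * (yv[s + 1L] - yv[s])
      ok <- ry >= 0.06 * h & ry <= 0.78 * h
      root_pts[[length(root_pts) + 1L]] <- cbind(rx[ok], ry[ok])
    }
  }
  root_pts <- do.call(rbind, root_pts)

  # tubercle classes, radii and cluster membership
  n <- params$n_tubercles
  truth <- data.frame(image_id = character(), truth_id = integer(),
                      x_mm = numeric(), y_mm = numeric(),
                      radius_mm = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  placed <- matrix(numeric(), ncol = 3L)  # x_px, y_px, radius_px
  min_gap_px <- 2.2 * ppm

  place_one <- function(r_px, near = NULL, near_gap = NULL, exempt = 0L) {
    for (try in seq_len(1000L)) {
      if (is.null(near)) {
        p <- root_pts[sample.int(nrow(root_pts), 1L), ]
        cand <- p + rnorm(2, 0, 0.8 * ppm)
      } else {
        ang <- runif(1, 0, 2 * pi)
        cand <- near + near_gap * c(cos(ang), sin(ang))
      }
      if (cand[1L] < r_px + 2 || cand[1L] > w - r_px - 3 ||
          cand[2L] < r_px + 2 || cand[2L] > 0.80 * h - 2) next
      if (nrow(placed) > 0L) {
        d <- sqrt((placed[, 1L] - cand[1L])^2 + (placed[, 2L] - cand[2L])^2)
        viol <- d < placed[, 3L] + r_px + min_gap_px
        if (exempt > 0L) viol[exempt] <- FALSE  # a partner may touch its mate
        if (any(viol)) next
      }
      return(cand)
    }
    stop_rz("could not place %d objects on a %d x %d canvas (overfull scene)",
            n, w, h, class = "placement_error")
  }

  if (n > 0L) {
    classes <- rep("tubercle", n)
    u <- runif(n)
    classes[u < params$pale_frac] <- "pale"
    classes[u >= params$pale_frac &
            u < params$pale_frac + params$necrotic_frac] <- "necrotic"
    radii_mm <- runif(n, params$radius_range_mm[1L], params$radius_range_mm[2L])
    n_pairs <- floor(round(params$cluster_frac * n) / 2)
    pair_first <- if (n_pairs > 0L) seq_len(n_pairs) * 2L - 1L else integer()

    i <- 1L
    while (i <= n) {
      r_px <- radii_mm[i] * ppm
      is_pair_lead <- i %in% pair_first && i < n
      cand <- place_one(r_px)
      placed <- rbind(placed, c(cand, r_px))
      truth <- rbind(truth, data.frame(
        image_id = image_id, truth_id = i,
        x_mm = cand[1L] / ppm, y_mm = cand[2L] / ppm,
        radius_mm = radii_mm[i], class = classes[i],
        stringsAsFactors = FALSE))
      if (is_pair_lead) {
        j <- i + 1L
        rj_px <- radii_mm[j] * ppm
        gap <- 0.8 * (r_px + rj_px)
        cand2 <- place_one(rj_px, near = cand, near_gap = gap,
                           exempt = nrow(placed))
        placed <- rbind(placed, c(cand2, rj_px))
        truth <- rbind(truth, data.frame(
          image_id = image_id, truth_id = j,
          x_mm = cand2[1L] / ppm, y_mm = cand2[2L] / ppm,
          radius_mm = radii_mm[j], class = classes[j],
          stringsAsFactors = FALSE))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  # blobs to render: every ground-truth tubercle, then distractors
  blobs <- list()
  for (k in seq_len(nrow(truth))) {
    hsb <- draw_class_hsb(truth$class[k])
    r_px <- truth$radius_mm[k] * ppm
    q <- runif(1, 0.8, 1)
    blobs[[length(blobs) + 1L]] <- list(
      cx = truth$x_mm[k] * ppm, cy = truth$y_mm[k] * ppm,
      a = r_px / sqrt(q), b = r_px * sqrt(q), theta = runif(1, 0, pi),
      col = hsb_bytes_to_rgb(hsb["h"], hsb["s"], hsb["b"])[1L, ],
      soft = truth$class[k] != "necrotic")
  }
  if (params$n_distractors > 0L && y_rock < h) {
    for (d in seq_len(params$n_distractors)) {
      r_px <- runif(1, 0.2, 1.0) * ppm
      hsb <- draw_class_hsb("tubercle")
      blobs[[length(blobs) + 1L]] <- list(
        cx = runif(1, r_px + 2, w - r_px - 3),
        cy = runif(1, y_rock + r_px + 2, h - r_px - 3),
        a = r_px, b = r_px, theta = 0,
        col = hsb_bytes_to_rgb(hsb["h"], hsb["s"], hsb["b"])[1L, ],
        soft = TRUE)
    }
  }
  if (params$stem_base) {
    hsb <- draw_class_hsb("tubercle")
    blobs[[length(blobs) + 1L]] <- list(
      cx = w / 2 + rnorm(1, 0, 2 * ppm), cy = 0.6 * ppm,
      a = 2 * ppm, b = 0.7 * ppm, theta = 0,
      col = hsb_bytes_to_rgb(hsb["h"], hsb["s"], hsb["b"])[1L, ],
      soft = TRUE)
  }
  for (bl in blobs) {
    p <- ellipse_patch(bl$cx, bl$cy, bl$a, bl$b, bl$theta, w, h, soft = bl$soft)
    if (is.null(p)) next
    a1 <- p$alpha; a0 <- 1 - a1
    Rm[p$ri, p$ci] <- a1 * bl$col[1L] + a0 * Rm[p$ri, p$ci]
    Gm[p$ri, p$ci] <- a1 * bl$col[2L] + a0 * Gm[p$ri, p$ci]
    Bm[p$ri, p$ci] <- a1 * bl$col[3L] + a0 * Bm[p$ri, p$ci]
  }

  img <- array(0, dim = c(h, w, 3L))
  img[, , 1L] <- Rm; img[, , 2L] <- Gm; img[, , 3L] <- Bm
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, truth = truth, params = params)
}

#' Scenario of an experiment design
#'
#' @param label Scenario name (used as the image-id prefix).
#' @param n_images Number of rhizotron images to simulate.
#' @param counts Count distribution for the true number of tubercles per
#'   image: `list("truncnorm", mean, sd)` (normal truncated at zero, rounded),
#'   `list("uniform_int", min, max)`, or `list("constant", value)`.
#' @param overrides Named list of [scene_params()] fields overriding the base
#'   parameters for this scenario (e.g. `necrotic_frac`).
#' @return A `scenario` object.
#' @export
scenario <- function(label, n_images, counts, overrides = list()) {
  stopifnot(is.character(label), n_images >= 1, length(counts) >= 1L)
  counts <- as.list(counts)
  if (!counts[[1L]] %in% c("truncnorm", "uniform_int", "constant")) {
    stop_rz("unknown count distribution '%s'", counts[[1L]],
            class = "invalid_design")
  }
  if (length(counts) > 1L) {
    counts[-1L] <- lapply(counts[-1L], as.numeric)
  }
  structure(list(label = label, n_images = as.integer(n_images),
                 counts = counts, overrides = overrides),
            class = "scenario")
}

draw_count <- function(counts) {
  switch(counts[[1L]],
    truncnorm = {
      for (i in 1:100) {
        x <- rnorm(1, counts[[2L]], counts[[3L]])
        if (x >= 0) return(as.integer(round(x)))
      }
      0L
    },
    uniform_int = sample(seq.int(counts[[2L]], counts[[3L]]), 1L),
    constant = as.integer(counts[[2L]]))
}

#' Experiment design: a list of scenarios
#'
#' @param ... [scenario()] objects.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(...) {
  sc <- list(...)
  if (length(sc) == 1L && is.list(sc[[1L]]) && !inherits(sc[[1L]], "scenario")) {
    sc <- sc[[1L]]
  }
  stopifnot(length(sc) >= 1L, all(vapply(sc, inherits, logical(1), "scenario")))
  if (anyDuplicated(vapply(sc, `[[`, character(1), "label"))) {
    stop_rz("scenario labels must be unique", class = "invalid_design")
  }
  structure(list(scenarios = sc), class = "experiment_design")
}

#' Single-susceptible-line benchmark design
#'
#' Nineteen rhizotrons of one susceptible line with true counts drawn
#' uniformly over 10-80 tubercles, mirroring a manual-versus-automatic
#' agreement experiment on a single genotype.
#'
#' @param n_images Number of rhizotrons.
#' @param count_range Integer range of true counts.
#' @return An `experiment_design`.
#' @export
design_single_line <- function(n_images = 19L, count_range = c(10L, 80L)) {
  experiment_design(scenario("susceptible", n_images,
                             list("uniform_int", count_range[1L], count_range[2L])))
}

#' Genotype-panel benchmark design
#'
#' Four resistance scenarios — susceptible (counts ~ N(45, 6) truncated),
#' intermediate (~ N(15, 5)), tolerant (0-4 tubercles) and fully resistant
#' (always 0) — five rhizotrons each, mirroring a multi-genotype phenotyping
#' experiment that includes zero-count images.
#'
#' @param n_per_scenario Rhizotrons per scenario.
#' @return An `experiment_design`.
#' @export
design_genotype_panel <- function(n_per_scenario = 5L) {
  experiment_design(
    scenario("susceptible", n_per_scenario, list("truncnorm", 45, 6)),
    scenario("intermediate", n_per_scenario, list("truncnorm", 15, 5)),
    scenario("tolerant", n_per_scenario, list("uniform_int", 0, 4)),
    scenario("resistant", n_per_scenario, list("constant", 0)))
}

# Per-image plan for an experiment: image ids, scenarios, true counts and
# scene seeds. One master stream yields two sub-seeds per image (count draw,
# scene rendering), taken up front in design order, so extending a design
# never perturbs earlier images.
experiment_plan <- function(design, master_seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  total <- sum(vapply(design$scenarios, `[[`, integer(1), "n_images"))
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, 2L * total)
  rows <- list(); k <- 0L
  for (sc in design$scenarios) {
    for (i in seq_len(sc$n_images)) {
      k <- k + 1L
      set.seed(seeds[2L * k - 1L])
      rows[[k]] <- data.frame(
        image_id = sprintf("%s_%03d", sc$label, i), scenario = sc$label,
        true_count = draw_count(sc$counts), seed = seeds[2L * k],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

scenario_params <- function(base_params, design, scenario_label, n, seed) {
  sc <- Filter(function(s) s$label == scenario_label, design$scenarios)[[1L]]
  p <- base_params
  for (nm in names(sc$overrides)) p[[nm]] <- sc$overrides[[nm]]
  p$n_tubercles <- n
  p$seed <- seed
  p
}

#' Generate a full synthetic experiment
#'
#' Draws per-image true counts from each scenario's distribution and renders
#' every image with [generate_rhizotron_image()]. A master seed feeds one
#' global stream from which two sub-seeds per image (count draw, scene
#' rendering) are taken up front, so extending a design never perturbs
#' earlier images.
#'
#' @param design An [experiment_design()].
#' @param base_params [scene_params()] shared by all scenarios (per-scenario
#'   `overrides` are applied on top; `n_tubercles` and `seed` are set per
#'   image).
#' @param master_seed Integer master seed.
#' @param output_dir If non-`NULL`, images are written as PNG plus
#'   `truth.csv` and `manifest.csv`; otherwise images are kept in memory.
#' @return A list with `manifest` (data frame `image_id`, `scenario`,
#'   `true_count`, `seed`), `truth` (pooled ground-truth table), and `images`
#'   (named list of RGB arrays; empty when written to disk).
#' @export
generate_experiment <- function(design, base_params = scene_params(),
                                master_seed = 1L, output_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(base_params, "scene_params"))
  plan <- experiment_plan(design, master_seed)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  truths <- list(); images <- list()
  for (k in seq_len(nrow(plan))) {
    p <- scenario_params(base_params, design, plan$scenario[k],
                         plan$true_count[k], plan$seed[k])
    out <- generate_rhizotron_image(p, image_id = plan$image_id[k])
    truths[[plan$image_id[k]]] <- out$truth
    if (is.null(output_dir)) {
      images[[plan$image_id[k]]] <- out$image
    } else {
      write_image_rgb(out$image, file.path(output_dir,
                                           paste0(plan$image_id[k], ".png")))
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  if (!is.null(output_dir)) {
    utils::write.csv(round_truth(truth), file.path(output_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(plan, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(manifest = plan, truth = truth, images = images,
       output_dir = output_dir)
}

round_truth <- function(truth) {
  for (cc in c("x_mm", "y_mm", "radius_mm")) truth[[cc]] <- round(truth[[cc]], 6)
  truth
}
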