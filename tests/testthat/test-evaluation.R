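pts <- function(x, y, id = "img") {
  data.frame(image_id = rep(id, length(x)), truth_id = seq_along(x),
             x_mm = x, y_mm = y, radius_mm = rep(1, length(x)),
             class = rep("tubercle", length(x)), stringsAsFactors = FALSE)
}
dets <- function(x, y, id = "img") {
  structure(data.frame(particle_id = seq_along(x),
                       class = rep("tubercle", length(x)),
                       centroid_x_mm = x, centroid_y_mm = y,
                       stringsAsFactors = FALSE),
            class = c("particle_set", "data.frame"), image_id = id)
}

test_that("identical point sets match perfectly", {
  m <- match_particles(dets(c(1, 5, 9), c(1, 5, 9)), pts(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(m$tp, 3L); expect_equal(m$fp, 0L); expect_equal(m$fn, 0L)
  expect_equal(m$recall, 1); expect_equal(m$precision, 1)
})

test_that("empty detection sets give zero recall, not division errors", {
  m <- match_particles(dets(numeric(), numeric()), pts(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(m$tp, 0L); expect_equal(m$fn, 3L)
  expect_equal(m$recall, 0)
  expect_true(is.nan(m$precision))
  m2 <- match_particles(dets(numeric(), numeric()), pts(numeric(), numeric()))
  expect_true(is.nan(m2$recall)); expect_true(is.nan(m2$precision))
})

test_that("the distance threshold separates matches from misses", {
  m1 <- match_particles(dets(1.5, 0), pts(0, 0), tolerance_mm = 2)
  expect_equal(m1$tp, 1L)
  expect_equal(m1$pairs$distance_mm, 1.5)
  m2 <- match_particles(dets(2.5, 0), pts(0, 0), tolerance_mm = 2)
  expect_equal(m2$tp, 0L); expect_equal(m2$fp, 1L); expect_equal(m2$fn, 1L)
})

test_that("matching is one-to-one, nearest-first", {
  # one detection between two truths: pairs with the nearer one only
  m <- match_particles(dets(1.2, 0), pts(c(0, 2), c(0, 0)), tolerance_mm = 2)
  expect_equal(m$tp, 1L)
  expect_equal(m$pairs$truth_id, 2L)  # 0.8 mm beats 1.2 mm
  expect_equal(m$fn, 1L)
  # two detections, two truths, crossing distances resolved greedily
  m2 <- match_particles(dets(c(0, 1), c(0, 0)), pts(c(0.2, 1.4), c(0, 0)))
  expect_equal(m2$tp, 2L)
})

test_that("swapping detections and truth swaps recall and precision", {
  set.seed(61)
  for (i in 1:10) {
    na <- sample(3:8, 1); nt <- sample(3:8, 1)
    ax <- runif(na, 0, 20); ay <- runif(na, 0, 20)
    tx <- runif(nt, 0, 20); ty <- runif(nt, 0, 20)
    m <- match_particles(dets(ax, ay), pts(tx, ty))
    m_swap <- match_particles(dets(tx, ty), pts(ax, ay))
    expect_equal(m$recall, m_swap$precision)
    expect_equal(m$precision, m_swap$recall)
    expect_equal(m$tp, m_swap$tp)
  }
})

test_that("raising the tolerance never loses true positives", {
  set.seed(62)
  for (i in 1:10) {
    ax <- runif(6, 0, 15); ay <- runif(6, 0, 15)
    tx <- runif(6, 0, 15); ty <- runif(6, 0, 15)
    tps <- vapply(c(0.5, 1, 2, 4, 8), function(tol) {
      match_particles(dets(ax, ay), pts(tx, ty), tolerance_mm = tol)$tp
    }, integer(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("mismatched image ids are rejected", {
  expect_error(match_particles(dets(1, 1, id = "a"), pts(1, 1, id = "b")),
               class = "evaluation_error")
})

test_that("count agreement reproduces hand-computed statistics", {
  a1 <- agreement_stats(data.frame(reference = c(10, 20, 30),
                                   automatic = c(10, 20, 30)))
  expect_equal(a1$pearson_r, 1)
  expect_equal(a1$slope_origin, 1)
  a2 <- agreement_stats(data.frame(reference = c(10, 20, 30),
                                   automatic = c(20, 40, 60)))
  expect_equal(a2$pearson_r, 1)
  expect_equal(a2$slope_origin, 2)
  # hand-computed product-moment oracle
  a3 <- agreement_stats(data.frame(reference = c(10, 20, 30),
                                   automatic = c(12, 18, 33)))
  expect_equal(a3$slope_origin, 1470 / 1400)
  expect_equal(a3$pearson_r, 210 / sqrt(200 * 234), tolerance = 1e-12)
  expect_equal(round(a3$pearson_r, 4), 0.9707)
})

test_that("degenerate count vectors give NA statistics, not errors", {
  a <- agreement_stats(data.frame(reference = c(5, 5, 5), automatic = c(1, 2, 3)))
  expect_true(is.na(a$pearson_r))
  expect_equal(a$slope_origin, sum(c(5, 5, 5) * c(1, 2, 3)) / 75)
  z <- agreement_stats(data.frame(reference = c(0, 0), automatic = c(1, 2)))
  expect_true(is.na(z$slope_origin))
})

test_that("agreement is order-invariant, and r (but not slope) is symmetric", {
  set.seed(63)
  x <- sample(10:60, 8); y <- x + sample(-4:4, 8, replace = TRUE)
  a <- agreement_stats(data.frame(reference = x, automatic = y))
  perm <- sample(8)
  ap <- agreement_stats(data.frame(reference = x[perm], automatic = y[perm]))
  expect_equal(a$pearson_r, ap$pearson_r)
  expect_equal(a$slope_origin, ap$slope_origin)
  sw <- agreement_stats(data.frame(reference = y, automatic = x))
  expect_equal(sw$pearson_r, a$pearson_r)
  expect_false(isTRUE(all.equal(sw$slope_origin, a$slope_origin)))
})

test_that("experiment-level reports pool matching and count agreement", {
  set.seed(64)
  sets <- list(); truths <- list()
  for (i in 1:5) {
    id <- paste0("img", i)
    x <- runif(6, 0, 20); y <- runif(6, 0, 20)
    sets[[id]] <- dets(x, y, id = id)
    truths[[id]] <- pts(x, y, id = id)
  }
  truth <- do.call(rbind, truths)
  rep1 <- evaluate_experiment(sets, truth)
  expect_equal(rep1$recall_mean, 1); expect_equal(rep1$recall_sd, 0)
  expect_equal(rep1$precision_mean, 1)
  # one image fully missed among four perfect ones
  sets$img3 <- dets(numeric(), numeric(), id = "img3")
  rep2 <- evaluate_experiment(sets, truth)
  expect_equal(rep2$recall_mean, 0.8)
  expect_equal(rep2$n_precision, 4L)  # precision undefined on the empty image
  # an image without any truth is excluded and reported
  sets$extra <- dets(1, 1, id = "extra")
  expect_message(rep3 <- evaluate_experiment(sets, truth), "extra")
  expect_equal(rep3$excluded, "extra")
  expect_equal(nrow(rep3$per_image), 5L)
})

test_that("zero-count images enter the pooled counts via empty_truth_ids", {
  sets <- list(a = dets(c(1, 5), c(1, 5), id = "a"),
               b = dets(numeric(), numeric(), id = "b"))
  truth <- pts(c(1, 5), c(1, 5), id = "a")
  rep <- evaluate_experiment(sets, truth, empty_truth_ids = "b")
  expect_equal(nrow(rep$per_image), 2L)
  expect_equal(rep$per_image$n_truth[rep$per_image$image_id == "b"], 0L)
})
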