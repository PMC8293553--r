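test_that("the generator is bit-reproducible given a seed", {
  a <- generate_rhizotron_image(small_scene(n = 6, seed = 101), "rep")
  b <- generate_rhizotron_image(small_scene(n = 6, seed = 101), "rep")
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_rhizotron_image(small_scene(n = 6, seed = 102), "rep")
  expect_false(identical(a$image, c$image))
})

test_that("an empty scene yields an empty truth and a zero count", {
  out <- generate_rhizotron_image(small_scene(n = 0, seed = 1), "empty")
  expect_equal(nrow(out$truth), 0L)
  ps <- count_tubercles(out$image, pipeline_config(), image_id = "empty")
  expect_equal(attr(ps, "counts")[["tubercle"]], 0L)
})

test_that("clean scenes are recovered perfectly across seeds", {
  for (seed in 1:5) {
    out <- generate_rhizotron_image(small_scene(n = 8, seed = seed), "clean")
    ps <- count_tubercles(out$image, pipeline_config(), image_id = "clean")
    m <- match_particles(ps, out$truth)
    expect_equal(m$recall, 1)
    expect_equal(m$precision, 1)
  }
})

test_that("every tubercle-class colour is detectable in isolation", {
  # the colour model and the detection band must be consistent by construction
  band <- hsb_range(0, 55, 102, 255, 95, 255)
  set.seed(71)
  for (i in 1:50) {
    hsb <- rhizocount:::draw_class_hsb("tubercle")
    col <- rhizocount:::hsb_bytes_to_rgb(hsb["h"], hsb["s"], hsb["b"])[1, ]
    img <- flat_image(60, 60)
    img[25:35, 25:35, 1] <- col[1]
    img[25:35, 25:35, 2] <- col[2]
    img[25:35, 25:35, 3] <- col[3]
    mask <- threshold_hsb(rgb_to_hsb(img), band)
    expect_equal(sum(mask), 121)
  }
  for (cls in c("pale", "necrotic")) {
    for (i in 1:20) {
      hsb <- rhizocount:::draw_class_hsb(cls)
      col <- rhizocount:::hsb_bytes_to_rgb(hsb["h"], hsb["s"], hsb["b"])[1, ]
      img <- flat_image(60, 60)
      img[25:35, 25:35, 1] <- col[1]
      img[25:35, 25:35, 2] <- col[2]
      img[25:35, 25:35, 3] <- col[3]
      expect_equal(sum(threshold_hsb(rgb_to_hsb(img), band)), 0)
    }
  }
})

test_that("raising pale fraction lowers recall; distractors lower precision", {
  seeds <- 1:20
  run_one <- function(seed, ...) {
    out <- generate_rhizotron_image(small_scene(n = 8, seed = seed, ...), "c")
    ps <- count_tubercles(out$image, pipeline_config(), image_id = "c")
    match_particles(ps, out$truth)
  }
  rec_clean <- vapply(seeds, function(s) run_one(s)$recall, numeric(1))
  rec_pale <- vapply(seeds, function(s) run_one(s, pale_frac = 0.4)$recall,
                     numeric(1))
  expect_lt(mean(rec_pale), mean(rec_clean))
  prec_clean <- vapply(seeds, function(s) run_one(s)$precision, numeric(1))
  prec_dist <- vapply(seeds, function(s) run_one(s, n_distractors = 3L)$precision,
                      numeric(1))
  expect_lt(mean(prec_dist), mean(prec_clean))
})

test_that("touching clusters merge into fewer detected particles", {
  merged <- 0L
  for (seed in 1:10) {
    out <- generate_rhizotron_image(small_scene(n = 10, seed = seed,
                                                cluster_frac = 0.6), "cl")
    ps <- count_tubercles(out$image, pipeline_config(), image_id = "cl")
    merged <- merged + (nrow(out$truth) - nrow(ps))
  }
  expect_gt(merged, 0L)
})

test_that("experiment designs draw counts per scenario with a manifest", {
  design <- experiment_design(
    scenario("susceptible", 4, list("truncnorm", 12, 3)),
    scenario("tolerant", 3, list("uniform_int", 0, 2)),
    scenario("resistant", 3, list("constant", 0)))
  res <- generate_experiment(design, small_scene(n = 0, seed = 1),
                             master_seed = 5)
  expect_equal(nrow(res$manifest), 10L)
  expect_equal(res$manifest$true_count[res$manifest$scenario == "resistant"],
               rep(0L, 3))
  expect_true(all(res$manifest$true_count[res$manifest$scenario == "tolerant"]
                  %in% 0:2))
  expect_equal(sum(res$manifest$true_count), nrow(res$truth))
  means <- tapply(res$manifest$true_count, res$manifest$scenario, mean)
  expect_gt(means[["susceptible"]], means[["tolerant"]])
  expect_gte(means[["tolerant"]], means[["resistant"]])
})

test_that("extending a design never perturbs earlier images", {
  d1 <- experiment_design(scenario("a", 3, list("uniform_int", 2, 6)))
  d2 <- experiment_design(scenario("a", 5, list("uniform_int", 2, 6)))
  p1 <- rhizocount:::experiment_plan(d1, master_seed = 9)
  p2 <- rhizocount:::experiment_plan(d2, master_seed = 9)
  expect_equal(p1, p2[1:3, ])
})

test_that("uniform-range designs keep manifest counts within range", {
  d <- design_single_line(n_images = 6, count_range = c(10, 80))
  p <- rhizocount:::experiment_plan(d, master_seed = 3)
  expect_true(all(p$true_count >= 10 & p$true_count <= 80))
  expect_equal(nrow(p), 6L)
  d2 <- design_genotype_panel(2)
  p2 <- rhizocount:::experiment_plan(d2, master_seed = 3)
  expect_equal(nrow(p2), 8L)
  expect_true(all(p2$true_count[p2$scenario == "resistant"] == 0))
})

test_that("overfull scenes fail with a placement error", {
  p <- scene_params(canvas_px = c(200, 200), n_tubercles = 60,
                    radius_range_mm = c(0.5, 1.5), seed = 1)
  expect_error(generate_rhizotron_image(p), class = "placement_error")
})
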