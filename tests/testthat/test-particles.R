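cal22 <- scale_calibration(22)
band_size <- size_range(0.05, 20)
wide_size <- size_range(0, 1e9)

test_that("hole filling fills enclosed background only", {
  # annulus -> solid disc
  ring <- disc_mask(40, 40, 20, 20, 12) & !disc_mask(40, 40, 20, 20, 6)
  expect_equal(fill_holes(ring), disc_mask(40, 40, 20, 20, 12))
  # solid disc unchanged
  disc <- disc_mask(40, 40, 20, 20, 10)
  expect_equal(fill_holes(disc), disc)
  # C-shape open to the border stays open (oracle agreement)
  cshape <- matrix(FALSE, 20, 20)
  cshape[5:15, 5:15] <- TRUE
  cshape[8:12, 8:20] <- FALSE
  expect_equal(fill_holes(cshape), oracle_fill_holes(cshape))
  expect_true(all(fill_holes(cshape) >= cshape))
})

test_that("particle area conversion and size filtering follow the calibration", {
  # a 314-px blob at 22 px/mm is 0.6488 mm^2, inside 0.05-20
  mask <- matrix(FALSE, 30, 170)
  mask[10:11, 5:161] <- TRUE  # 2 x 157 = 314 px
  ps <- find_particles(mask, cal22, band_size)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$area_px, 314L)
  expect_equal(ps$area_mm2, 314 / 484, tolerance = 1e-12)
  # a 5-px speck is 0.0103 mm^2 and is filtered out
  speck <- matrix(FALSE, 10, 10)
  speck[3, 3:7] <- TRUE
  expect_equal(nrow(find_particles(speck, cal22, band_size)), 0L)
  # but kept when the filter allows it
  expect_equal(nrow(find_particles(speck, cal22, wide_size)), 1L)
  # size bounds are inclusive at both ends: with pixel area exactly
  # 1/16 mm^2 (4 px/mm), a 4-px particle of exactly 0.25 mm^2 survives a
  # filter whose min or max equals its area
  exact <- matrix(FALSE, 20, 20)
  exact[1:2, 1:2] <- TRUE  # 4 px
  cal4 <- scale_calibration(4)
  expect_equal(nrow(find_particles(exact, cal4, size_range(0.25, 20))), 1L)
  expect_equal(nrow(find_particles(exact, cal4, size_range(0.01, 0.25))), 1L)
  expect_equal(find_particles(exact, cal4, size_range(0.25, 20))$area_mm2, 0.25)
})

test_that("diagonally touching blobs merge under 8-connectivity", {
  mask <- matrix(FALSE, 20, 20)
  mask[3:6, 3:6] <- TRUE
  mask[7:10, 7:10] <- TRUE  # touches only at the (6,6)/(7,7) diagonal
  ps <- find_particles(mask, cal22, wide_size)
  expect_equal(nrow(ps), 1L)
  expect_equal(oracle_count_components(mask), 1L)
  mask[7, 7] <- FALSE  # break the corner contact on one side only
  mask[6, 6] <- FALSE
  expect_equal(nrow(find_particles(mask, cal22, wide_size)),
               oracle_count_components(mask))
})

test_that("particle ids follow raster order of first pixels", {
  mask <- matrix(FALSE, 30, 30)
  mask[20:22, 2:4] <- TRUE    # lower-left, but appears later in raster order
  mask[2:4, 20:22] <- TRUE    # topmost first
  mask[10:12, 10:12] <- TRUE
  ps <- find_particles(mask, cal22, wide_size)
  expect_equal(ps$particle_id, 1:3)
  expect_equal(order(ps$bbox_y), 1:3)
})

test_that("component areas conserve the foreground pixel count", {
  set.seed(21)
  for (i in 1:10) {
    mask <- fill_holes(random_mask(40, 40, runif(1, 0.2, 0.5)))
    ps <- find_particles(mask, cal22, wide_size)
    expect_equal(sum(ps$area_px), sum(mask))
  }
})

test_that("centroids are binary centres of mass in mm from the crop origin", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:7, 9:11] <- TRUE  # 3x3 square centred at 0-based (x=9, y=5)
  ps <- find_particles(mask, cal22, wide_size)
  expect_equal(ps$centroid_x_mm, 9 / 22)
  expect_equal(ps$centroid_y_mm, 5 / 22)
  expect_equal(ps$bbox_x, 8L); expect_equal(ps$bbox_y, 4L)
  expect_equal(ps$bbox_w, 3L); expect_equal(ps$bbox_h, 3L)
})

test_that("translation shifts centroids exactly and preserves counts/areas", {
  set.seed(31)
  base <- matrix(FALSE, 60, 60)
  base[10:20, 10:25] <- random_mask(11, 16, 0.6)
  base[35:45, 30:40] <- random_mask(11, 11, 0.6)
  ps0 <- find_particles(base, cal22, wide_size)
  for (shift in list(c(3L, 5L), c(10L, 2L))) {
    dx <- shift[1L]; dy <- shift[2L]
    moved <- matrix(FALSE, 60, 60)
    idx <- which(base, arr.ind = TRUE)
    moved[cbind(idx[, 1] + dy, idx[, 2] + dx)] <- TRUE
    ps1 <- find_particles(moved, cal22, wide_size)
    expect_equal(nrow(ps1), nrow(ps0))
    expect_equal(ps1$area_px, ps0$area_px)
    expect_equal(ps1$centroid_x_mm, ps0$centroid_x_mm + dx / 22)
    expect_equal(ps1$centroid_y_mm, ps0$centroid_y_mm + dy / 22)
  }
})

test_that("counting is invariant under 2x upsampling with doubled calibration", {
  discs <- disc_mask(80, 80, 20, 20, 6) | disc_mask(80, 80, 55, 50, 12)
  up <- kronecker(discs, matrix(TRUE, 2, 2)) == 1
  ps1 <- find_particles(discs, cal22, band_size)
  ps2 <- find_particles(up, scale_calibration(44), band_size)
  expect_equal(nrow(ps2), nrow(ps1))
  expect_equal(ps2$area_mm2, ps1$area_mm2, tolerance = 0.05)
})

test_that("enlarging the size range never decreases the particle count", {
  set.seed(41)
  for (i in 1:5) {
    mask <- random_mask(50, 50, 0.35)
    n_narrow <- nrow(find_particles(mask, cal22, size_range(0.01, 0.5)))
    n_wide <- nrow(find_particles(mask, cal22, size_range(0.005, 1)))
    expect_gte(n_wide, n_narrow)
  }
})
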