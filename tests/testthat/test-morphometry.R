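test_that("acquisition sizing rule gives the minimum pixel count", {
  expect_identical(pixel_resolution(300, 1), 600L)
  expect_identical(pixel_resolution(5, 5), 2L)
  expect_identical(pixel_resolution(450, 1.5), 600L)
  expect_identical(pixel_resolution(100, 0.3), as.integer(ceiling(100 / 0.3 * 2)))
  expect_error(pixel_resolution(-1, 1), "positive")
  expect_error(pixel_resolution(1, 300), ">=")
})

test_that("plate calibration derives the pixel pitch", {
  cal <- calibrate_plate(plate_presets$a3, c(2970, 4200))
  expect_equal(cal$mm_per_pixel, 0.1)
  expect_equal(cal$pixel_area_mm2, 0.01)

  expect_warning(cal2 <- calibrate_plate(c(100, 100), c(1000, 500)),
                 "2%")
  expect_equal(cal2$mm_per_pixel, mean(c(0.1, 0.2)))

  expect_error(calibrate_plate(c(0, 100), c(10, 10)), "positive")

  fx <- get_suite()$axial_tube
  d <- dim(unclass(fx$image))
  cal3 <- calibrate_plate(fx$spec$plate_mm, c(d[2], d[1]))
  expect_equal(cal3$mm_per_pixel, fx$truth$mm_per_pixel)
})

test_that("projected area is the calibrated foreground count", {
  cal <- test_cal()
  empty <- binary_mask(matrix(0L, 5, 5))
  expect_equal(projected_area(empty, cal), list(area_mm2 = 0, n_pixels = 0L))

  block <- matrix(0L, 20, 20); block[6:15, 6:15] <- 1L
  pa <- projected_area(binary_mask(block), cal)
  expect_equal(pa$n_pixels, 100L)
  expect_equal(pa$area_mm2, 1.0)
  # exact linearity in the pixel count
  block[1, 1] <- 1L
  expect_equal(projected_area(binary_mask(block), cal)$area_mm2, 1.01)
})

test_that("lateral area follows the cylinder projection identity", {
  expect_equal(lateral_surface_area(0), 0)
  expect_equal(lateral_surface_area(10), 10 * pi)
  expect_equal(lateral_surface_area(10, "literal", m = 3), 30 * pi)
  expect_error(lateral_surface_area(-1), ">= 0")
  # exact linearity
  expect_equal(lateral_surface_area(7.3) / 7.3, pi)
})

test_that("skeletonization thins to a one-pixel-wide connected curve", {
  bar <- matrix(0L, 30, 70); bar[14:16, 11:60] <- 1L
  sk <- unclass(skeletonize(binary_mask(bar)))
  idx <- which(sk == 1L, arr.ind = TRUE)
  expect_gte(diff(range(idx[, 2])), 44)      # spans nearly the full bar
  nb <- rootmorph:::neighbour_count(sk)
  expect_lte(max(nb[sk == 1L]), 2L)          # a simple path
  expect_equal(sum(nb[sk == 1L] == 1L), 2L)  # exactly two endpoints

  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_identical(unclass(skeletonize(binary_mask(single))), single)
  empty <- matrix(0L, 5, 5)
  expect_identical(unclass(skeletonize(binary_mask(empty))), empty)
})

test_that("skeletons are subsets of the mask with no 2x2 blocks", {
  set.seed(41)
  for (i in 1:15) {
    m <- binary_close(random_mask(28, 28, p = 0.55), se_box(3))
    sk <- unclass(skeletonize(m))
    expect_true(all(sk <= unclass(m)))
    blocks <- sk[-1, -1] & sk[-nrow(sk), -1] &
      sk[-1, -ncol(sk)] & sk[-nrow(sk), -ncol(sk)]
    expect_false(any(blocks))
  }
})

test_that("chain-code length weights axial and diagonal steps exactly", {
  cal <- test_cal()
  axial <- matrix(0L, 5, 15); axial[3, 3:13] <- 1L  # 11 pixels
  res <- chain_code_length(binary_mask(axial), cal)
  expect_equal(res$n1, 10L)
  expect_equal(res$n2, 0L)
  expect_equal(res$length_mm, 10 * 0.1)

  diag_m <- matrix(0L, 15, 15); diag_m[cbind(3:13, 3:13)] <- 1L
  res2 <- chain_code_length(binary_mask(diag_m), cal)
  expect_equal(res2$n1, 0L)
  expect_equal(res2$n2, 10L)
  expect_equal(res2$length_mm, 10 * sqrt(2) * 0.1)

  # L-path: 6 axial steps then 5 diagonal steps
  lpath <- matrix(0L, 10, 15)
  lpath[2, 2:8] <- 1L
  lpath[cbind(3:7, 9:13)] <- 1L
  res3 <- chain_code_length(binary_mask(lpath), cal)
  expect_equal(res3$n1, 6L)
  expect_equal(res3$n2, 5L)
  expect_equal(res3$length_mm, (6 + 5 * sqrt(2)) * 0.1)

  # isolated pixels contribute no steps
  dot <- matrix(0L, 4, 4); dot[2, 2] <- 1L
  expect_equal(chain_code_length(binary_mask(dot), cal)$length_mm, 0)
})

test_that("inscribed-circle detection recovers disk radii", {
  mk_disk <- function(H, W, centres, radii) {
    x <- matrix(rep(seq_len(W), each = H), H, W)
    y <- matrix(rep(seq_len(H), W), H, W)
    m <- matrix(0L, H, W)
    for (i in seq_along(radii))
      m[(x - centres[[i]][2])^2 + (y - centres[[i]][1])^2 < radii[i]^2] <- 1L
    binary_mask(m)
  }
  one <- mk_disk(60, 60, list(c(30, 30)), 20)
  cs <- detect_circles(one)
  expect_equal(nrow(cs), 1L)
  expect_lt(abs(cs$radius_px - 20), 1)

  expect_equal(nrow(detect_circles(binary_mask(matrix(0L, 10, 10)))), 0L)

  two <- mk_disk(80, 140, list(c(40, 35), c(40, 100)), c(10, 30))
  cs2 <- detect_circles(two)
  expect_equal(nrow(cs2), 2L)
  expect_true(all(abs(sort(cs2$radius_px) - c(10, 30)) < 1))

  # radius range is honoured
  expect_equal(nrow(detect_circles(one, r_range = c(0, 10))), 0L)
})

test_that("average diameter is the calibrated mean of the radii", {
  cal <- test_cal()
  expect_equal(average_diameter(as_circle_set(5), cal), 1.0)
  cal1 <- calibrate_plate(c(100, 100), c(100, 100))  # 1 mm/px
  expect_equal(average_diameter(as_circle_set(c(10, 20, 30)), cal1), 40)
  expect_true(is.na(average_diameter(as_circle_set(numeric(0)), cal)))
})

test_that("volume follows the cylinder model and propagates missingness", {
  expect_equal(root_volume(2, 100, "cylinder"), pi * 100)
  expect_equal(root_volume(2, 0, "cylinder"), 0)
  expect_equal(root_volume(2, 0, "literal"), 0)
  expect_equal(root_volume(3, 10, "literal"), 15)
  expect_true(is.na(root_volume(NA_real_, 10, "cylinder")))
  expect_error(root_volume(1, -1), ">= 0")
})

test_that("measure_root recovers the generator ground truth", {
  cal <- test_cal()
  suite <- get_suite()
  tubes <- c("axial_tube", "diagonal_tube", "rotated45_tube", "y_branch")
  for (nm in tubes) {
    fx <- suite[[nm]]
    m <- measure_root(preprocess_root(fx$image), cal)
    tr <- fx$truth
    expect_lt(abs(m$length_mm / tr$total_length_mm - 1), 0.02, label = nm)
    expect_lt(abs(m$projected_area_mm2 / tr$projected_area_mm2 - 1), 0.02,
              label = nm)
    expect_lt(abs(m$avg_diameter_mm / tr$mean_width_mm - 1), 0.05, label = nm)
    expect_lt(abs(m$volume_mm3 / tr$volume_mm3 - 1), 0.05, label = nm)
    # internal consistency of the cylinder model
    expect_equal(m$volume_mm3, pi * (m$avg_diameter_mm / 2)^2 * m$length_mm)
    expect_equal(m$surface_area_mm2, pi * m$projected_area_mm2)
  }
})

test_that("an empty mask flags no root instead of fabricating zeros", {
  cal <- test_cal()
  m <- measure_root(binary_mask(matrix(0L, 10, 10)), cal)
  expect_true(m$no_root)
  expect_equal(m$length_mm, 0)
  expect_equal(m$circle_count, 0L)
})

test_that("physical measurements are stable across pixel pitches", {
  seg <- data.frame(x0 = 10, y0 = 30, x1 = 90, y1 = 30, width = 2)
  out <- lapply(c(0.1, 0.2), function(p) {
    fx <- render_root(root_spec(seg, c(100, 60), p))
    cal <- calibrate_plate(c(100, 60), c(100, 60) / p)
    measure_root(preprocess_root(fx$image), cal)
  })
  for (f in c("length_mm", "projected_area_mm2", "avg_diameter_mm",
              "volume_mm3"))
    expect_lt(abs(out[[1]][[f]] / out[[2]][[f]] - 1), 0.03, label = f)
})
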