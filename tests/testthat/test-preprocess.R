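test_that("grayscale conversion matches the channel weights", {
  px <- function(r, g, b) color_image(array(c(r, g, b), c(1, 1, 3)))
  expect_equal(unclass(to_gray(px(255, 255, 255), "weighted"))[1, 1], 255L)
  expect_equal(unclass(to_gray(px(0, 0, 0), "weighted"))[1, 1], 0L)
  expect_equal(unclass(to_gray(px(0, 0, 0), "blue_channel"))[1, 1], 0L)
  # 255 * 0.299 = 76.245, rounded half-up
  expect_equal(unclass(to_gray(px(255, 0, 0), "weighted"))[1, 1], 76L)
  expect_equal(unclass(to_gray(px(10, 20, 200), "blue_channel"))[1, 1], 200L)

  set.seed(11)
  a <- array(sample(0:255, 8 * 9 * 3, TRUE), c(8, 9, 3))
  img <- color_image(a)
  expect_identical(unclass(to_gray(img, "blue_channel")), a[, , 3])
  expected <- floor(a[, , 1] * 0.299 + a[, , 2] * 0.587 + a[, , 3] * 0.114 + 0.5)
  expect_identical(unclass(to_gray(img, "weighted")),
                   matrix(as.integer(expected), 8, 9))
})

test_that("histogram counts every pixel exactly once", {
  img <- gray_image(matrix(7L, 2, 2))
  h <- compute_histogram(img)
  expect_equal(h$counts[8], 4L)
  expect_equal(sum(h$counts), 4L)

  img2 <- gray_image(matrix(c(0L, 0L, 255L), 1, 3))
  h2 <- compute_histogram(img2)
  expect_equal(h2$counts[1], 2L)
  expect_equal(h2$counts[256], 1L)

  set.seed(3)
  img3 <- random_gray(64, 64)
  h3 <- compute_histogram(img3)
  tally <- vapply(0:255, function(k) sum(unclass(img3) == k), integer(1))
  expect_identical(h3$counts, tally)
  expect_equal(sum(h3$counts), 64L * 64L)
})

test_that("valley threshold finds a unique interior minimum or declines", {
  k <- 0:255
  # two clean triangular modes at 40 and 255 meeting at a unique zero at 120
  bimodal <- make_histogram(pmax(0, 160 - 2 * abs(k - 40)) +
                            pmax(0, 2 * (k - 120)))
  res <- valley_threshold(bimodal)
  expect_s3_class(res, "threshold_result")
  expect_equal(res$threshold, 120L)
  expect_equal(res$method, "valley")

  # overlapping triangles with asymmetric slopes: unique smoothed minimum
  overlap <- make_histogram(pmax(0, 2 * (65 - abs(k - 40))) +
                            pmax(0, 100 - abs(k - 200)))
  expect_equal(valley_threshold(overlap)$threshold, 105L)

  # unimodal: no valley exists
  unimodal <- make_histogram(round(10000 * dnorm(k, 128, 30)))
  expect_null(valley_threshold(unimodal))

  # two spikes with a broad flat valley: minimum not unique
  spikes <- integer(256); spikes[c(51, 181)] <- 100L
  expect_null(valley_threshold(make_histogram(spikes)))

  expect_error(valley_threshold(make_histogram(integer(256))), "empty")
})

test_that("iterative threshold reaches the ISODATA fixed point", {
  spike2 <- integer(256); spike2[c(1, 256)] <- 100L
  res <- iterative_threshold(make_histogram(spike2), t0 = 128)
  expect_equal(res$threshold, 128L)
  expect_equal(res$method, "iterative")

  # all mass at one gray level: that level, no iterations
  single <- integer(256); single[101] <- 50L
  res1 <- iterative_threshold(make_histogram(single))
  expect_equal(res1$threshold, 100L)
  expect_equal(res1$iterations, 0L)

  expect_error(iterative_threshold(make_histogram(integer(256))), "empty")
})

test_that("iterative threshold is invariant to the start between two spikes", {
  spikes <- integer(256); spikes[c(11, 201)] <- 50L  # levels 10 and 200
  h <- make_histogram(spikes)
  fixed <- vapply(seq(11, 199, by = 4), function(t0)
    iterative_threshold(h, t0)$threshold, integer(1))
  expect_true(all(fixed == fixed[1]))
  expect_equal(fixed[1], 105L)  # midpoint of the two class means
})

test_that("iterative threshold terminates within 256 steps on random data", {
  set.seed(21)
  for (i in 1:25) {
    img <- random_gray(32, 32)
    res <- iterative_threshold(compute_histogram(img))
    expect_lte(res$iterations, 256L)
    expect_gte(res$threshold, 0L)
    expect_lte(res$threshold, 255L)
  }
})

test_that("thresholding uses strict inequalities on both polarities", {
  img <- gray_image(matrix(128L, 4, 4))
  expect_true(all(unclass(apply_threshold(img, 127, "bright_foreground")) == 1L))
  expect_true(all(unclass(apply_threshold(img, 128, "bright_foreground")) == 0L))
  expect_true(all(unclass(apply_threshold(img, 128, "dark_foreground")) == 0L))
  expect_true(all(unclass(apply_threshold(img, 129, "dark_foreground")) == 1L))
  expect_error(apply_threshold(img, 300), "255")
})

test_that("thresholding a synthetic plate recovers the root pixels", {
  fx <- get_suite()$axial_tube
  gray <- to_gray(fx$image, "blue_channel")
  t <- iterative_threshold(compute_histogram(gray))
  mask <- apply_threshold(gray, t, "dark_foreground")
  px <- fx$truth$root_pixel_set
  expect_gte(mean(unclass(mask)[px] == 1L), 0.99)
})

test_that("median filter equals the brute-force windowed sort", {
  const <- gray_image(matrix(9L, 6, 6))
  expect_identical(unclass(median_filter(const)), unclass(const))

  impulse <- matrix(0L, 7, 7); impulse[4, 4] <- 255L
  out <- median_filter(gray_image(impulse))
  expect_true(all(unclass(out) == 0L))

  set.seed(5)
  for (i in 1:5) {
    img <- random_gray(17, 23)
    for (w in list(c(3L, 3L), c(5L, 3L), c(5L, 5L))) {
      expect_identical(unclass(median_filter(img, w)),
                       oracle_median(unclass(img), w[1], w[2]))
    }
  }

  expect_error(median_filter(random_gray(4, 4), c(5, 5)), "larger")
  expect_error(median_filter(random_gray(4, 4), c(2, 2)), "odd")
})
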