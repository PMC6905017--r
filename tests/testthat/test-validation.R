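test_that("sample standard deviation uses the n-1 denominator", {
  expect_equal(sample_sd(c(4, 4, 4)), 0)
  expect_equal(sample_sd(c(1, 2, 3)), 1)
  expect_error(sample_sd(5), "two values")

  set.seed(13)
  x <- rnorm(50, 10, 3)
  two_pass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(sample_sd(x), two_pass, tolerance = 1e-12)

  # translation invariance and linear scaling
  expect_equal(sample_sd(x + 100), sample_sd(x))
  expect_equal(sample_sd(3 * x), 3 * sample_sd(x))
})

test_that("error analysis compares instrument totals", {
  expect_equal(error_analysis(c(1, 2, 3), c(1, 2, 3)),
               list(delta = 0, delta_rel_pct = 0))
  expect_equal(error_analysis(101, 100),
               list(delta = 1, delta_rel_pct = 1))

  x <- c(5000, 5083.355); y <- c(5000, 5000)   # totals 10083.355 vs 10000
  res <- error_analysis(x, y)
  expect_equal(res$delta, 83.355)
  expect_equal(res$delta_rel_pct, 0.83355)
  expect_gt(res$delta_rel_pct, 0)

  expect_error(error_analysis(1:3, 1:2), "equal length")
  expect_error(error_analysis(c(1, -1), c(1, -1)), "zero")
})

test_that("relative error obeys the swap identity", {
  set.seed(19)
  for (i in 1:20) {
    x <- runif(10, 50, 150); y <- runif(10, 50, 150)
    dxy <- error_analysis(x, y)$delta_rel_pct
    dyx <- error_analysis(y, x)$delta_rel_pct
    expect_equal(dxy * sum(y), -dyx * sum(x))
  }
})

test_that("the screened t test matches the textbook pooled formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 50)
  res <- independent_t_test(x, y)
  # hand-coded pooled-variance oracle
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_ref <- 2 * pt(-abs(t_ref), length(x) + length(y) - 2)
  expect_equal(res$pooled$t, t_ref)
  expect_equal(res$pooled$df, 8)
  expect_equal(res$pooled$p, p_ref)
})

test_that("identical and degenerate samples take the zero-t convention", {
  res <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  const <- independent_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$t_stat, 0)
  expect_equal(const$p_value, 1)
  expect_equal(const$levene_p, 1)
})

test_that("the Levene screen agrees with the reference implementation", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(12, 50, 5); y <- rnorm(15, 52, if (i %% 2) 5 else 15)
    res <- independent_t_test(x, y)
    v <- c(x, y)
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    ref <- car::leveneTest(v ~ g, center = mean)
    expect_equal(res$levene_F, ref$`F value`[1])
    expect_equal(res$levene_p, ref$`Pr(>F)`[1])
    # the screen picks pooled exactly when the variances pass it
    expect_equal(res$equal_variance_assumed, ref$`Pr(>F)`[1] > 0.05)
    expect_equal(res$t_stat,
                 if (res$equal_variance_assumed) res$pooled$t else res$welch$t)
  }
})

test_that("instrument calibration recovers exact and planted lines", {
  x <- c(1, 2, 3, 4)
  fit <- calibrate_instruments(x, x)
  expect_equal(fit$gain, 1)
  expect_equal(fit$offset, 0)
  expect_equal(fit$r_squared, 1)

  fit2 <- calibrate_instruments(x, 2 * x + 3)
  expect_equal(fit2$gain, 2)
  expect_equal(fit2$offset, 3)
  expect_equal(fit2$r_squared, 1)
  expect_equal(correct_readings(fit2, 10), 23)

  expect_error(calibrate_instruments(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(calibrate_instruments(1:2, 1:2), "n >= 3")

  set.seed(37)
  xs <- runif(30, 100, 1000)
  ys <- 1.01 * xs - 8 + rnorm(30, 0, 5)
  fit3 <- calibrate_instruments(xs, ys)
  se <- summary(fit3$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit3$gain - 1.01), 3 * se["x"])
  expect_lt(abs(fit3$offset - (-8)), 3 * se["(Intercept)"])
  expect_gt(fit3$r_squared, 0.99)
})

test_that("OLS residuals are orthogonal to the fitted values", {
  set.seed(43)
  x <- runif(25, 0, 10); y <- 2 * x + rnorm(25)
  fit <- calibrate_instruments(x, y)
  r <- residuals(fit$fit)
  f <- fitted(fit$fit)
  expect_lt(abs(sum(r * f)) / sqrt(sum(r^2) * sum(f^2)), 1e-10)
})

test_that("the per-parameter report mirrors the component statistics", {
  set.seed(47)
  test_df <- data.frame(area = rnorm(10, 500, 50), len = rnorm(10, 800, 90))
  ref_df <- data.frame(area = test_df$area + rnorm(10, 0, 5),
                       len = test_df$len + rnorm(10, 0, 5))
  rep <- validate_instruments(test_df, ref_df)
  expect_equal(rep$parameter, c("area", "len"))
  expect_equal(rep$S_x[1], sample_sd(test_df$area))
  expect_equal(rep$delta[2], sum(test_df$len) - sum(ref_df$len))
  expect_true(all(rep$r_squared >= 0 & rep$r_squared <= 1))
  expect_error(validate_instruments(test_df[1, ], ref_df[1, ]), "3 paired")
  expect_error(validate_instruments(data.frame(a = 1:5),
                                    data.frame(b = 1:5)),
               "shared numeric")
})
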