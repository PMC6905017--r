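#' Sample standard deviation
#'
#' Sample standard deviation with the `n - 1` denominator,
#' `S = sqrt(sum((x - mean(x))^2) / (n - 1))`.
#'
#' @param x Numeric vector, `length(x) >= 2`.
#' @return `S`.
#' @examples
#' sample_sd(c(1, 2, 3))  # 1
#' @export
sample_sd <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("sample_sd: need at least two values", call. = FALSE)
  stats::sd(x)
}

#' Totals-based error analysis between two instruments
#'
#' Absolute error `delta = sum(x) - sum(y)` and relative error
#' `delta_rel = 100 * (sum(x) - sum(y)) / sum(y)` (in percent, signed),
#' where `x` are the test instrument's readings and `y` the reference
#' instrument's.
#'
#' @param x,y Equal-length numeric vectors (test, reference).
#' @return List with `delta` and `delta_rel_pct`.
#' @export
error_analysis <- function(x, y) {
  if (length(x) != length(y))
    stop("error_analysis: x and y must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("error_analysis: empty input", call. = FALSE)
  if (sum(y) == 0)
    stop("error_analysis: reference total is zero; relative error undefined",
         call. = FALSE)
  delta <- sum(x) - sum(y)
  list(delta = delta, delta_rel_pct = 100 * delta / sum(y))
}

# Classic Levene screen: one-way ANOVA on mean-centred absolute deviations.
levene_screen <- function(x, y) {
  ad <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (stats::var(ad) == 0) return(list(F = 0, p = 1))
  ft <- stats::oneway.test(ad ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Independent-samples t test with a variance-homogeneity screen
#'
#' The workflow used to compare a test instrument against a reference one:
#' a classic Levene screen (one-way ANOVA of the mean-centred absolute
#' deviations, at the 0.05 level) decides between the pooled-variance and
#' the Welch t test; both variants are reported, alongside the screen and a
#' verdict -- "no significant difference" when the selected two-tailed p
#' value exceeds `alpha`. Two identical zero-variance samples return
#' `t = 0`, `p = 1` by convention.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alpha Significance level for the verdict (default 0.01).
#' @return A list of class `"instrument_t_test"`: `levene_F`, `levene_p`,
#'   `equal_variance_assumed`, `pooled` and `welch` (each `t`, `df`, `p`),
#'   `t_stat`, `df`, `p_value` (the selected variant), `alpha`,
#'   `significant`.
#' @export
independent_t_test <- function(x, y, alpha = 0.01) {
  if (length(x) < 2L || length(y) < 2L)
    stop("independent_t_test: each sample needs n >= 2", call. = FALSE)
  lev <- levene_screen(x, y)
  equal_var <- lev$p > 0.05

  df_pooled <- length(x) + length(y) - 2
  run_t <- function(var.equal) {
    tryCatch({
      tt <- stats::t.test(x, y, var.equal = var.equal)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = unname(tt$p.value))
    }, error = function(e) {
      # constant data: t.test refuses; use the zero/infinite convention
      if (isTRUE(all.equal(mean(x), mean(y))))
        list(t = 0, df = df_pooled, p = 1)
      else
        list(t = sign(mean(x) - mean(y)) * Inf, df = df_pooled, p = 0)
    })
  }
  pooled <- run_t(TRUE)
  welch <- run_t(FALSE)
  sel <- if (equal_var) pooled else welch

  structure(list(levene_F = lev$F, levene_p = lev$p,
                 equal_variance_assumed = equal_var,
                 pooled = pooled, welch = welch,
                 t_stat = sel$t, df = sel$df, p_value = sel$p,
                 alpha = alpha, significant = sel$p <= alpha),
            class = "instrument_t_test")
}

#' @export
print.instrument_t_test <- function(x, ...) {
  cat("<instrument_t_test>\n")
  cat(sprintf("  Levene screen          : F = %.4g, p = %.4g (%s variances)\n",
              x$levene_F, x$levene_p,
              if (x$equal_variance_assumed) "equal" else "unequal"))
  cat(sprintf("  equal variances assumed: t = %.4g, df = %.4g, p = %.4g\n",
              x$pooled$t, x$pooled$df, x$pooled$p))
  cat(sprintf("  not assumed (Welch)    : t = %.4g, df = %.4g, p = %.4g\n",
              x$welch$t, x$welch$df, x$welch$p))
  cat(sprintf("  verdict at alpha = %g  : %s\n", x$alpha,
              if (x$significant) "significant difference"
              else "no significant difference"))
  invisible(x)
}

#' Linear cross-calibration of two instruments
#'
#' Ordinary least squares of the reference instrument's readings on the test
#' instrument's: `y = gain * x + offset`, with the coefficient of
#' determination R^2. Corrected test readings are `gain * x + offset`.
#'
#' @param x Test-instrument readings (n >= 3, non-constant).
#' @param y Reference-instrument readings.
#' @return A list of class `"instrument_fit"`: `gain`, `offset`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
calibrate_instruments <- function(x, y) {
  if (length(x) != length(y))
    stop("calibrate_instruments: x and y must have equal length",
         call. = FALSE)
  if (length(x) < 3L)
    stop("calibrate_instruments: need n >= 3", call. = FALSE)
  if (stats::var(x) == 0)
    stop("calibrate_instruments: test readings are constant; fit undefined",
         call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  # summary.lm warns on exact lines ("essentially perfect fit"); exact
  # agreement between instruments is a legitimate input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(gain = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
                 r_squared = r2, n = length(x), fit = fit),
            class = "instrument_fit")
}

#' @export
print.instrument_fit <- function(x, ...) {
  cat(sprintf(
    "<instrument_fit> gain = %.5g, offset = %.5g, R2 = %.5f (n = %d)\n",
    x$gain, x$offset, x$r_squared, x$n))
  invisible(x)
}

#' Apply a calibration fit to test readings
#'
#' @param fit An `"instrument_fit"`.
#' @param x Test readings to correct.
#' @return `gain * x + offset`.
#' @export
correct_readings <- function(fit, x) {
  stopifnot(inherits(fit, "instrument_fit"))
  fit$gain * x + fit$offset
}

#' Full per-parameter validation report
#'
#' For each shared numeric column of the two data frames (one row per
#' sample, one column per morphological parameter) computes the two sample
#' standard deviations, the totals-based absolute and relative errors, the
#' screened t test, and the linear calibration fit.
#'
#' @param test,reference Data frames with identical numeric columns and
#'   equal row counts; `test` holds this system's readings, `reference` the
#'   reference instrument's.
#' @param alpha Significance level for the t-test verdict.
#' @return Data frame with one row per parameter: `parameter`, `n`, `S_x`,
#'   `S_y`, `delta`, `delta_rel_pct`, `levene_F`, `levene_p`, `t_stat`,
#'   `df`, `p_value`, `equal_variance_assumed`, `significant`, `gain`,
#'   `offset`, `r_squared`.
#' @export
validate_instruments <- function(test, reference, alpha = 0.01) {
  cols <- intersect(names(test), names(reference))
  cols <- cols[vapply(test[cols], is.numeric, logical(1)) &
               vapply(reference[cols], is.numeric, logical(1))]
  if (length(cols) == 0L)
    stop("validate_instruments: no shared numeric columns", call. = FALSE)
  if (nrow(test) != nrow(reference))
    stop("validate_instruments: row counts differ", call. = FALSE)
  if (nrow(test) < 3L)
    stop("validate_instruments: need at least 3 paired samples",
         call. = FALSE)
  rows <- lapply(cols, function(cn) {
    x <- test[[cn]]; y <- reference[[cn]]
    err <- error_analysis(x, y)
    tt <- independent_t_test(x, y, alpha)
    cal <- calibrate_instruments(x, y)
    data.frame(parameter = cn, n = length(x),
               S_x = sample_sd(x), S_y = sample_sd(y),
               delta = err$delta, delta_rel_pct = err$delta_rel_pct,
               levene_F = tt$levene_F, levene_p = tt$levene_p,
               t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
               equal_variance_assumed = tt$equal_variance_assumed,
               significant = tt$significant,
               gain = cal$gain, offset = cal$offset,
               r_squared = cal$r_squared)
  })
  do.call(rbind, rows)
}
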