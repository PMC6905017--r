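#' Preprocessing configuration
#'
#' Collects the tunable options of [preprocess_root()]: an optional crop
#' rectangle (1-based inclusive rows/cols), the grayscale mode, the median
#' window, the structuring-element size for the morphological cleanup, the
#' threshold polarity and an optional threshold-method override.
#'
#' @param crop_rows,crop_cols `c(first, last)` or `NULL` for no crop.
#' @param gray_mode `"blue_channel"` (default) or `"weighted"`.
#' @param median_window Odd `c(height, width)` for [median_filter()].
#' @param se_size Odd side of the [se_box()] used by close/open cleanup.
#' @param polarity Passed to [apply_threshold()]; roots are dark on a white
#'   plate, so the default is `"dark_foreground"`.
#' @param threshold_method `"auto"` (valley with iterative fallback, the
#'   default), `"valley"`, `"iterative"`, or a fixed integer gray level.
#' @param t0 Optional initial threshold for [iterative_threshold()].
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(crop_rows = NULL, crop_cols = NULL,
                              gray_mode = c("blue_channel", "weighted"),
                              median_window = c(3L, 3L),
                              se_size = 3L,
                              polarity = c("dark_foreground",
                                           "bright_foreground"),
                              threshold_method = "auto",
                              t0 = NULL) {
  structure(list(crop_rows = crop_rows, crop_cols = crop_cols,
                 gray_mode = match.arg(gray_mode),
                 median_window = as.integer(rep(median_window,
                                                length.out = 2L)),
                 se_size = as.integer(se_size),
                 polarity = match.arg(polarity),
                 threshold_method = threshold_method,
                 t0 = t0),
            class = "preprocess_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Preprocess a plate photograph into a binary root mask
#'
#' Runs the full segmentation chain: optional crop to the plate, grayscale
#' conversion (blue channel by default), gray-level histogram, threshold
#' selection -- the valley method when the histogram is cleanly bimodal,
#' otherwise the iterative method -- thresholding, median filtering, then
#' morphological closing followed by opening (fill small cavities, then
#' remove fine debris). Deterministic for fixed input and configuration.
#'
#' @param img A [color_image()].
#' @param config A [preprocess_config()].
#' @return A list of class `"root_preprocess"`: `mask` ([binary_mask()]),
#'   `threshold` (`"threshold_result"`), `gray` (the [gray_image()] the
#'   threshold was derived from) and `config`.
#' @export
preprocess_root <- function(img, config = preprocess_config()) {
  stopifnot(inherits(img, "color_image"), inherits(config, "preprocess_config"))

  if (!is.null(config$crop_rows) || !is.null(config$crop_cols)) {
    d <- img_dim(img)
    rows <- if (is.null(config$crop_rows)) c(1L, d[1]) else config$crop_rows
    cols <- if (is.null(config$crop_cols)) c(1L, d[2]) else config$crop_cols
    img <- with_stage("crop", crop_image(img, rows, cols))
  }

  gray <- with_stage("gray", to_gray(img, config$gray_mode))
  hist <- with_stage("histogram", compute_histogram(gray))

  tm <- config$threshold_method
  thr <- with_stage("threshold", {
    if (is.numeric(tm)) {
      threshold_result(tm, "fixed", 0L)
    } else if (identical(tm, "valley")) {
      v <- valley_threshold(hist)
      if (is.null(v))
        stop("no admissible histogram valley (use method \"auto\" to allow ",
             "the iterative fallback)")
      v
    } else if (identical(tm, "iterative")) {
      iterative_threshold(hist, config$t0)
    } else {  # auto: valley with iterative fallback
      v <- valley_threshold(hist)
      if (is.null(v)) iterative_threshold(hist, config$t0) else v
    }
  })

  mask <- with_stage("binarize", apply_threshold(gray, thr, config$polarity))
  mask <- with_stage("median", median_filter(mask, config$median_window))
  se <- se_box(config$se_size)
  mask <- with_stage("morphology", binary_open(binary_close(mask, se), se))

  structure(list(mask = mask, threshold = thr, gray = gray, config = config),
            class = "root_preprocess")
}

#' @export
print.root_preprocess <- function(x, ...) {
  d <- img_dim(x$mask)
  cat(sprintf("<root_preprocess> %d x %d px mask, %d foreground px, t = %d (%s)\n",
              d[1], d[2], sum(unclass(x$mask)), x$threshold$threshold,
              x$threshold$method))
  invisible(x)
}
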