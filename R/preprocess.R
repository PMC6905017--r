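#' Convert a color image to grayscale
#'
#' Two conversions are offered. `"weighted"` is the standard luminance
#' combination `Gray = 0.299 R + 0.587 G + 0.114 B`, rounded half-up to an
#' integer gray level. `"blue_channel"` extracts the B plane unchanged: on a
#' white plate the blue channel separates dark roots from background better
#' than the R or G planes (roots are brownish, so their blue reflectance is
#' lowest), and it is the pipeline default.
#'
#' @param img A [color_image()].
#' @param mode `"blue_channel"` (default) or `"weighted"`.
#' @return A [gray_image()].
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' to_gray(color_image(px), "weighted")  # 76
#' @export
to_gray <- function(img, mode = c("blue_channel", "weighted")) {
  stopifnot(inherits(img, "color_image"))
  mode <- match.arg(mode)
  a <- unclass(img)
  m <- if (mode == "blue_channel") {
    a[, , 3L]
  } else {
    floor(a[, , 1L] * 0.299 + a[, , 2L] * 0.587 + a[, , 3L] * 0.114 + 0.5)
  }
  gray_image(matrix(as.integer(m), dim(a)[1], dim(a)[2]))
}

#' Gray-level histogram
#'
#' Counts pixels at each of the 256 gray levels. The counts always sum to the
#' pixel count of the source image.
#'
#' @param img A [gray_image()].
#' @return An object of class `"gray_histogram"`: a list with `counts`
#'   (length-256 integer vector, index `k + 1` holds the count of level `k`),
#'   `levels` (0:255) and `total`.
#' @export
compute_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- tabulate(as.integer(unclass(img)) + 1L, nbins = 256L)
  structure(list(counts = counts, levels = 0:255, total = sum(counts)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat(sprintf("<gray_histogram> %d pixels, levels %d..%d, %d occupied\n",
              x$total, min(nz), max(nz), length(nz)))
  invisible(x)
}

threshold_result <- function(threshold, method, iterations = 0L) {
  structure(list(threshold = as.integer(threshold), method = method,
                 iterations = as.integer(iterations)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t = %d (%s%s)\n", x$threshold, x$method,
              if (x$method == "iterative")
                sprintf(", %d iterations", x$iterations) else ""))
  invisible(x)
}

# Moving-average smoothing with truncated windows at the ends.
smooth_counts <- function(counts, width = 5L) {
  n <- length(counts)
  h <- width %/% 2L
  cs <- c(0, cumsum(counts))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Valley threshold for a bimodal histogram
#'
#' When a gray histogram shows two clear peaks (plate and root), the gray
#' level at the valley between them is a natural segmentation threshold. The
#' histogram is first smoothed with a width-5 moving average; the method then
#' requires exactly two modes, each side of the valley holding at least 5% of
#' the pixel mass, and a unique interior minimum between the modes. Any other
#' shape (unimodal, broad flat valley, multi-modal) returns `NULL` so that
#' the caller can fall back to [iterative_threshold()].
#'
#' @param h A `"gray_histogram"` from [compute_histogram()].
#' @param min_mode_mass Minimum fraction of total pixels on each side of the
#'   valley (default 0.05).
#' @param smooth_width Moving-average width used before mode search.
#' @return A `"threshold_result"` with `method = "valley"`, or `NULL` when no
#'   admissible valley exists.
#' @export
valley_threshold <- function(h, min_mode_mass = 0.05, smooth_width = 5L) {
  stopifnot(inherits(h, "gray_histogram"))
  if (h$total == 0L) stop("valley_threshold: empty histogram", call. = FALSE)
  s <- smooth_counts(h$counts, smooth_width)

  # run-length encode; a run is a mode when strictly above both flanking runs
  r <- rle(s)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(vals)
  left <- c(-Inf, vals[-k])
  right <- c(vals[-1], -Inf)
  is_mode <- vals > left & vals > right & vals > 0
  modes <- which(is_mode)
  if (length(modes) != 2L) return(NULL)

  # unique interior minimum strictly between the two mode runs
  lo <- ends[modes[1]] + 1L
  hi <- starts[modes[2]] - 1L
  if (lo > hi) return(NULL)
  seg <- s[lo:hi]
  mn <- min(seg)
  at <- which(seg == mn)
  if (length(at) != 1L) return(NULL)
  t <- lo + at - 1L  # 1-based index; gray level = t - 1

  mass_lo <- sum(h$counts[seq_len(t)])
  mass_hi <- h$total - mass_lo
  if (mass_lo < min_mode_mass * h$total || mass_hi < min_mode_mass * h$total)
    return(NULL)
  threshold_result(t - 1L, "valley", 0L)
}

round_half_up <- function(x) floor(x + 0.5)

#' Iterative (ISODATA-style) threshold
#'
#' Fixed-point iteration on the gray histogram: given a current threshold
#' `T`, the two class means (levels `<= T` and levels `> T`) are computed and
#' the new threshold is their midpoint, rounded half-up to an integer gray
#' level; iteration stops when the threshold no longer changes. The map is
#' bounded and monotone on integer thresholds, so it terminates; a 256-step
#' cap is enforced as a safety net. The default start is the midpoint of the
#' lowest and highest occupied gray levels.
#'
#' @param h A `"gray_histogram"`.
#' @param t0 Initial threshold (integer gray level); default midpoint of the
#'   occupied range.
#' @return A `"threshold_result"` with `method = "iterative"` and the number
#'   of update steps performed. A histogram with all mass at one level
#'   returns that level with 0 iterations.
#' @examples
#' img <- gray_image(matrix(c(0L, 255L), 16, 16))
#' iterative_threshold(compute_histogram(img))  # t = 128
#' @export
iterative_threshold <- function(h, t0 = NULL) {
  stopifnot(inherits(h, "gray_histogram"))
  if (h$total == 0L) stop("iterative_threshold: empty histogram",
                          call. = FALSE)
  nz <- which(h$counts > 0L) - 1L  # occupied gray levels
  lo <- min(nz); hi <- max(nz)
  if (lo == hi) return(threshold_result(lo, "iterative", 0L))

  if (is.null(t0)) t0 <- round_half_up((lo + hi) / 2)
  t <- min(max(as.integer(t0), lo), hi - 1L)  # keep both classes non-empty

  k <- 0:255
  iters <- 0L
  repeat {
    below <- k <= t
    mu1 <- sum(h$counts[below] * k[below]) / sum(h$counts[below])
    mu2 <- sum(h$counts[!below] * k[!below]) / sum(h$counts[!below])
    t_new <- as.integer(round_half_up((mu1 + mu2) / 2))
    t_new <- min(max(t_new, lo), hi - 1L)
    iters <- iters + 1L
    if (t_new == t || iters >= 256L) break
    t <- t_new
  }
  threshold_result(t_new, "iterative", iters)
}

#' Threshold a gray image into a binary mask
#'
#' With `polarity = "bright_foreground"` a pixel is foreground when its value
#' strictly exceeds the threshold. Roots, however, are darker than the white
#' plate, so the pipeline default is `"dark_foreground"`: foreground when the
#' value is strictly below the threshold (the mirror image of the bright
#' rule, preserving the strict inequality, so a uniform image never comes
#' out all-foreground).
#'
#' @param img A [gray_image()].
#' @param t Threshold, an integer gray level in 0-255, or a
#'   `"threshold_result"`.
#' @param polarity `"dark_foreground"` (default) or `"bright_foreground"`.
#' @return A [binary_mask()].
#' @export
apply_threshold <- function(img,
                            t,
                            polarity = c("dark_foreground",
                                         "bright_foreground")) {
  stopifnot(inherits(img, "gray_image"))
  polarity <- match.arg(polarity)
  if (inherits(t, "threshold_result")) t <- t$threshold
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t > 255L)
    stop("apply_threshold: threshold must be in [0, 255]", call. = FALSE)
  m <- unclass(img)
  binary_mask(if (polarity == "bright_foreground") m > t else m < t)
}

#' Median filter
#'
#' Each output pixel is the median of the window centred on it; this removes
#' isolated impulse (salt-and-pepper) noise while preserving edges. At the
#' image border the window is truncated to the in-image cells, and for
#' even-count windows the lower median is taken, so the output is always an
#' existing integer gray value and the filter is deterministic.
#'
#' @param img A [gray_image()] or [binary_mask()].
#' @param window Odd window dimensions `c(height, width)`; a single odd
#'   number is recycled.
#' @return Filtered image of the same class.
#' @export
median_filter <- function(img, window = c(3L, 3L)) {
  stopifnot(inherits(img, c("gray_image", "binary_mask")))
  window <- as.integer(rep(window, length.out = 2L))
  if (any(window < 1L) || any(window %% 2L == 0L))
    stop("median_filter: window dimensions must be odd and >= 1",
         call. = FALSE)
  d <- img_dim(img)
  if (window[1] > d[1] || window[2] > d[2])
    stop("median_filter: window larger than image", call. = FALSE)
  out <- cpp_median_filter(unclass(img), window[1], window[2])
  if (inherits(img, "gray_image")) gray_image(out) else binary_mask(out)
}
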