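#' Minimum pixel resolution for image acquisition
#'
#' Sizing rule for choosing a camera: to resolve features of size
#' `min_feature_mm` on an object of length `max_length_mm`, the sensor must
#' provide at least `2 * max_length_mm / min_feature_mm` pixels along the
#' object (two pixels per smallest feature). Non-integer results are rounded
#' up, since a pixel count cannot be fractional.
#'
#' @param max_length_mm Maximum length of the detected object, mm.
#' @param min_feature_mm Smallest feature (eigenvalue) to resolve, mm.
#' @return Required pixel count (integer).
#' @examples
#' pixel_resolution(300, 1)  # 600
#' @export
pixel_resolution <- function(max_length_mm, min_feature_mm) {
  if (!is.numeric(max_length_mm) || !is.numeric(min_feature_mm) ||
      max_length_mm <= 0 || min_feature_mm <= 0)
    stop("pixel_resolution: lengths must be positive", call. = FALSE)
  if (max_length_mm < min_feature_mm)
    stop("pixel_resolution: max_length_mm must be >= min_feature_mm",
         call. = FALSE)
  as.integer(ceiling(max_length_mm / min_feature_mm * 2))
}

#' Millimetre-per-pixel calibration from the background plate
#'
#' The plate's physical size is known; its pixel extent in the (cropped)
#' image gives the scale. The two axis ratios are averaged; if they disagree
#' by more than 2% (non-square pixels, perspective) a warning is raised.
#'
#' Standard plate sizes are available as `plate_presets`:
#' `plate_presets$a3` (297 x 420 mm) and `plate_presets$large`
#' (610 x 420 mm).
#'
#' @param plate_mm Plate physical size `c(width, height)` in mm.
#' @param plate_px Plate pixel extent `c(width, height)`.
#' @return A `"pixel_calibration"`: list with `mm_per_pixel`,
#'   `pixel_area_mm2` (its square) and `source`.
#' @examples
#' calibrate_plate(c(297, 420), c(2970, 4200))  # 0.1 mm/px
#' @export
calibrate_plate <- function(plate_mm, plate_px) {
  plate_mm <- as.numeric(plate_mm); plate_px <- as.numeric(plate_px)
  if (length(plate_mm) != 2L || length(plate_px) != 2L ||
      any(plate_mm <= 0) || any(plate_px <= 0))
    stop("calibrate_plate: plate dimensions must be positive", call. = FALSE)
  ratios <- plate_mm / plate_px
  if (abs(ratios[1] - ratios[2]) > 0.02 * mean(ratios))
    warning(sprintf(
      "calibrate_plate: axis scales differ by more than 2%% (%.4g vs %.4g mm/px)",
      ratios[1], ratios[2]))
  p <- mean(ratios)
  structure(list(mm_per_pixel = p, pixel_area_mm2 = p^2,
                 source = list(plate_mm = plate_mm, plate_px = plate_px)),
            class = "pixel_calibration")
}

#' @rdname calibrate_plate
#' @export
plate_presets <- list(a3 = c(297, 420), large = c(610, 420))

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %.5g mm/px (%.5g mm2/px)\n",
              x$mm_per_pixel, x$pixel_area_mm2))
  invisible(x)
}

#' Projected (silhouette) area of the root
#'
#' The segmented image is the root's vertical projection; its physical area
#' is the foreground pixel count times the per-pixel area.
#'
#' @param mask A [binary_mask()].
#' @param cal A `"pixel_calibration"`.
#' @return List with `area_mm2` and `n_pixels`.
#' @export
projected_area <- function(mask, cal) {
  stopifnot(inherits(mask, "binary_mask"), inherits(cal, "pixel_calibration"))
  n <- sum(unclass(mask))
  list(area_mm2 = cal$pixel_area_mm2 * n, n_pixels = as.integer(n))
}

#' Lateral (cylinder-model) surface area
#'
#' Under the cylindrical approximation -- the root as a stack of short
#' circular cylinders viewed side-on -- the lateral surface area of a
#' cylinder of diameter d and length l is pi*d*l while its projection is
#' d*l, so `S_lateral = pi * S_vertical` independently of how finely the
#' root is cut into segments. That identity is the default. A `"literal"`
#' mode multiplying by a user-supplied segment count `m` is retained for
#' reproducing formulations that keep the segment count as a factor.
#'
#' @param projected_mm2 Projected area, mm^2.
#' @param mode `"cylinder"` (default) or `"literal"`.
#' @param m Segment count used by the literal mode (default 1).
#' @return Lateral surface area, mm^2.
#' @export
lateral_surface_area <- function(projected_mm2, mode = c("cylinder",
                                                         "literal"),
                                 m = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(projected_mm2) || projected_mm2 < 0)
    stop("lateral_surface_area: projected area must be >= 0", call. = FALSE)
  if (mode == "cylinder") pi * projected_mm2 else pi * projected_mm2 * m
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton that
#' preserves the mask's topology and spans its medial axis; a cleanup pass
#' removes any residual 2 x 2 foreground blocks. The skeleton is always a
#' subset of the mask's foreground.
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  binary_mask(cpp_thin(unclass(mask)))
}

# 8-neighbour foreground count for every pixel (zero-padded borders).
neighbour_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  s <- matrix(0L, H, W)
  for (dr in -1:1)
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      s <- s + p[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
    }
  s
}

#' Maximal inscribed circles along the skeleton
#'
#' Estimates root cross-sections: at every skeleton pixel the Euclidean
#' distance to the nearest background pixel is the radius of the maximal
#' inscribed circle centred there. Candidates are then reduced by greedy
#' non-maximum suppression (largest radius first, ties broken by position):
#' a candidate whose centre lies strictly inside an already kept circle is
#' dropped. A filled disk therefore yields a single circle, while a tube
#' yields a chain of circles of its half-width spaced along the axis. Only
#' radii inside `r_range` are kept.
#'
#' @param mask A [binary_mask()].
#' @param r_range Admissible radius range in pixels, default `c(0, 100)`
#'   (exclusive lower bound).
#' @param skeleton Optional precomputed [skeletonize()] result.
#' @param distance_map Optional precomputed Euclidean distance map of the
#'   mask (foreground-to-nearest-background, pixels).
#' @return A `"circle_set"`: data frame with columns `row`, `col`,
#'   `radius_px`.
#' @export
detect_circles <- function(mask, r_range = c(0, 100), skeleton = NULL,
                           distance_map = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  empty <- data.frame(row = integer(), col = integer(),
                      radius_px = numeric())
  if (sum(unclass(mask)) == 0L)
    return(structure(empty, class = c("circle_set", "data.frame")))
  if (is.null(skeleton)) skeleton <- skeletonize(mask)

  dm <- if (is.null(distance_map))
    EBImage::distmap(unclass(mask), metric = "euclidean")
  else distance_map
  idx <- which(unclass(skeleton) == 1L, arr.ind = TRUE)
  r <- dm[idx]
  keep <- r > r_range[1] & r <= r_range[2]
  idx <- idx[keep, , drop = FALSE]
  r <- r[keep]
  if (length(r) == 0L)
    return(structure(empty, class = c("circle_set", "data.frame")))

  o <- order(-r, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  r <- r[o]
  kept <- integer(0)
  for (i in seq_along(r)) {
    inside <- FALSE
    for (j in kept) {
      if ((idx[i, 1] - idx[j, 1])^2 + (idx[i, 2] - idx[j, 2])^2 < r[j]^2) {
        inside <- TRUE
        break
      }
    }
    if (!inside) kept <- c(kept, i)
  }
  structure(data.frame(row = idx[kept, 1], col = idx[kept, 2],
                       radius_px = r[kept]),
            class = c("circle_set", "data.frame"))
}

#' Average root diameter from detected circles
#'
#' Twice the mean inscribed-circle radius, converted to millimetres. With no
#' circles the measurement is undefined and `NA` is returned (never 0), so
#' downstream quantities propagate missingness rather than silently
#' vanishing.
#'
#' @param circles A `"circle_set"` from [detect_circles()].
#' @param cal A `"pixel_calibration"`.
#' @return Average diameter in mm, or `NA_real_` when no circles were found.
#' @export
average_diameter <- function(circles, cal) {
  stopifnot(inherits(circles, "circle_set"),
            inherits(cal, "pixel_calibration"))
  if (nrow(circles) == 0L) return(NA_real_)
  2 * mean(circles$radius_px) * cal$mm_per_pixel
}

#' Chain-code length of a skeleton
#'
#' Walks the skeleton's 8-connected adjacency graph counting each edge once:
#' axial steps (horizontal/vertical neighbours) have length 1 pixel, diagonal
#' steps length sqrt(2). Diagonal adjacencies that share a foreground axial
#' neighbour are shortcut chords of the path, not steps, and are not counted;
#' junction pixels are therefore never double-counted. The physical length is
#' `mm_per_pixel * (N1 + N2 * sqrt(2))`. Isolated pixels contribute no steps.
#'
#' @param skel A skeleton [binary_mask()] from [skeletonize()].
#' @param cal A `"pixel_calibration"`.
#' @return List with `length_mm`, `n1` (axial steps), `n2` (diagonal steps).
#' @export
chain_code_length <- function(skel, cal) {
  stopifnot(inherits(skel, "binary_mask"),
            inherits(cal, "pixel_calibration"))
  n <- cpp_chain_counts(unclass(skel))
  list(length_mm = cal$mm_per_pixel * (n[["n1"]] + n[["n2"]] * sqrt(2)),
       n1 = n[["n1"]], n2 = n[["n2"]])
}

#' Root volume
#'
#' `"cylinder"` mode (the default) treats the root as a solid of revolution
#' of its average diameter: `V = pi * (D/2)^2 * L`, dimensionally consistent
#' in mm^3. `"literal"` mode computes `V = mean_radius * L` (units mm^2),
#' mirroring formulations that omit the cross-section factor; it is
#' retained for comparison only.
#'
#' @param avg_diameter_mm Average diameter, mm (may be `NA`).
#' @param length_mm Root length, mm.
#' @param mode `"cylinder"` or `"literal"`.
#' @return Volume (mm^3 in cylinder mode); `NA` when the diameter is
#'   missing and the length is positive.
#' @export
root_volume <- function(avg_diameter_mm, length_mm,
                        mode = c("cylinder", "literal")) {
  mode <- match.arg(mode)
  if (!is.numeric(length_mm) || (!is.na(length_mm) && length_mm < 0))
    stop("root_volume: length must be >= 0", call. = FALSE)
  if (isTRUE(length_mm == 0)) return(0)
  if (is.na(avg_diameter_mm)) return(NA_real_)
  if (mode == "cylinder") pi * (avg_diameter_mm / 2)^2 * length_mm
  else (avg_diameter_mm / 2) * length_mm
}

#' Measure all root morphological parameters from a mask
#'
#' Orchestrates the morphometry on a preprocessed binary mask: projected
#' area and the cylinder-model lateral surface area; skeletonization with
#' chain-code length plus a blunt-end compensation (thinning retracts every
#' open branch tip by about the local half-width, so the local inscribed
#' radius at each skeleton endpoint is added back); inscribed-circle average
#' diameter; and volume. An empty mask yields all-zero measurements flagged
#' `no_root`.
#'
#' @param mask A [binary_mask()] (or a `"root_preprocess"` result, whose
#'   mask and threshold are used).
#' @param cal A `"pixel_calibration"`.
#' @param volume_mode Passed to [root_volume()].
#' @param lateral_mode,m Passed to [lateral_surface_area()].
#' @param r_range Passed to [detect_circles()].
#' @return A `"root_measurements"` list: `projected_area_mm2`,
#'   `surface_area_mm2`, `avg_diameter_mm`, `length_mm`, `volume_mm3`,
#'   `n_foreground`, `n1`, `n2`, `circle_count`, `segment_count`,
#'   `threshold`, `threshold_method`, `no_root`.
#' @export
measure_root <- function(mask, cal, volume_mode = c("cylinder", "literal"),
                         lateral_mode = c("cylinder", "literal"), m = 1L,
                         r_range = c(0, 100)) {
  volume_mode <- match.arg(volume_mode)
  lateral_mode <- match.arg(lateral_mode)
  thr <- NA_integer_; thr_method <- NA_character_
  if (inherits(mask, "root_preprocess")) {
    thr <- mask$threshold$threshold
    thr_method <- mask$threshold$method
    mask <- mask$mask
  }
  stopifnot(inherits(mask, "binary_mask"), inherits(cal, "pixel_calibration"))

  proj <- projected_area(mask, cal)
  if (proj$n_pixels == 0L) {
    out <- list(projected_area_mm2 = 0, surface_area_mm2 = 0,
                avg_diameter_mm = 0, length_mm = 0, volume_mm3 = 0,
                n_foreground = 0L, n1 = 0L, n2 = 0L, circle_count = 0L,
                segment_count = as.integer(m), threshold = thr,
                threshold_method = thr_method, no_root = TRUE)
    return(structure(out, class = "root_measurements"))
  }

  surf <- lateral_surface_area(proj$area_mm2, lateral_mode, m)
  skel <- skeletonize(mask)
  len <- chain_code_length(skel, cal)
  dm <- EBImage::distmap(unclass(mask), metric = "euclidean")
  circles <- detect_circles(mask, r_range, skeleton = skel,
                            distance_map = dm)
  diam <- average_diameter(circles, cal)

  # Blunt-end compensation: thinning retracts every open branch tip by about
  # the local half-width, so the chain-code length underestimates the
  # centreline by that much per tip. The inscribed radius at each skeleton
  # endpoint (a pixel with exactly one 8-neighbour) estimates the retraction.
  sk <- unclass(skel)
  tips <- which(sk == 1L & neighbour_count(sk) == 1L)
  length_mm <- len$length_mm + sum(dm[tips]) * cal$mm_per_pixel

  vol <- root_volume(diam, length_mm, volume_mode)

  structure(list(projected_area_mm2 = proj$area_mm2,
                 surface_area_mm2 = surf,
                 avg_diameter_mm = diam,
                 length_mm = length_mm,
                 volume_mm3 = vol,
                 n_foreground = proj$n_pixels,
                 n1 = len$n1, n2 = len$n2,
                 circle_count = nrow(circles),
                 segment_count = as.integer(m),
                 threshold = thr, threshold_method = thr_method,
                 no_root = FALSE),
            class = "root_measurements")
}

#' @export
print.root_measurements <- function(x, ...) {
  cat("<root_measurements>\n")
  if (x$no_root) cat("  no root detected\n")
  cat(sprintf("  projected area : %10.3f mm2  (N_a = %d px)\n",
              x$projected_area_mm2, x$n_foreground))
  cat(sprintf("  surface area   : %10.3f mm2\n", x$surface_area_mm2))
  cat(sprintf("  avg diameter   : %10.3f mm   (%d circles)\n",
              x$avg_diameter_mm, x$circle_count))
  cat(sprintf("  length         : %10.3f mm   (N1 = %d, N2 = %d)\n",
              x$length_mm, x$n1, x$n2))
  cat(sprintf("  volume         : %10.3f mm3\n", x$volume_mm3))
  invisible(x)
}

#' @export
as.data.frame.root_measurements <- function(x, ...) {
  data.frame(projected_area_mm2 = x$projected_area_mm2,
             surface_area_mm2 = x$surface_area_mm2,
             avg_diameter_mm = x$avg_diameter_mm,
             length_mm = x$length_mm,
             volume_mm3 = x$volume_mm3,
             N_a = x$n_foreground, N1 = x$n1, N2 = x$n2,
             circle_count = x$circle_count,
             threshold = x$threshold,
             method = x$threshold_method)
}
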