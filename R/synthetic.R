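#' Specify a synthetic root image
#'
#' Describes a root-like scene with exactly known geometry: constant-width
#' straight segments (and optionally filled disks, useful as diameter
#' targets) drawn dark on a light plate of known physical size. Rendering is
#' deterministic given `seed`; analytic ground truth accompanies every
#' rendered image, so the whole measurement chain can be validated without
#' any real photograph.
#'
#' Coordinates are in millimetres with the origin at the plate's top-left
#' corner, `x` across the plate width (image columns) and `y` down the plate
#' height (image rows).
#'
#' @param segments Data frame with columns `x0`, `y0`, `x1`, `y1`, `width`
#'   (all mm); may have zero rows for a blank plate.
#' @param plate_mm Plate `c(width, height)` in mm.
#' @param mm_per_pixel Pixel pitch, mm.
#' @param root_color,plate_color RGB triples in 0-255. The defaults give a
#'   dark brownish root on a near-white plate, with the strongest contrast
#'   in the blue channel.
#' @param noise_fraction Salt-and-pepper fraction in `[0, 1]`: each pixel is
#'   independently replaced by pure black or pure white with this
#'   probability.
#' @param seed RNG seed used (only) for the noise.
#' @param disks Optional data frame with columns `cx`, `cy`, `radius` (mm).
#' @return A list of class `"root_spec"`.
#' @export
root_spec <- function(segments = data.frame(x0 = numeric(), y0 = numeric(),
                                            x1 = numeric(), y1 = numeric(),
                                            width = numeric()),
                      plate_mm = c(100, 60), mm_per_pixel = 0.1,
                      root_color = c(60, 40, 30),
                      plate_color = c(250, 250, 250),
                      noise_fraction = 0, seed = 1L, disks = NULL) {
  segments <- as.data.frame(segments)
  need <- c("x0", "y0", "x1", "y1", "width")
  if (!all(need %in% names(segments)))
    stop("root_spec: segments need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(segments) > 0) {
    if (any(segments$width <= 0))
      stop("root_spec: segment widths must be > 0", call. = FALSE)
    hw <- segments$width / 2
    if (any(pmin(segments$x0, segments$x1) - hw < 0) ||
        any(pmax(segments$x0, segments$x1) + hw > plate_mm[1]) ||
        any(pmin(segments$y0, segments$y1) - hw < 0) ||
        any(pmax(segments$y0, segments$y1) + hw > plate_mm[2]))
      stop("root_spec: segment (including its width) outside plate",
           call. = FALSE)
    if (any(segments$x0 == segments$x1 & segments$y0 == segments$y1))
      stop("root_spec: zero-length segment; use `disks` for round targets",
           call. = FALSE)
  }
  if (!is.null(disks)) {
    disks <- as.data.frame(disks)
    if (!all(c("cx", "cy", "radius") %in% names(disks)))
      stop("root_spec: disks need columns cx, cy, radius", call. = FALSE)
    if (any(disks$radius <= 0) ||
        any(disks$cx - disks$radius < 0) ||
        any(disks$cx + disks$radius > plate_mm[1]) ||
        any(disks$cy - disks$radius < 0) ||
        any(disks$cy + disks$radius > plate_mm[2]))
      stop("root_spec: disk outside plate", call. = FALSE)
  }
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("root_spec: noise_fraction must be in [0, 1]", call. = FALSE)
  stopifnot(mm_per_pixel > 0, length(plate_mm) == 2L, all(plate_mm > 0))
  structure(list(segments = segments, disks = disks,
                 plate_mm = as.numeric(plate_mm),
                 mm_per_pixel = as.numeric(mm_per_pixel),
                 root_color = as.integer(root_color),
                 plate_color = as.integer(plate_color),
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "root_spec")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Band membership at arbitrary sample points (mm): strictly within width/2 of
# the segment's centreline, axial projection within [0, L] (rectangular caps).
point_in_segments <- function(px, py, segments) {
  hit <- rep(FALSE, length(px))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    len <- sqrt(dx^2 + dy^2)
    ux <- dx / len; uy <- dy / len
    rx <- px - s$x0; ry <- py - s$y0
    t <- rx * ux + ry * uy
    d <- abs(rx * uy - ry * ux)
    hit <- hit | (t >= 0 & t <= len & d < s$width / 2)
  }
  hit
}

#' Render a synthetic root image with its ground truth
#'
#' Rasterizes the scene at the spec's pixel pitch: a pixel is root if and
#' only if its centre lies strictly within `width/2` of a segment centreline
#' (with flat end caps) or strictly inside a disk -- no anti-aliasing, so
#' pixel counts are reproducible bit-exactly. Salt-and-pepper noise, if
#' requested, is applied afterwards under the spec's seed.
#'
#' Ground truth is computed from the geometry, never from the raster: total
#' centreline length, length-weighted mean width, projected area (analytic
#' for a single band; fine-grid numeric union integration at a quarter-pixel
#' step when bands may overlap, so junctions are never double-counted),
#' lateral area (`pi *` projected area) and cylinder-model volume.
#'
#' @param spec A [root_spec()].
#' @return A list of class `"synthetic_root"`: `image` (a [color_image()]),
#'   `truth` (list: `total_length_mm`, `mean_width_mm`,
#'   `projected_area_mm2`, `lateral_area_mm2`, `volume_mm3`, `n_root_pixels`,
#'   `root_pixel_set` (two-column row/col matrix), `circles_px`,
#'   `mm_per_pixel`) and `spec`.
#' @export
render_root <- function(spec) {
  stopifnot(inherits(spec, "root_spec"))
  p <- spec$mm_per_pixel
  W <- as.integer(round(spec$plate_mm[1] / p))
  H <- as.integer(round(spec$plate_mm[2] / p))
  cx <- (seq_len(W) - 0.5) * p
  cy <- (seq_len(H) - 0.5) * p

  mask <- matrix(FALSE, H, W)
  segs <- spec$segments
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    hw <- s$width / 2
    rows <- which(cy > min(s$y0, s$y1) - hw - p & cy < max(s$y0, s$y1) + hw + p)
    cols <- which(cx > min(s$x0, s$x1) - hw - p & cx < max(s$x0, s$x1) + hw + p)
    if (!length(rows) || !length(cols)) next
    X <- matrix(cx[cols], length(rows), length(cols), byrow = TRUE)
    Y <- matrix(cy[rows], length(rows), length(cols))
    mask[rows, cols] <- mask[rows, cols] |
      matrix(point_in_segments(as.vector(X), as.vector(Y), s),
             length(rows), length(cols))
  }
  circles_px <- NULL
  if (!is.null(spec$disks)) {
    for (i in seq_len(nrow(spec$disks))) {
      d <- spec$disks[i, ]
      rows <- which(abs(cy - d$cy) < d$radius)
      cols <- which(abs(cx - d$cx) < d$radius)
      X <- matrix(cx[cols], length(rows), length(cols), byrow = TRUE)
      Y <- matrix(cy[rows], length(rows), length(cols))
      mask[rows, cols] <- mask[rows, cols] |
        ((X - d$cx)^2 + (Y - d$cy)^2 < d$radius^2)
    }
    circles_px <- data.frame(row = spec$disks$cy / p + 0.5,
                             col = spec$disks$cx / p + 0.5,
                             radius_px = spec$disks$radius / p)
  }

  img <- array(0L, c(H, W, 3L))
  for (ch in 1:3)
    img[, , ch] <- ifelse(mask, spec$root_color[ch], spec$plate_color[ch])

  if (spec$noise_fraction > 0) {
    img <- with_seed(spec$seed, {
      flip <- runif(H * W) < spec$noise_fraction
      value <- ifelse(runif(H * W) < 0.5, 0L, 255L)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[flip] <- value[flip]
        img[, , ch] <- plane
      }
      img
    })
  }

  truth <- compute_ground_truth(spec)
  truth$n_root_pixels <- sum(mask)
  truth$root_pixel_set <- which(mask, arr.ind = TRUE)
  truth$circles_px <- circles_px
  truth$mm_per_pixel <- p

  structure(list(image = color_image(img), truth = truth, spec = spec),
            class = "synthetic_root")
}

# Analytic (geometry-based) ground truth; numeric union integration only when
# several bands could overlap.
compute_ground_truth <- function(spec) {
  segs <- spec$segments
  lens <- if (nrow(segs)) sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
          else numeric(0)
  total_length <- sum(lens)
  mean_width <- if (total_length > 0) sum(segs$width * lens) / total_length
                else 0
  disk_area <- if (is.null(spec$disks)) 0 else sum(pi * spec$disks$radius^2)

  if (nrow(segs) <= 1L) {
    band_area <- sum(lens * segs$width)
  } else {
    # fine-grid union integration at a quarter-pixel step; sample points sit
    # at cell midpoints so grid-aligned band edges are integrated exactly
    delta <- spec$mm_per_pixel / 4
    hw <- max(segs$width) / 2
    lo_x <- max(0, min(segs$x0, segs$x1) - hw - delta)
    hi_x <- min(spec$plate_mm[1], max(segs$x0, segs$x1) + hw + delta)
    lo_y <- max(0, min(segs$y0, segs$y1) - hw - delta)
    hi_y <- min(spec$plate_mm[2], max(segs$y0, segs$y1) + hw + delta)
    gx <- seq(floor(lo_x / delta), ceiling(hi_x / delta)) * delta + delta / 2
    gy <- seq(floor(lo_y / delta), ceiling(hi_y / delta)) * delta + delta / 2
    X <- rep(gx, times = length(gy))
    Y <- rep(gy, each = length(gx))
    band_area <- sum(point_in_segments(X, Y, segs)) * delta^2
  }
  projected <- band_area + disk_area

  list(total_length_mm = total_length,
       mean_width_mm = mean_width,
       projected_area_mm2 = projected,
       lateral_area_mm2 = pi * projected,
       volume_mm3 = if (nrow(segs)) sum(pi * (segs$width / 2)^2 * lens) else 0)
}

#' @export
print.synthetic_root <- function(x, ...) {
  d <- img_dim(x$image)
  cat(sprintf(
    "<synthetic_root> %d x %d px, %d root px, L = %.2f mm, A = %.2f mm2\n",
    d[1], d[2], x$truth$n_root_pixels, x$truth$total_length_mm,
    x$truth$projected_area_mm2))
  invisible(x)
}

#' Canonical synthetic fixture suite
#'
#' Renders the fixtures used throughout the package's validation: an axial
#' tube, two 45-degree tubes (south-east and north-east going), a Y-branched
#' root, a two-disk diameter target, a blank plate, and the axial tube with
#' 0.5% and 1% salt-and-pepper noise. All live on a 100 x 60 mm plate.
#'
#' Geometry is designed around the raster: centreline coordinates are whole
#' millimetres, so at the default 0.1 mm/px pitch axial band edges fall on
#' pixel boundaries and axial pixel counts equal their analytic values
#' exactly. Axial widths are an even number of pixels (the thinned skeleton
#' then sits half a pixel off the centreline, which exactly cancels the
#' half-pixel offset of the background pixel centres in the inscribed-radius
#' estimate). The 45-degree widths place the band half-width three quarters
#' of the way between pixel diagonals (`h * sqrt(2) = K + 0.75` px), which
#' balances the residual lattice quantization evenly between the silhouette
#' area (about -1.2%) and the inscribed radius (about +1.2%) -- the best a
#' square lattice admits for oblique bands.
#'
#' @param mm_per_pixel Pixel pitch, mm (default 0.1).
#' @return Named list of [render_root()] results.
#' @export
fixture_suite <- function(mm_per_pixel = 0.1) {
  seg <- function(x0, y0, x1, y1, width)
    data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, width = width)
  plate <- c(100, 60)
  axial <- seg(10, 30, 90, 30, 1)
  w45 <- 41.5 / (10 * sqrt(2))   # 2.934 mm: 45-deg sweet spot, K = 20
  wbr <- 27.5 / (10 * sqrt(2))   # 1.945 mm: 45-deg sweet spot, K = 13
  specs <- list(
    axial_tube = root_spec(axial, plate, mm_per_pixel),
    diagonal_tube = root_spec(seg(30, 10, 70, 50, w45), plate, mm_per_pixel),
    rotated45_tube = root_spec(seg(15, 48, 55, 8, w45), plate, mm_per_pixel),
    y_branch = root_spec(rbind(seg(50, 8, 50, 28, 2),
                               seg(50, 28, 32, 46, wbr),
                               seg(50, 28, 68, 46, wbr)),
                         plate, mm_per_pixel),
    two_disks = root_spec(plate_mm = plate, mm_per_pixel = mm_per_pixel,
                          disks = data.frame(cx = c(30, 70), cy = c(30, 30),
                                             radius = c(1, 3))),
    blank_plate = root_spec(plate_mm = plate, mm_per_pixel = mm_per_pixel),
    axial_noise_half_pct = root_spec(axial, plate, mm_per_pixel,
                                     noise_fraction = 0.005, seed = 101L),
    axial_noise_one_pct = root_spec(axial, plate, mm_per_pixel,
                                    noise_fraction = 0.01, seed = 202L))
  lapply(specs, render_root)
}

#' Write rendered fixtures to disk
#'
#' Writes each fixture as a PNG plus a JSON manifest holding the scalar
#' ground-truth fields, the plate geometry and the pixel pitch (the pixel
#' set is omitted from the manifest; it is reproducible from the spec).
#'
#' @param suite Named list of `"synthetic_root"` objects, e.g. from
#'   [fixture_suite()].
#' @param dir Output directory (created if missing).
#' @return Data frame listing the written files, invisibly.
#' @export
write_fixtures <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(suite), function(nm) {
    fx <- suite[[nm]]
    img_path <- file.path(dir, paste0(nm, ".png"))
    man_path <- file.path(dir, paste0(nm, ".json"))
    a <- unclass(fx$image) / 255
    png::writePNG(a, img_path)
    man <- fx$truth[c("total_length_mm", "mean_width_mm",
                      "projected_area_mm2", "lateral_area_mm2",
                      "volume_mm3", "n_root_pixels", "mm_per_pixel")]
    man$plate_mm <- fx$spec$plate_mm
    man$plate_px <- rev(img_dim(fx$image))
    man$noise_fraction <- fx$spec$noise_fraction
    jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA)
    data.frame(name = nm, image = img_path, manifest = man_path)
  })
  invisible(do.call(rbind, rows))
}
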