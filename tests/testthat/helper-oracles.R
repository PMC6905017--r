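# Brute-force oracles, written independently of the package internals.

# Windowed median by explicit sort; truncated windows, lower median.
oracle_median <- function(m, wh = 3L, ww = 3L) {
  H <- nrow(m); W <- ncol(m)
  hr <- wh %/% 2L; hc <- ww %/% 2L
  out <- m
  for (r in seq_len(H))
    for (c in seq_len(W)) {
      v <- sort(as.vector(m[max(1L, r - hr):min(H, r + hr),
                            max(1L, c - hc):min(W, c + hc)]))
      out[r, c] <- v[(length(v) + 1L) %/% 2L]
    }
  out
}

se_offsets <- function(se) {
  off <- which(unclass(se) == 1L, arr.ind = TRUE)
  off[, 1] <- off[, 1] - (nrow(se) + 1L) %/% 2L
  off[, 2] <- off[, 2] - (ncol(se) + 1L) %/% 2L
  off
}

# Dilation as an explicit Minkowski sum: translate every foreground point by
# every element offset and take the union.
oracle_dilate <- function(a, se) {
  a <- unclass(a)
  H <- nrow(a); W <- ncol(a)
  out <- matrix(0L, H, W)
  off <- se_offsets(se)
  fg <- which(a == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(fg)))
    for (j in seq_len(nrow(off))) {
      r <- fg[i, 1] + off[j, 1]; c <- fg[i, 2] + off[j, 2]
      if (r >= 1L && r <= H && c >= 1L && c <= W) out[r, c] <- 1L
    }
  out
}

# Erosion by direct set containment: keep z iff every translated element
# cell lands on foreground (off-image counts as background).
oracle_erode <- function(a, se) {
  a <- unclass(a)
  H <- nrow(a); W <- ncol(a)
  out <- matrix(0L, H, W)
  off <- se_offsets(se)
  for (r in seq_len(H))
    for (c in seq_len(W)) {
      ok <- TRUE
      for (j in seq_len(nrow(off))) {
        rr <- r + off[j, 1]; cc <- c + off[j, 2]
        if (rr < 1L || rr > H || cc < 1L || cc > W || a[rr, cc] == 0L) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[r, c] <- 1L
    }
  out
}

# ISODATA fixed point computed on the raw pixel values (not the histogram),
# same class split (<= t vs > t) and half-up rounding.
oracle_isodata <- function(values, t0 = NULL) {
  if (is.null(t0))
    t0 <- floor((min(values) + max(values)) / 2 + 0.5)
  t <- as.integer(t0)
  for (i in 1:256) {
    lo <- values[values <= t]; hi <- values[values > t]
    stopifnot(length(lo) > 0L, length(hi) > 0L)
    tn <- as.integer(floor((mean(lo) + mean(hi)) / 2 + 0.5))
    if (tn == t) return(t)
    t <- tn
  }
  stop("oracle_isodata failed to converge")
}

random_gray <- function(H = 32L, W = 32L, lo = 0L, hi = 255L) {
  gray_image(matrix(sample(lo:hi, H * W, replace = TRUE), H, W))
}

# Random mask with a guaranteed background frame (so finite-grid morphology
# identities are exact for 3 x 3 elements).
random_mask <- function(H = 32L, W = 32L, p = 0.4, border = 1L) {
  m <- matrix(rbinom(H * W, 1L, p), H, W)
  if (border > 0L) {
    b <- seq_len(border)
    m[b, ] <- 0L; m[H + 1L - b, ] <- 0L
    m[, b] <- 0L; m[, W + 1L - b] <- 0L
  }
  binary_mask(m)
}

# Independent union-area integration for a root_spec: fine sub-grid (step
# p/5, deliberately different from the generator's p/4) over the scene
# bounding box, counting points inside any band or disk.
oracle_union_area <- function(spec) {
  segs <- spec$segments
  disks <- spec$disks
  if (nrow(segs) == 0L && is.null(disks)) return(0)
  delta <- spec$mm_per_pixel / 5
  xs <- c(segs$x0, segs$x1, if (!is.null(disks)) c(disks$cx - disks$radius,
                                                   disks$cx + disks$radius))
  ys <- c(segs$y0, segs$y1, if (!is.null(disks)) c(disks$cy - disks$radius,
                                                   disks$cy + disks$radius))
  pad <- max(c(segs$width / 2, 0)) + delta
  # midpoint sampling: cell centres, so grid-aligned edges are unbiased
  gx <- seq(floor((min(xs) - pad) / delta),
            ceiling((max(xs) + pad) / delta)) * delta + delta / 2
  gy <- seq(floor((min(ys) - pad) / delta),
            ceiling((max(ys) + pad) / delta)) * delta + delta / 2
  X <- rep(gx, times = length(gy))
  Y <- rep(gy, each = length(gx))
  inside <- rep(FALSE, length(X))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
    ux <- (s$x1 - s$x0) / len; uy <- (s$y1 - s$y0) / len
    t <- (X - s$x0) * ux + (Y - s$y0) * uy
    d <- abs((X - s$x0) * uy - (Y - s$y0) * ux)
    inside <- inside | (t >= 0 & t <= len & d < s$width / 2)
  }
  if (!is.null(disks))
    for (i in seq_len(nrow(disks)))
      inside <- inside | ((X - disks$cx[i])^2 + (Y - disks$cy[i])^2 <
                            disks$radius[i]^2)
  sum(inside) * delta^2
}

make_histogram <- function(counts) {
  structure(list(counts = as.integer(counts), levels = 0:255,
                 total = sum(counts)),
            class = "gray_histogram")
}

as_circle_set <- function(radius_px) {
  structure(data.frame(row = rep(0L, length(radius_px)),
                       col = rep(0L, length(radius_px)),
                       radius_px = radius_px),
            class = c("circle_set", "data.frame"))
}

# Shared calibration (0.1 mm/px from a 100 x 60 mm plate) and one lazily
# rendered fixture suite reused across test files.
test_cal <- function() calibrate_plate(c(100, 60), c(1000, 600))

suite_cache <- new.env()
get_suite <- function() {
  if (is.null(suite_cache$suite)) suite_cache$suite <- fixture_suite()
  suite_cache$suite
}
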