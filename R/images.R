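#' Image containers
#'
#' Lightweight containers for the three raster stages of the pipeline:
#' `color_image` (H x W x 3 integer array, 8-bit RGB), `gray_image`
#' (H x W integer matrix, values 0-255) and `binary_mask` (H x W matrix of
#' 0/1, 1 = root foreground). Pixels are addressed `(row, col)`, 1-based,
#' origin at the top-left corner.
#'
#' @param pixels For `color_image` an H x W x 3 numeric array with values in
#'   0-255; for `gray_image` an H x W matrix with values in 0-255; for
#'   `binary_mask` an H x W matrix containing only 0 and 1 (logical matrices
#'   are accepted).
#' @return An object of class `"color_image"`, `"gray_image"` or
#'   `"binary_mask"`; the underlying data are stored as integer.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' mask <- binary_mask(matrix(c(0, 1), 4, 4))
#' @name image-containers
NULL

#' @rdname image-containers
#' @export
color_image <- function(pixels) {
  a <- pixels
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop("color_image: `pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(a)[1] < 1L || dim(a)[2] < 1L)
    stop("color_image: empty image", call. = FALSE)
  storage.mode(a) <- "integer"
  if (anyNA(a) || min(a) < 0L || max(a) > 255L)
    stop("color_image: channel values must be integers in [0, 255]",
         call. = FALSE)
  structure(a, class = "color_image")
}

#' @rdname image-containers
#' @export
gray_image <- function(pixels) {
  m <- pixels
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("gray_image: `pixels` must be a non-empty matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  if (anyNA(m) || min(m) < 0L || max(m) > 255L)
    stop("gray_image: values must be integers in [0, 255]", call. = FALSE)
  structure(m, class = "gray_image")
}

#' @rdname image-containers
#' @export
binary_mask <- function(pixels) {
  m <- pixels
  if (is.logical(m)) m[] <- as.integer(m)
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("binary_mask: `pixels` must be a non-empty matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop("binary_mask: only values 0 and 1 are allowed", call. = FALSE)
  structure(m, class = "binary_mask")
}

img_dim <- function(x) dim(unclass(x))[1:2]

#' @export
print.color_image <- function(x, ...) {
  d <- dim(unclass(x))
  cat(sprintf("<color_image> %d x %d px, 8-bit RGB\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(unclass(x))
  cat(sprintf("<gray_image> %d x %d px, range [%d, %d]\n",
              d[1], d[2], min(unclass(x)), max(unclass(x))))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(unclass(x))
  n <- sum(unclass(x))
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.2f%%)\n",
              d[1], d[2], n, 100 * n / prod(d)))
  invisible(x)
}

#' Read a plate photograph
#'
#' Reads a PNG, TIFF or JPEG file into a [color_image()]. Values are scaled
#' to 8 bits per channel; grayscale files are replicated across the three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return A [color_image()].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) stop("read_plate_image: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("read_plate_image: unsupported format `.", ext, "`", call. = FALSE))
  if (max(a) > 1) {  # as.is readers; deeper than 8 bits
    warning("read_plate_image: >8-bit input rescaled to 8 bits")
    a <- a / max(a)
  }
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(a, c(dim(a)[1:2], 3L))
  color_image(array(as.integer(floor(a * 255 + 0.5)), dim(a)))
}

#' Write a binary mask as a PNG file
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask A [binary_mask()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(matrix(as.double(unclass(mask)), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' Crop an image to a pixel rectangle
#'
#' Used to crop the photograph down to the background plate so that the
#' plate's pixel extent can calibrate the millimetre scale. Rows and columns
#' are 1-based and inclusive; the rectangle must lie fully inside the image.
#'
#' @param img A [color_image()] or [gray_image()].
#' @param rows,cols Integer vectors `c(first, last)`.
#' @return An image of the same class with the rectangle's dimensions.
#' @examples
#' img <- gray_image(matrix(1:100, 10, 10))
#' crop_image(img, rows = c(3, 6), cols = c(4, 8))
#' @export
crop_image <- function(img, rows, cols) {
  stopifnot(inherits(img, c("color_image", "gray_image")))
  d <- img_dim(img)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L ||
      rows[1] < 1L || cols[1] < 1L || rows[2] > d[1] || cols[2] > d[2] ||
      rows[1] > rows[2] || cols[1] > cols[2])
    stop("crop_image: rectangle outside image bounds", call. = FALSE)
  a <- unclass(img)
  if (inherits(img, "color_image"))
    color_image(a[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE])
  else
    gray_image(a[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
}
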