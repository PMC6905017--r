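#' Structuring elements
#'
#' `se_box(n)` builds the all-ones square element of odd side `n` used by the
#' binary cleanup stage; `structuring_element()` validates an arbitrary 0/1
#' mask with odd sides and a foreground origin (centre cell). `se_reflect()`
#' returns the point reflection through the origin, which appears in the
#' erosion/dilation duality.
#'
#' @param n Odd side length.
#' @param mask Matrix of 0/1 with odd side lengths and `1` at the centre.
#' @param se A structuring element.
#' @return A `"structuring_element"`: an integer 0/1 matrix.
#' @export
se_box <- function(n = 3L) {
  n <- as.integer(n)
  structuring_element(matrix(1L, n, n))
}

#' @rdname se_box
#' @export
structuring_element <- function(mask) {
  if (is.logical(mask)) mask[] <- as.integer(mask)
  if (!is.matrix(mask) || any(dim(mask) %% 2L == 0L))
    stop("structuring_element: side lengths must be odd", call. = FALSE)
  storage.mode(mask) <- "integer"
  if (!all(mask == 0L | mask == 1L))
    stop("structuring_element: only values 0 and 1 are allowed",
         call. = FALSE)
  if (mask[(nrow(mask) + 1L) %/% 2L, (ncol(mask) + 1L) %/% 2L] != 1L)
    stop("structuring_element: origin (centre cell) must be 1", call. = FALSE)
  structure(mask, class = "structuring_element")
}

#' @rdname se_box
#' @export
se_reflect <- function(se) {
  m <- unclass(se)
  structuring_element(m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))),
                        drop = FALSE])
}

#' Binary morphology
#'
#' Set-theoretic dilation, erosion, opening and closing of a binary mask by a
#' structuring element. Dilation unions the element stamped over every
#' foreground pixel (fills small cavities and joins close fragments);
#' erosion keeps a pixel only when the whole element, translated there, fits
#' inside the foreground (removes debris smaller than the element) -- cells
#' beyond the image border count as background, per the literal set
#' definition on the finite image support. Opening is erosion then dilation
#' (removes specks, anti-extensive, idempotent); closing is dilation then
#' erosion (fills cavities, extensive, idempotent). Erosion and dilation are
#' dual: the complement of an erosion equals the dilation of the complement
#' by the reflected element.
#'
#' @param a A [binary_mask()].
#' @param b A structuring element, see [se_box()].
#' @return A [binary_mask()].
#' @examples
#' m <- binary_mask(matrix(0L, 7, 7))
#' m[4, 4] <- 1L
#' sum(binary_dilate(m, se_box(3)))  # 9
#' sum(binary_open(m, se_box(3)))    # 0: isolated pixel removed
#' @name binary-morphology
NULL

check_morph_args <- function(a, b) {
  if (!inherits(a, "binary_mask"))
    stop("expected a binary_mask", call. = FALSE)
  if (!inherits(b, "structuring_element"))
    stop("expected a structuring_element", call. = FALSE)
}

#' @rdname binary-morphology
#' @export
binary_dilate <- function(a, b = se_box(3L)) {
  check_morph_args(a, b)
  binary_mask(cpp_dilate(unclass(a), unclass(b)))
}

#' @rdname binary-morphology
#' @export
binary_erode <- function(a, b = se_box(3L)) {
  check_morph_args(a, b)
  binary_mask(cpp_erode(unclass(a), unclass(b)))
}

#' @rdname binary-morphology
#' @export
binary_open <- function(a, b = se_box(3L)) {
  binary_dilate(binary_erode(a, b), b)
}

#' @rdname binary-morphology
#' @export
binary_close <- function(a, b = se_box(3L)) {
  binary_erode(binary_dilate(a, b), b)
}
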