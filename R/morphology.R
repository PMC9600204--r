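check_binary <- function(b) {
  if (!is.matrix(b) || !all(b %in% c(0L, 1L))) {
    ts_error("expected a binary (0/1) matrix", "thalscreen_format_error")
  }
  invisible(b)
}

check_se <- function(size) {
  if (!is_count(size) || size %% 2 != 1) {
    ts_error("structuring element size must be a positive odd integer",
             "thalscreen_parameter_error")
  }
  as.integer(size)
}

#' Binary erosion with a square structuring element
#'
#' A pixel survives iff the `size` x `size` square centred on it fits
#' entirely inside the foreground; pixels outside the image count as
#' background, so erosion peels a frame off a full-foreground image.
#'
#' @param b Binary (0/1) integer matrix.
#' @param size Odd side length of the square element.
#' @return Eroded binary matrix.
#' @export
erode <- function(b, size = 5) {
  check_binary(b)
  .cpp_binary_erode(b, check_se(size))
}

#' Binary dilation with a square structuring element
#'
#' A pixel is set iff the `size` x `size` square centred on it intersects
#' the foreground.
#'
#' @inheritParams erode
#' @return Dilated binary matrix.
#' @export
dilate <- function(b, size = 5) {
  check_binary(b)
  .cpp_binary_dilate(b, check_se(size))
}

#' Split touching lanes by two-scale erosion and compensating dilation
#'
#' Bands of adjacent patients occasionally run together on a strip; a thin
#' bridge then joins two lane blobs into one connected component. Eroding
#' twice, at a small and a larger scale, removes such bridges, and a
#' dilation at the larger scale restores most of the lost band extent:
#' erosion with the `small` element, erosion with the `large` (5 x 5)
#' element, then dilation with the `large` element. The result is always a
#' subset of `dilate(b)` and of `b` itself.
#'
#' @param b Binary (0/1) integer matrix.
#' @param small,large Odd sizes of the two erosion elements (defaults 3
#'   and 5); the dilation reuses `large`.
#' @return Binary matrix with touching objects separated.
#' @export
separate_objects <- function(b, small = 3, large = 5) {
  check_binary(b)
  dilate(erode(erode(b, small), large), large)
}

#' Label 8-connected foreground components
#'
#' Maximal 8-connected foreground regions receive labels 1..n in raster
#' order (row by row, left to right) of each component's first pixel.
#'
#' @param b Binary (0/1) integer matrix.
#' @param connectivity Only 8 is supported (the boundary-detection step of
#'   the pipeline).
#' @return A list with `label_map` (integer matrix, 0 = background) and
#'   `n_components`.
#' @export
connected_components <- function(b, connectivity = 8) {
  check_binary(b)
  if (connectivity != 8) {
    ts_error("only 8-connectivity is supported", "thalscreen_parameter_error")
  }
  lab <- .cpp_label_components(b)
  n <- attr(lab, "n_components")
  attr(lab, "n_components") <- NULL
  list(label_map = lab, n_components = n)
}
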