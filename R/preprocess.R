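#' Convert an RGB strip image to grayscale
#'
#' Luma-weighted combination with ITU-R BT.601 weights
#' (0.299, 0.587, 0.114), rounded to the nearest integer.
#'
#' @param rgb An H x W x 3 array with values in 0--255.
#' @return An integer matrix of gray levels in 0--255.
#' @export
to_grayscale <- function(rgb) {
  stopifnot_rgb(rgb)
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(round(g)), nrow = dim(rgb)[1])
}

#' Complement a grayscale image
#'
#' Maps every pixel to `255 - value`, turning dark bands on a light
#' background into bright foreground. An involution.
#'
#' @param g An integer matrix of gray levels in 0--255.
#' @return The complemented matrix.
#' @export
complement_image <- function(g) {
  if (!is.matrix(g)) ts_error("expected a matrix", "thalscreen_format_error")
  matrix(255L - as.integer(g), nrow = nrow(g))
}

gaussian_kernel_1d <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# pad indices with symmetric (edge-repeating) reflection
reflect_idx <- function(n, pad) {
  c(rev(seq_len(pad)), seq_len(n), n + 1 - seq_len(pad))
}

#' Gaussian blur with reflected borders
#'
#' Separable Gaussian convolution (default 5 x 5, sigma 1) applied to a
#' grayscale image; borders are reflected, and the result is rounded and
#' clipped back to 0--255. A unit-sum kernel leaves constant images
#' unchanged and preserves total intensity of interior-supported content.
#'
#' @param g Integer matrix of gray levels.
#' @param kernel Odd kernel size (the denoising filter uses 5).
#' @param sigma Gaussian standard deviation in pixels.
#' @return Blurred integer matrix.
#' @export
gaussian_blur <- function(g, kernel = 5, sigma = 1) {
  if (!is.matrix(g)) ts_error("expected a matrix", "thalscreen_format_error")
  if (kernel %% 2 != 1 || kernel < 1) {
    ts_error("kernel size must be odd", "thalscreen_parameter_error")
  }
  if (sigma <= 0) ts_error("sigma must be positive",
                           "thalscreen_parameter_error")
  k <- gaussian_kernel_1d(kernel, sigma)
  pad <- (kernel - 1) / 2
  x <- g[reflect_idx(nrow(g), pad), , drop = FALSE]
  # convolve along rows
  out <- matrix(0, nrow(g), ncol(g))
  for (t in seq_len(kernel)) {
    out <- out + k[t] * x[t:(t + nrow(g) - 1), , drop = FALSE]
  }
  x <- out[, reflect_idx(ncol(g), pad), drop = FALSE]
  out <- matrix(0, nrow(g), ncol(g))
  for (t in seq_len(kernel)) {
    out <- out + k[t] * x[, t:(t + ncol(g) - 1), drop = FALSE]
  }
  matrix(as.integer(round(clip255(out))), nrow = nrow(g))
}

#' Otsu's threshold
#'
#' Scans all 256 candidate thresholds and returns the one maximizing the
#' between-class variance of the gray-level histogram (equivalently,
#' minimizing the within-class variance); ties are broken toward the
#' smallest threshold. Foreground is defined as `pixels > t`.
#'
#' @param g Integer matrix of gray levels in 0--255.
#' @return The threshold, an integer in 0--254.
#' @export
otsu_threshold <- function(g) {
  if (!is.matrix(g)) ts_error("expected a matrix", "thalscreen_format_error")
  v <- as.integer(g)
  if (min(v) == max(v)) {
    ts_error("Otsu threshold undefined for a constant image",
             "thalscreen_degenerate_histogram_error")
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  omega0 <- cumsum(p)                       # P(value <= t)
  mu_cum <- cumsum(p * levels)
  mu_total <- mu_cum[256]
  omega1 <- 1 - omega0
  # between-class variance at each t in 0..255 (foreground = > t)
  valid <- omega0 > 0 & omega1 > 0
  sigma_b <- rep(-Inf, 256)
  mu0 <- mu_cum[valid] / omega0[valid]
  mu1 <- (mu_total - mu_cum[valid]) / omega1[valid]
  sigma_b[valid] <- omega0[valid] * omega1[valid] * (mu0 - mu1)^2
  as.integer(which.max(sigma_b) - 1L)       # which.max takes the first max
}

#' Binarize a grayscale image at a threshold
#'
#' @param g Integer matrix of gray levels.
#' @param threshold Foreground is `pixels > threshold`.
#' @return Integer matrix in `{0, 1}`.
#' @export
binarize <- function(g, threshold) {
  if (!is.matrix(g)) ts_error("expected a matrix", "thalscreen_format_error")
  matrix(as.integer(g > threshold), nrow = nrow(g))
}

#' Run the filtering-and-thresholding front end on a strip image
#'
#' Grayscale conversion, complementation, 5 x 5 Gaussian blur, Otsu
#' thresholding on the blurred complement, and binarization.
#'
#' @param rgb An H x W x 3 strip image.
#' @param kernel,sigma Blur parameters.
#' @return A list with `gray`, `complement`, `blurred`, `threshold` and
#'   `binary`.
#' @export
preprocess_strip <- function(rgb, kernel = 5, sigma = 1) {
  g <- to_grayscale(rgb)
  comp <- complement_image(g)
  bl <- gaussian_blur(comp, kernel = kernel, sigma = sigma)
  t <- otsu_threshold(bl)
  list(gray = g, complement = comp, blurred = bl, threshold = t,
       binary = binarize(bl, t))
}
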