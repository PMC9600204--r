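#' Derive lane boxes from labeled components
#'
#' Components smaller than `min_area` pixels are discarded as stain
#' specks. Surviving components are grouped whenever their column
#' intervals overlap or come within `gap_tol` pixels of each other — the
#' bands of one patient stack vertically and share a column span. Each
#' group yields one box covering the full strip height and the group's
#' column extent padded by `margin` pixels (clipped to the image).
#'
#' @param cl A labeling from [connected_components()].
#' @param min_area Minimum component area in pixels.
#' @param expected_lanes Optional expected lane count; a mismatch attaches
#'   a structured warning (class `thalscreen_lane_mismatch`) and a
#'   `"warnings"` attribute to the result — never a silent discrepancy.
#' @param margin Column padding per side, pixels.
#' @param gap_tol Column intervals closer than this many pixels are merged
#'   into one lane group.
#' @return A list of [lane_box()] objects ordered left to right, with a
#'   `"warnings"` attribute (possibly empty character vector).
#' @export
lanes_from_components <- function(cl, min_area, expected_lanes = NULL,
                                  margin = 2, gap_tol = 2) {
  lab <- cl$label_map
  n <- cl$n_components
  H <- nrow(lab); W <- ncol(lab)
  if (n > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(areas >= min_area)
  } else {
    keep <- integer(0)
  }
  if (length(keep) == 0L) {
    ts_error("no foreground components survive the area filter",
             "thalscreen_no_lanes_error")
  }
  cols <- col(lab)
  iv <- t(vapply(keep, function(k) {
    cc <- cols[lab == k]
    c(min(cc), max(cc))                  # 1-based inclusive column range
  }, numeric(2)))
  ord <- order(iv[, 1], iv[, 2])
  iv <- iv[ord, , drop = FALSE]
  # sweep-line grouping of overlapping / near-touching column intervals
  g0 <- iv[1, 1]; g1 <- iv[1, 2]
  groups <- list()
  for (t in seq_len(nrow(iv))[-1]) {
    if (iv[t, 1] <= g1 + gap_tol) {
      g1 <- max(g1, iv[t, 2])
    } else {
      groups[[length(groups) + 1L]] <- c(g0, g1)
      g0 <- iv[t, 1]; g1 <- iv[t, 2]
    }
  }
  groups[[length(groups) + 1L]] <- c(g0, g1)
  boxes <- lapply(groups, function(g) {
    lane_box(0L, H,
             max(0L, g[1] - 1L - margin),       # to 0-based, padded
             min(W, g[2] + margin))
  })
  warns <- character(0)
  if (!is.null(expected_lanes) && length(boxes) != expected_lanes) {
    msg <- sprintf("expected %d lanes but detected %d",
                   expected_lanes, length(boxes))
    warns <- msg
    ts_warning(msg, "thalscreen_lane_mismatch")
  }
  attr(boxes, "warnings") <- warns
  boxes
}

#' Crop a lane and resample it to the classifier input size
#'
#' Crops the strip to `box` and resamples the crop with bilinear
#' interpolation to exactly `out_w` columns by `out_h` rows (default
#' 30 x 150, the fixed classifier input). A crop already at the target
#' size passes through pixel-identically.
#'
#' @param strip H x W x 3 RGB array.
#' @param box A [lane_box()] within the image.
#' @param out_h,out_w Output rows and columns.
#' @return A `lane_image`: integer array `c(out_h, out_w, 3)` with the
#'   source box attached as attribute `"box"`.
#' @export
crop_and_resize <- function(strip, box, out_h = 150, out_w = 30) {
  stopifnot_rgb(strip)
  d <- dim(strip)
  if (box$row1 > d[1] || box$col1 > d[2]) {
    ts_error("lane box exceeds image bounds", "thalscreen_geometry_error")
  }
  crop <- strip[(box$row0 + 1L):box$row1, (box$col0 + 1L):box$col1, ,
                drop = FALSE]
  res <- .cpp_resize_bilinear(array(as.double(crop), dim = dim(crop)),
                              as.integer(out_h), as.integer(out_w))
  out <- array(as.integer(round(clip255(res))), dim = c(out_h, out_w, 3L))
  attr(out, "box") <- box
  class(out) <- c("lane_image", class(out))
  out
}

#' Extract all patient lanes from a strip image
#'
#' The full segmentation pipeline: grayscale, complement, 5 x 5 Gaussian
#' blur, Otsu binarization, two-scale erosion with compensating dilation,
#' 8-connected component labeling, lane box derivation, and per-lane
#' cropping to the fixed 30 x 150 RGB input.
#'
#' @param strip H x W x 3 RGB array (or a path readable by
#'   [read_image()]).
#' @param expected_lanes Expected number of lanes (8 for the standard
#'   strip format); mismatches raise a structured warning.
#' @param min_area_frac Minimum component area as a fraction of image
#'   pixels.
#' @param separate Apply [separate_objects()] before labeling (on by
#'   default; disable to see merged lanes fuse).
#' @param margin,gap_tol,kernel,sigma Passed to the underlying steps.
#' @return A list of `lane_image` crops in left-to-right order; attributes
#'   `"boxes"` and `"warnings"` carry the detected boxes and any lane
#'   count mismatch messages.
#' @export
extract_lanes <- function(strip, expected_lanes = NULL,
                          min_area_frac = 0.0005, separate = TRUE,
                          margin = 2, gap_tol = 2, kernel = 5, sigma = 1) {
  if (is.character(strip)) strip <- read_image(strip)
  stopifnot_rgb(strip)
  pre <- tryCatch(
    preprocess_strip(strip, kernel = kernel, sigma = sigma),
    thalscreen_degenerate_histogram_error = function(e) {
      ts_error("no foreground found: strip image is featureless",
               "thalscreen_no_lanes_error")
    })
  mask <- pre$binary
  if (separate) mask <- separate_objects(mask)
  cl <- connected_components(mask)
  min_area <- min_area_frac * length(mask)
  boxes <- lanes_from_components(cl, min_area = min_area,
                                 expected_lanes = expected_lanes,
                                 margin = margin, gap_tol = gap_tol)
  lanes <- lapply(boxes, function(b) crop_and_resize(strip, b))
  attr(lanes, "boxes") <- boxes
  attr(lanes, "warnings") <- attr(boxes, "warnings")
  lanes
}
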