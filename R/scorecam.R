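minmax_01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Score-CAM saliency map for a lane image
#'
#' Gradient-free class activation mapping: each channel of the chosen
#' convolutional activation is min-max normalized, upsampled to the input
#' size, and used to mask the input (elementwise product against a zero
#' baseline); the masked input's forward-pass softmax score for the target
#' class is that channel's weight. The map is the rectified weighted sum
#' of the normalized upsampled channels, min-max normalized to `[0, 1]`.
#' Channels with constant activation carry no signal and are skipped; if
#' every channel is constant (e.g. all-zero activations) the map is all
#' zero.
#'
#' @param fit A `tinycnn_fit` or `tinycnn_model`.
#' @param lane A lane image (H x W x 3, 0--255).
#' @param target Target class (`"normal"` or `"thalassaemia"`).
#' @param layer Convolutional activation to explain: `"conv1"` or
#'   `"conv2"` (default: the last convolutional layer).
#' @return A `saliency_map`: matrix in `[0, 1]` with the input's spatial
#'   dimensions, with attributes `target` and `layer`.
#' @export
scorecam_map <- function(fit, lane, target = "thalassaemia",
                         layer = "conv2") {
  model <- if (inherits(fit, "tinycnn_fit")) fit$model else fit
  if (!layer %in% c("conv1", "conv2")) {
    ts_error("`layer` must name a convolutional activation ('conv1'/'conv2')",
             "thalscreen_parameter_error")
  }
  cls <- match(target, CLASS_LEVELS)
  if (is.na(cls)) {
    ts_error("unknown target class", "thalscreen_parameter_error")
  }
  h <- dim(lane)[1]; w <- dim(lane)[2]
  x <- array(lane / 255, dim = c(h, w, 3, 1))
  fw <- nn_forward(model, x, keep = TRUE)
  acts <- fw[[layer]]
  n_ch <- dim(acts)[3]
  cam <- matrix(0, h, w)
  for (ch in seq_len(n_ch)) {
    a <- acts[, , ch, 1]
    if (diff(range(a)) <= 0) next
    up <- .cpp_resize_bilinear(minmax_01(a), h, w)
    masked <- array(as.vector(x) * rep(as.vector(up), 3),
                    dim = c(h, w, 3, 1))
    wgt <- nn_forward(model, masked)$probs[cls, 1]
    cam <- cam + wgt * up
  }
  cam <- pmax(cam, 0)
  cam <- minmax_01(cam)
  structure(cam, class = c("saliency_map", class(cam)),
            target = target, layer = layer)
}

#' Overlay a saliency map on a lane image
#'
#' Alpha-blends a blue-to-red colormap of the map over the lane: blue
#' marks regions with little influence on the decision, red the dominant
#' ones.
#'
#' @param map A `saliency_map` (values in `[0, 1]`).
#' @param lane The lane image the map was computed for.
#' @param alpha Blend weight of the colormap; `0` returns the lane
#'   unchanged.
#' @return An H x W x 3 integer RGB array.
#' @export
overlay_saliency <- function(map, lane, alpha = 0.45) {
  stopifnot_rgb(lane)
  if (!all(dim(map) == dim(lane)[1:2])) {
    ts_error("saliency map and lane dimensions differ",
             "thalscreen_geometry_error")
  }
  if (alpha == 0) return(lane)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(map))
  out <- array(0L, dim = dim(lane))
  for (ch in 1:3) {
    plane <- (1 - alpha) * lane[, , ch] +
      alpha * matrix(cols[, ch], nrow(map), ncol(map))
    out[, , ch] <- as.integer(round(clip255(plane)))
  }
  out
}
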