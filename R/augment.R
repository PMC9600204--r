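#' Augmentation specification
#'
#' The training-set augmentation applies, per variant, one of three
#' geometric strategies in a fixed cycle (rotation, scaling, translation),
#' with the parameter drawn uniformly from its range: clockwise rotation
#' of 3--5 degrees, magnification of 2.5--10%, or horizontal-and-vertical
#' translation of 5--10% of the image size (random direction). Fourteen
#' variants per image turn each training image into fifteen.
#'
#' @param rotation_deg_range Clockwise rotation range in degrees.
#' @param scale_frac_range Magnification range as a fraction above 1.
#' @param translate_frac_range Translation range as a fraction of each
#'   dimension.
#' @param n_variants Number of augmented variants per image.
#' @param seed Integer seed for the parameter draws.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(rotation_deg_range = c(3, 5),
                         scale_frac_range = c(0.025, 0.10),
                         translate_frac_range = c(0.05, 0.10),
                         n_variants = 14, seed = 1) {
  if (!is_count(n_variants)) {
    ts_error("n_variants must be a positive integer",
             "thalscreen_parameter_error")
  }
  structure(list(rotation_deg_range = rotation_deg_range,
                 scale_frac_range = scale_frac_range,
                 translate_frac_range = translate_frac_range,
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# Build the inverse affine map (output pixel -> source coords) for one
# strategy and apply it with bilinear sampling and border replication.
apply_affine <- function(img, m) {
  res <- .cpp_warp_affine(array(as.double(img), dim = dim(img)), m)
  array(as.integer(round(clip255(res))), dim = dim(img))
}

# One augmented variant; draws from the current RNG stream.
augment_one <- function(lane, strategy, spec) {
  h <- dim(lane)[1]; w <- dim(lane)[2]
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  if (strategy == "rotation") {
    ang <- runif(1, spec$rotation_deg_range[1], spec$rotation_deg_range[2])
    th <- ang * pi / 180
    m <- rbind(c(cos(th), -sin(th), cr - cos(th) * cr + sin(th) * cc),
               c(sin(th),  cos(th), cc - sin(th) * cr - cos(th) * cc))
    params <- list(strategy = "rotation", angle_deg = ang)
  } else if (strategy == "scale") {
    s <- 1 + runif(1, spec$scale_frac_range[1], spec$scale_frac_range[2])
    m <- rbind(c(1 / s, 0, cr - cr / s),
               c(0, 1 / s, cc - cc / s))
    params <- list(strategy = "scale", factor = s)
  } else {
    tr <- sample(c(-1, 1), 1) * runif(1, spec$translate_frac_range[1],
                                      spec$translate_frac_range[2]) * h
    tc <- sample(c(-1, 1), 1) * runif(1, spec$translate_frac_range[1],
                                      spec$translate_frac_range[2]) * w
    m <- rbind(c(1, 0, -tr),
               c(0, 1, -tc))
    params <- list(strategy = "translation", shift_rows = tr,
                   shift_cols = tc)
  }
  out <- apply_affine(lane, m)
  attr(out, "augment_params") <- params
  out
}

augment_image_core <- function(lane, spec) {
  strategies <- c("rotation", "scale", "translation")
  out <- vector("list", spec$n_variants + 1L)
  out[[1L]] <- lane
  for (k in seq_len(spec$n_variants)) {
    out[[k + 1L]] <- augment_one(lane, strategies[(k - 1L) %% 3L + 1L], spec)
  }
  out
}

#' Augment one lane image
#'
#' Produces `n_variants + 1` images: the original first, then one variant
#' per cycle position (rotation, scale, translation, rotation, ...), each
#' with its parameter drawn from the seeded generator. Output dimensions
#' and the 0--255 range are preserved (border replication after the
#' transform); the applied parameters are attached to each variant as
#' attribute `"augment_params"`.
#'
#' @param lane A lane image array (rows x cols x 3).
#' @param spec An [augment_spec()].
#' @return A list of `spec$n_variants + 1` arrays.
#' @export
augment_image <- function(lane, spec = augment_spec()) {
  stopifnot_rgb(lane)
  with_seed(spec$seed, function() augment_image_core(lane, spec))
}

#' Augment a set of lane images
#'
#' Applies [augment_image()] to every input under a single seeded stream,
#' so the output count is always `(n_variants + 1) * length(lanes)`
#' (e.g. 189 training images per class per fold become 2835). Attribute
#' `"source"` records the index of each output's source image; labels, if
#' given, are carried over unchanged to every variant.
#'
#' @param lanes List of lane image arrays (possibly empty).
#' @param spec An [augment_spec()].
#' @param labels Optional label vector, one per input image.
#' @return A list of augmented images with attributes `"source"` and
#'   (when `labels` is given) `"labels"`.
#' @export
augment_set <- function(lanes, spec = augment_spec(), labels = NULL) {
  if (!is.null(labels) && length(labels) != length(lanes)) {
    ts_error("`labels` must match `lanes` in length",
             "thalscreen_parameter_error")
  }
  if (length(lanes) == 0L) {
    out <- list()
    attr(out, "source") <- integer(0)
    if (!is.null(labels)) attr(out, "labels") <- character(0)
    return(out)
  }
  out <- with_seed(spec$seed, function() {
    unlist(lapply(lanes, augment_image_core, spec = spec), recursive = FALSE)
  })
  per <- spec$n_variants + 1L
  attr(out, "source") <- rep(seq_along(lanes), each = per)
  if (!is.null(labels)) attr(out, "labels") <- rep(labels, each = per)
  out
}
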