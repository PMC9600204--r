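#' Band specification for a synthetic lane
#'
#' A band is one haemoglobin variant's stained stripe. Its position along
#' the migration axis is a fraction of the lane length measured from the
#' application point (row 0); HbA migrates farthest (largest fraction),
#' HbA2 least. `intensity_frac` is the band's share of the lane's total
#' stain, and `width_frac` its Gaussian spread as a fraction of lane
#' length.
#'
#' @param variant One of `"HbA"`, `"HbF"`, `"HbA2"`.
#' @param center_frac Band centre as a fraction of lane length in (0, 1).
#' @param intensity_frac Fraction of total stain in `[0, 1]`.
#' @param width_frac Gaussian sigma as a fraction of lane length.
#' @return A `band_spec` list.
#' @export
band_spec <- function(variant, center_frac, intensity_frac, width_frac) {
  variant <- match.arg(variant, c("HbA", "HbF", "HbA2"))
  if (center_frac <= 0 || center_frac >= 1 || intensity_frac < 0 ||
      intensity_frac > 1 || width_frac <= 0) {
    ts_error("invalid band specification", "thalscreen_spec_error")
  }
  structure(list(variant = variant, center_frac = center_frac,
                 intensity_frac = intensity_frac, width_frac = width_frac),
            class = "band_spec")
}

default_lane_opts <- function() {
  list(
    jitter_px       = 3,
    # HbA2 share of total stain: < 3.5% in normal adults, elevated (up to
    # ~7%) in beta-thalassaemia trait
    hba2_normal     = c(0.015, 0.034),
    hba2_thal       = c(0.040, 0.070),
    hbf_prob_normal = 0,
    hbf_prob_thal   = 0.5,
    hbf_range       = c(0.03, 0.12),
    centers         = c(HbA = 0.78, HbF = 0.55, HbA2 = 0.30),
    width_frac      = c(HbA = 0.025, HbF = 0.020, HbA2 = 0.018),
    band_col_frac   = 0.6,   # band width as a fraction of the lane slot
    edge_px         = 8,     # cosine taper of stain toward the band edges
    gain            = 2.5    # stain density -> darkness saturation gain
  )
}

#' Specification of a synthetic electrophoresis strip
#'
#' Describes a Ponceau-stained strip holding up to `n_lanes` patients side
#' by side along the columns, migration running down the rows from the
#' application point at row 0. Nuisance structure mirrors scanned strips:
#' additive Gaussian noise, a lateral illumination gradient, per-lane
#' position jitter, and (with probability `merge_prob` per adjacent pair)
#' touching lanes whose band blobs overlap by 1--3 px.
#'
#' @param height_px,width_px Canvas size in pixels (rows x columns).
#' @param n_lanes Number of patient lanes (the scanner format holds 8).
#' @param noise_sd Additive Gaussian noise, 8-bit gray levels.
#' @param illumination_slope Lateral illumination gradient, gray levels per
#'   pixel of column offset from the strip centre.
#' @param merge_prob Probability that an adjacent lane pair is shifted to
#'   touch.
#' @param seed Integer seed; identical `(spec, seed)` pairs render
#'   bit-identical strips.
#' @param lane_opts Named list overriding entries of the default lane
#'   composition (band centres, HbA2 intensity ranges per class, HbF
#'   probability, jitter).
#' @return A `strip_spec` list.
#' @export
strip_spec <- function(height_px = 320, width_px = 1280, n_lanes = 8,
                       noise_sd = 3, illumination_slope = 0.01,
                       merge_prob = 0, seed = 1, lane_opts = list()) {
  if (!is_count(height_px) || !is_count(width_px)) {
    ts_error("strip dimensions must be positive integers",
             "thalscreen_spec_error")
  }
  if (!is_count(n_lanes)) {
    ts_error("n_lanes must be a positive integer", "thalscreen_spec_error")
  }
  if (merge_prob < 0 || merge_prob > 1) {
    ts_error("merge_prob must lie in [0, 1]", "thalscreen_spec_error")
  }
  opts <- modifyList(default_lane_opts(), lane_opts)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 n_lanes = as.integer(n_lanes),
                 noise_sd = noise_sd,
                 illumination_slope = illumination_slope,
                 merge_prob = merge_prob,
                 seed = as.integer(seed),
                 lane_opts = opts),
            class = "strip_spec")
}

# Draw the band composition of one lane. HbA takes the stain remainder so
# that intensity fractions sum to 1.
draw_lane_bands <- function(label, opts) {
  if (label == "thalassaemia") {
    a2 <- runif(1, opts$hba2_thal[1], opts$hba2_thal[2])
    f  <- if (runif(1) < opts$hbf_prob_thal)
      runif(1, opts$hbf_range[1], opts$hbf_range[2]) else 0
  } else {
    a2 <- runif(1, opts$hba2_normal[1], opts$hba2_normal[2])
    f  <- if (runif(1) < opts$hbf_prob_normal)
      runif(1, opts$hbf_range[1], opts$hbf_range[2]) else 0
  }
  bands <- list(band_spec("HbA", opts$centers[["HbA"]], 1 - a2 - f,
                          opts$width_frac[["HbA"]]),
                band_spec("HbA2", opts$centers[["HbA2"]], a2,
                          opts$width_frac[["HbA2"]]))
  if (f > 0) {
    bands <- append(bands, list(band_spec("HbF", opts$centers[["HbF"]], f,
                                          opts$width_frac[["HbF"]])), 1)
  }
  bands
}

#' Render a synthetic strip with ground truth
#'
#' Draws `spec$n_lanes` lanes of dark-red bands on a pink Ponceau-like
#' background. Each band is a 1-D Gaussian ridge along the rows whose
#' integrated darkness is proportional to its stain fraction, windowed to
#' the lane's column span. Ground truth records per-lane boxes (pairwise
#' disjoint; overlaps from merged lanes are split at the midline), class
#' labels, and band centre rows.
#'
#' @param spec A [strip_spec()].
#' @param labels Optional character vector of lane labels
#'   (`"normal"`/`"thalassaemia"`); drawn 50/50 from the spec seed when
#'   omitted.
#' @return A list with elements `image` (H x W x 3 integer array) and
#'   `truth` (list of `lane_boxes`, `labels`, `band_centers`,
#'   `band_intensities`, `band_windows`).
#' @export
#' @examples
#' st <- render_strip(strip_spec(seed = 7))
#' length(st$truth$lane_boxes)
render_strip <- function(spec, labels = NULL) {
  if (!inherits(spec, "strip_spec")) {
    ts_error("`spec` must be a strip_spec", "thalscreen_spec_error")
  }
  n <- spec$n_lanes
  if (!is.null(labels)) {
    if (length(labels) != n ||
        !all(labels %in% c("normal", "thalassaemia"))) {
      ts_error("`labels` must give 'normal'/'thalassaemia' per lane",
               "thalscreen_spec_error")
    }
  }
  with_seed(spec$seed, function() {
    H <- spec$height_px; W <- spec$width_px; opts <- spec$lane_opts
    if (is.null(labels)) {
      labels <- sample(c("normal", "thalassaemia"), n, replace = TRUE)
    }
    slot <- W / n
    bw <- max(4L, as.integer(round(opts$band_col_frac * slot)))
    jit <- if (opts$jitter_px > 0)
      round(runif(n, -opts$jitter_px, opts$jitter_px)) else rep(0, n)
    c0 <- as.integer(round((seq_len(n) - 1) * slot + (slot - bw) / 2 + jit))
    c1 <- c0 + bw                       # half-open column windows
    # merged-lane nuisance: a thin smear of stain joins the HbA blobs of
    # an adjacent pair (sample material dragged between application
    # points), so the pair forms one connected component until the
    # two-scale erosion cuts the neck
    merged_pairs <- if (n > 1) which(runif(n - 1) < spec$merge_prob)
                    else integer(0)
    c0 <- pmax(0L, pmin(c0, W - 2L)); c1 <- pmax(c0 + 1L, pmin(c1, W))

    lane_bands <- lapply(labels, draw_lane_bands, opts = opts)
    rows <- seq_len(H) - 1L
    darkness <- matrix(0, H, W)
    band_centers <- vector("list", n)
    band_intens <- vector("list", n)
    for (k in seq_len(n)) {
      stain <- numeric(H)
      ctr <- numeric(0); intens <- numeric(0)
      for (b in lane_bands[[k]]) {
        mu <- b$center_frac * (H - 1)
        sigma <- b$width_frac * H
        stain <- stain + b$intensity_frac * exp(-(rows - mu)^2 / (2 * sigma^2))
        ctr[b$variant] <- round(mu)
        intens[b$variant] <- b$intensity_frac
      }
      dk <- 255 * pmin(1, opts$gain * stain)
      cols <- (c0[k] + 1L):c1[k]
      # stain fades toward the lane edges, so band blobs are rounded and
      # touching lanes meet in a narrow neck rather than a solid block
      d_edge <- pmin(seq_along(cols) - 0.5, rev(seq_along(cols)) - 0.5)
      profile <- sin(pi / 2 * pmin(1, d_edge / opts$edge_px))
      darkness[, cols] <- pmax(darkness[, cols], outer(dk, profile))
      band_centers[[k]] <- ctr
      band_intens[[k]] <- intens
    }
    # draw the merging smears: ~4 rows tall at the HbA migration position,
    # moderate darkness, bridging the gap between the two band windows
    for (k in merged_pairs) {
      mu <- opts$centers[["HbA"]] * (H - 1)
      smear_rows <- pmax(1L, pmin(H, as.integer(round(mu)) + (-1L:2L)))
      smear_cols <- ((c1[k] - opts$edge_px):(c0[k + 1] + opts$edge_px)) + 1L
      smear_cols <- smear_cols[smear_cols >= 1 & smear_cols <= W]
      darkness[smear_rows, smear_cols] <-
        pmax(darkness[smear_rows, smear_cols], 0.55 * 255)
    }

    base <- c(243, 205, 205)          # Ponceau-pink background
    wts <- c(0.45, 0.95, 0.90)        # band colour: dark red
    illum <- spec$illumination_slope * (seq_len(W) - 1L - (W - 1) / 2)
    noise <- if (spec$noise_sd > 0) matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
             else matrix(0, H, W)
    img <- array(0L, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- base[ch] - wts[ch] * darkness +
        matrix(illum, H, W, byrow = TRUE) + noise
      img[, , ch] <- as.integer(round(clip255(plane)))
    }

    # ground-truth boxes: stain windows, overlap split at the midline so
    # boxes stay pairwise disjoint
    g0 <- c0; g1 <- c1
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        if (g1[k] > g0[k + 1]) {
          mid <- as.integer(floor((g1[k] + g0[k + 1]) / 2))
          g1[k] <- mid; g0[k + 1] <- mid
        }
      }
    }
    boxes <- lapply(seq_len(n), function(k) lane_box(0L, H, g0[k], g1[k]))
    list(image = img,
         truth = list(lane_boxes = boxes, labels = labels,
                      band_centers = band_centers,
                      band_intensities = band_intens,
                      band_windows = cbind(col0 = c0, col1 = c1),
                      merged_pairs = merged_pairs))
  })
}

#' Generate a synthetic strip dataset on disk
#'
#' Renders `n_strips` strips as PNG files plus a CSV manifest with one row
#' per lane (columns `strip_path, lane_index, row0, row1, col0, col1,
#' label`). Class labels are assigned so that the overall fraction of
#' thalassaemia lanes matches `class_balance` to within one lane, then
#' shuffled across strips with the spec seed. Per-strip render seeds are
#' derived from `spec$seed` by fixed offsets, so a rerun with the same
#' arguments is byte-identical.
#'
#' @param n_strips Number of strips to render.
#' @param class_balance Target fraction of thalassaemia lanes.
#' @param spec A [strip_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_strips, class_balance = 0.5, spec = strip_spec(),
                             out_dir) {
  if (!is_count(n_strips)) {
    ts_error("n_strips must be a positive integer", "thalscreen_spec_error")
  }
  if (class_balance < 0 || class_balance > 1) {
    ts_error("class_balance must lie in [0, 1]", "thalscreen_spec_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    ts_error(sprintf("cannot create output directory '%s'", out_dir),
             "thalscreen_io_error")
  }
  total <- n_strips * spec$n_lanes
  n_thal <- round(class_balance * total)
  labels_all <- with_seed(spec$seed, function() {
    sample(c(rep("thalassaemia", n_thal), rep("normal", total - n_thal)))
  })
  rows <- vector("list", n_strips)
  for (s in seq_len(n_strips)) {
    sp <- spec
    sp$seed <- spec$seed + s            # fixed per-strip fan-out
    lab <- labels_all[((s - 1) * spec$n_lanes + 1):(s * spec$n_lanes)]
    st <- render_strip(sp, labels = lab)
    fname <- sprintf("strip_%04d.png", s)
    write_image(st$image, file.path(out_dir, fname))
    bx <- do.call(rbind, lapply(st$truth$lane_boxes, function(b)
      data.frame(row0 = b$row0, row1 = b$row1, col0 = b$col0, col1 = b$col1)))
    rows[[s]] <- data.frame(strip_path = fname,
                            lane_index = seq_len(spec$n_lanes) - 1L,
                            bx, label = lab,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
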