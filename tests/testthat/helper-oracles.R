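# Independent oracles and shared fixtures, all built in code.

# Brute-force Otsu: minimize within-class variance over all 256 thresholds,
# computed directly from pixel values (not from the histogram recursion).
otsu_oracle <- function(g) {
  v <- as.numeric(g)
  best_t <- NA_integer_
  best_wcv <- Inf
  for (t in 0:255) {
    fg <- v[v > t]; bg <- v[v <= t]
    if (length(fg) == 0 || length(bg) == 0) next
    wcv <- sum((bg - mean(bg))^2) + sum((fg - mean(fg))^2)
    if (wcv < best_wcv - 1e-9) { best_wcv <- wcv; best_t <- t }
  }
  best_t
}

# Iterative flood-fill component labelling; labels in raster order (row by
# row, left to right) of each component's first pixel.
floodfill_oracle <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 1L && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        stack <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (t in seq_len(nrow(nbr))) {
            ii <- p[1] + nbr[t, 1]; jj <- p[2] + nbr[t, 2]
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
                mask[ii, jj] == 1L && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# Bilinear resize with half-pixel centres and clamped borders, written
# independently with plain loops.
bilinear_oracle <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      sr <- min(max((i - 0.5) * h / out_h - 0.5, 0), h - 1)
      sc <- min(max((j - 0.5) * w / out_w - 0.5, 0), w - 1)
      r0 <- floor(sr); c0 <- floor(sc)
      r1 <- min(r0 + 1, h - 1); c1 <- min(c0 + 1, w - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- (1 - fr) * ((1 - fc) * m[r0 + 1, c0 + 1] +
                               fc * m[r0 + 1, c1 + 1]) +
                   fr * ((1 - fc) * m[r1 + 1, c0 + 1] +
                         fc * m[r1 + 1, c1 + 1])
    }
  }
  out
}

# Step-by-step Score-CAM recipe, using the model only as a black-box scorer.
scorecam_oracle <- function(model, lane, target, layer) {
  h <- dim(lane)[1]; w <- dim(lane)[2]
  cls <- match(target, c("normal", "thalassaemia"))
  x <- array(lane / 255, dim = c(h, w, 3, 1))
  acts <- nn_forward(model, x, keep = TRUE)[[layer]]
  cam <- matrix(0, h, w)
  for (ch in seq_len(dim(acts)[3])) {
    a <- acts[, , ch, 1]
    if (max(a) - min(a) <= 0) next
    norm <- (a - min(a)) / (max(a) - min(a))
    up <- bilinear_oracle(norm, h, w)
    masked <- array(0, dim = c(h, w, 3, 1))
    for (cc in 1:3) masked[, , cc, 1] <- x[, , cc, 1] * up
    wgt <- nn_forward(model, masked)$probs[cls, 1]
    cam <- cam + wgt * up
  }
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- (cam - min(cam)) / (max(cam) - min(cam))
  cam
}

# All-pairs AUC: concordant fraction with half credit for ties.
auc_oracle <- function(truth, score, positive = "thalassaemia") {
  pos <- score[truth == positive]
  neg <- score[truth != positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# --- shared fixtures -------------------------------------------------------

# Lane crops with well-separated classes, via the full extraction pipeline.
build_lane_set <- function(n_strips, seed, noise_sd = 2) {
  sp <- strip_spec(seed = seed, noise_sd = noise_sd, lane_opts = list(
    hba2_normal = c(0.005, 0.015), hba2_thal = c(0.055, 0.07)))
  lanes <- list(); labels <- character(0)
  for (s in seq_len(n_strips)) {
    spp <- sp
    spp$seed <- sp$seed + s
    st <- render_strip(spp)
    for (k in seq_len(sp$n_lanes)) {
      id <- sprintf("s%d_l%d", s, k)
      lanes[[id]] <- crop_and_resize(st$image, st$truth$lane_boxes[[k]])
      labels[id] <- st$truth$labels[k]
    }
  }
  list(lanes = lanes, labels = labels)
}

# One trained fit on separable lanes, trained once per test run and reused.
fixture_env <- new.env(parent = emptyenv())
get_trained_fit <- function() {
  if (is.null(fixture_env$fit)) {
    d <- build_lane_set(12, seed = 400)
    split <- make_folds(d$labels, k = 4, val_per_class = 6, seed = 1)[[1]]
    fixture_env$fit <- train_tinycnn(
      d$lanes[split$train_ids], d$labels[split$train_ids],
      d$lanes[split$val_ids], d$labels[split$val_ids],
      cfg = train_config(max_epochs = 6, seed = 3))
    fixture_env$data <- d
  }
  list(fit = fixture_env$fit, data = fixture_env$data)
}

clip255_test <- function(x) pmin(pmax(x, 0), 255)

random_mask <- function(h, w, p = 0.45) {
  matrix(as.integer(runif(h * w) < p), h, w)
}
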