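toy_lane <- function(h = 8, w = 8, seed = 77) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

test_that("a single-channel layer returns its own normalized upsampled map", {
  model <- tinycnn_init(input_h = 8, input_w = 8, c1 = 1, c2 = 1, seed = 5)
  lane <- toy_lane()
  cam <- scorecam_map(model, lane, layer = "conv1")
  x <- array(lane / 255, dim = c(8, 8, 3, 1))
  a <- nn_forward(model, x, keep = TRUE)$conv1[, , 1, 1]
  expected <- (a - min(a)) / (max(a) - min(a))   # same dims: no resampling
  expect_equal(unclass(cam)[, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the map matches an independent step-by-step oracle", {
  model <- tinycnn_init(input_h = 8, input_w = 8, c1 = 2, c2 = 2, seed = 11)
  lane <- toy_lane(seed = 13)
  for (layer in c("conv1", "conv2")) {
    cam <- scorecam_map(model, lane, target = "thalassaemia", layer = layer)
    oracle <- scorecam_oracle(model, lane, "thalassaemia", layer)
    expect_lt(max(abs(unclass(cam)[, ] - oracle)), 1e-6)
  }
  # range and shape contracts
  cam <- scorecam_map(model, lane, layer = "conv2")
  expect_identical(dim(cam), dim(lane)[1:2])
  expect_gte(min(cam), 0); expect_lte(max(cam), 1)
  expect_equal(max(cam), 1)                     # max is 1 unless all zero
})

test_that("all-zero activations give an all-zero map", {
  model <- tinycnn_init(input_h = 8, input_w = 8, c1 = 2, c2 = 2, seed = 3)
  model$params$W1[] <- 0
  model$params$b1[] <- 0
  cam <- scorecam_map(model, toy_lane(), layer = "conv1")
  expect_true(all(cam == 0))
})

test_that("invalid layers and targets are rejected", {
  model <- tinycnn_init(input_h = 8, input_w = 8, seed = 1)
  lane <- toy_lane()
  expect_error(scorecam_map(model, lane, layer = "fc"),
               class = "thalscreen_parameter_error")
  expect_error(scorecam_map(model, lane, target = "mild"),
               class = "thalscreen_parameter_error")
})

test_that("the overlay blends a blue-to-red map over the lane", {
  lane <- toy_lane(12, 10)
  zero_map <- matrix(0, 12, 10)
  ov <- overlay_saliency(zero_map, lane, alpha = 0.5)
  expect_identical(dim(ov), dim(lane))
  # a zero map tints toward blue: blue channel gains, red never gains
  expect_gte(mean(ov[, , 3]) - mean(lane[, , 3]) / 2, 0)
  expect_true(all(ov[, , 1] <= lane[, , 1] * 0.5 + 128))
  # identity blend
  expect_identical(overlay_saliency(zero_map, lane, alpha = 0), lane)
  expect_error(overlay_saliency(matrix(0, 3, 3), lane),
               class = "thalscreen_geometry_error")
})

test_that("saliency of a trained model concentrates on the band rows", {
  fx <- get_trained_fit()
  d <- fx$data
  # thalassaemia lanes classified by the trained net: saliency inside the
  # band rows (scaled to crop coordinates) should exceed the outside mean
  thal_ids <- names(d$labels)[d$labels == "thalassaemia"][1:6]
  inside_minus_outside <- vapply(thal_ids, function(id) {
    cam <- scorecam_map(fx$fit, d$lanes[[id]])
    # band centres at fractions 0.78 / 0.55 / 0.30 of the lane length
    rows <- round(c(0.78, 0.55, 0.30) * 149) + 1
    band <- unique(unlist(lapply(rows, function(r)
      max(1, r - 12):min(150, r + 12))))
    mean(cam[band, ]) - mean(cam[-band, ])
  }, numeric(1))
  expect_gt(mean(inside_minus_outside), 0)
})
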