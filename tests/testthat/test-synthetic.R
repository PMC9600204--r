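test_that("a rendered strip carries one ground-truth box and label per lane", {
  st <- render_strip(strip_spec(seed = 5))
  expect_length(st$truth$lane_boxes, 8)
  expect_length(st$truth$labels, 8)
  expect_identical(dim(st$image), c(320L, 1280L, 3L))
  # boxes inside bounds, pairwise disjoint, ordered by column
  c0 <- vapply(st$truth$lane_boxes, `[[`, integer(1), "col0")
  c1 <- vapply(st$truth$lane_boxes, `[[`, integer(1), "col1")
  expect_true(all(c0 >= 0 & c1 <= 1280))
  expect_true(all(diff(c0) > 0))
  expect_true(all(c1[-8] <= c0[-1]))
})

test_that("noiseless rendering puts band peaks exactly at the spec centres", {
  sp <- strip_spec(seed = 9, noise_sd = 0, illumination_slope = 0,
                   merge_prob = 0, lane_opts = list(jitter_px = 0))
  st <- render_strip(sp)
  g <- to_grayscale(st$image)
  for (k in seq_len(8)) {
    box <- st$truth$lane_boxes[[k]]
    mid <- (box$col0 + box$col1) %/% 2 + 1L
    centers <- st$truth$band_centers[[k]]
    intens <- st$truth$band_intensities[[k]]
    for (v in names(centers)) {
      # darkest rows near the recorded centre; saturated bands plateau, so
      # the rendered centre is the midpoint of the darkest plateau
      win <- (centers[[v]] - 20):(centers[[v]] + 20) + 1L
      vals <- g[win, mid]
      plateau <- win[vals == min(vals)] - 1L
      # plateau midpoint matches the spec centre up to the half-pixel
      # ambiguity of rasterizing a symmetric profile
      expect_lte(abs(mean(plateau) - centers[[v]]), 1,
                 label = sprintf("lane %d band %s centre offset", k, v))
    }
    # label encoding: HbA2 share below/above the carrier cutoff
    if (st$truth$labels[k] == "normal") {
      expect_lt(intens[["HbA2"]], 0.035)
    } else {
      expect_gte(intens[["HbA2"]], 0.035)
    }
  }
})

test_that("rendering is bit-identical for identical spec and seed", {
  sp <- strip_spec(seed = 42, merge_prob = 0.3)
  a <- render_strip(sp)
  b <- render_strip(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # and differs for another seed
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(render_strip(sp2)$image, a$image))
})

test_that("invalid strip specifications are rejected", {
  expect_error(strip_spec(height_px = 0), class = "thalscreen_spec_error")
  expect_error(strip_spec(merge_prob = 1.5), class = "thalscreen_spec_error")
  expect_error(render_strip(strip_spec(), labels = c("normal", "nope")),
               class = "thalscreen_spec_error")
})

test_that("generate_dataset writes a balanced, reproducible manifest", {
  out1 <- file.path(tempdir(), "ds1"); out2 <- file.path(tempdir(), "ds2")
  sp <- strip_spec(seed = 17, height_px = 160, width_px = 640)
  m <- generate_dataset(10, class_balance = 0.5, spec = sp, out_dir = out1)
  expect_equal(nrow(m), 80)
  expect_equal(sum(m$label == "thalassaemia"), 40)
  expect_equal(sum(m$label == "normal"), 40)
  expect_true(all(file.exists(file.path(out1, unique(m$strip_path)))))
  # rerun: byte-identical manifest
  generate_dataset(10, class_balance = 0.5, spec = sp, out_dir = out2)
  expect_identical(readLines(file.path(out1, "manifest.csv")),
                   readLines(file.path(out2, "manifest.csv")))
  # degenerate balance
  m1 <- generate_dataset(2, class_balance = 1, spec = sp,
                         out_dir = file.path(tempdir(), "ds3"))
  expect_true(all(m1$label == "thalassaemia"))
})
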