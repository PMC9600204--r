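test_that("grayscale conversion uses BT.601 luma weights", {
  white <- array(255L, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255L))
  black <- array(0L, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(black) == 0L))
  red <- array(0L, dim = c(1, 1, 3)); red[1, 1, 1] <- 255L
  expect_equal(to_grayscale(red)[1, 1], 76L)   # round(0.299 * 255)
  expect_error(to_grayscale(matrix(0, 2, 2)),
               class = "thalscreen_format_error")
})

test_that("complement maps v to 255 - v and is an involution", {
  g <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
  expect_true(all(complement_image(g) == 255L - g))
  expect_identical(complement_image(complement_image(g)), g)
  expect_true(all(complement_image(matrix(100L, 3, 3)) == 155L))
})

test_that("gaussian blur preserves constants, mass, and the kernel shape", {
  const <- matrix(137L, 12, 9)
  expect_identical(gaussian_blur(const), const)
  # impulse response equals the analytic normalized 5x5 kernel
  imp <- matrix(0L, 11, 11); imp[6, 6] <- 255L
  k1 <- exp(-(-2:2)^2 / 2); k1 <- k1 / sum(k1)
  expected <- round(255 * outer(k1, k1))
  got <- gaussian_blur(imp, kernel = 5, sigma = 1)
  expect_equal(got[4:8, 4:8], expected, tolerance = 0)
  # unit-sum kernel conserves total intensity for interior content
  expect_equal(sum(got), sum(round(255 * outer(k1, k1))))
  expect_error(gaussian_blur(const, kernel = 4),
               class = "thalscreen_parameter_error")
  expect_error(gaussian_blur(const, sigma = 0),
               class = "thalscreen_parameter_error")
})

test_that("otsu threshold matches the brute-force within-class-variance scan", {
  set.seed(71)
  # two-valued image: smallest maximizing threshold is the lower value
  two <- matrix(sample(c(50L, 200L), 400, replace = TRUE), 20, 20)
  expect_equal(otsu_threshold(two), 50L)
  expect_equal(otsu_threshold(two), otsu_oracle(two))
  # well-separated bimodal image
  bim <- matrix(as.integer(clip255_test(round(c(rnorm(300, 60, 10),
                                           rnorm(300, 190, 12))))), 20, 30)
  expect_equal(otsu_threshold(bim), otsu_oracle(bim))
  # assorted random images
  for (t in 1:25) {
    g <- matrix(sample(0:255, 15 * 14, replace = TRUE), 15, 14)
    expect_equal(otsu_threshold(g), otsu_oracle(g), info = paste("case", t))
  }
  expect_error(otsu_threshold(matrix(7L, 4, 4)),
               class = "thalscreen_degenerate_histogram_error")
})

test_that("binarization partitions the image at the threshold", {
  g <- matrix(sample(0:255, 200, replace = TRUE), 10, 20)
  t <- otsu_threshold(g)
  b <- binarize(g, t)
  expect_true(all(b %in% c(0L, 1L)))
  expect_equal(sum(b == 1) + sum(b == 0), length(g))
  expect_identical(b == 1L, g > t)
})

test_that("the preprocessing front end composes the stages in order", {
  st <- render_strip(strip_spec(seed = 2, height_px = 160, width_px = 640))
  pre <- preprocess_strip(st$image)
  expect_identical(pre$complement, complement_image(pre$gray))
  expect_identical(pre$blurred, gaussian_blur(pre$complement))
  expect_identical(pre$threshold, otsu_threshold(pre$blurred))
  expect_identical(pre$binary, binarize(pre$blurred, pre$threshold))
  # bands darker than background => complement makes them the foreground
  expect_lt(mean(pre$binary), 0.5)
})
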