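test_that("fold construction reproduces the 262-per-class protocol", {
  ids <- sprintf("im%03d", 1:524)
  labels <- setNames(rep(c("normal", "thalassaemia"), each = 262), ids)
  folds <- make_folds(labels, k = 5, val_per_class = 21, seed = 7)
  expect_length(folds, 5)
  for (f in folds) {
    for (cl in c("normal", "thalassaemia")) {
      expect_equal(sum(labels[f$test_ids] == cl), 52)
      expect_equal(sum(labels[f$val_ids] == cl), 21)
      expect_equal(sum(labels[f$train_ids] == cl), 189)
    }
    # no leakage between test and the rest
    expect_length(intersect(f$test_ids, c(f$train_ids, f$val_ids)), 0)
  }
  pooled_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_equal(length(pooled_test), 520)       # 2 x 5 x 52
  expect_equal(anyDuplicated(pooled_test), 0)  # rotation covers 260/class
  expect_equal(length(unique(pooled_test)), 520)
})

test_that("fold construction handles small classes and bad parameters", {
  labels <- setNames(rep(c("a", "b"), each = 10), paste0("s", 1:20))
  folds <- make_folds(labels, k = 5, val_per_class = 1, seed = 1)
  f <- folds[[1]]
  expect_equal(length(f$test_ids), 4)          # 2 per class
  expect_equal(length(f$val_ids), 2)
  expect_equal(length(f$train_ids), 14)        # 7 per class
  expect_error(make_folds(labels, k = 1, val_per_class = 1),
               class = "thalscreen_parameter_error")
  expect_identical(make_folds(labels, k = 5, val_per_class = 1, seed = 3),
                   make_folds(labels, k = 5, val_per_class = 1, seed = 3))
})

test_that("the early-stopping policy reduces the rate and halts on schedule", {
  st <- thalscreen:::early_stop_state()
  # flat validation loss from the start: improvement only at epoch 1,
  # learning-rate cut after 4 bad epochs, stop after 5 (epoch 6)
  decisions <- list()
  for (epoch in 1:10) {
    st <- thalscreen:::early_stop_update(st, 1.0, 4, 5)
    decisions[[epoch]] <- st
    if (st$stop) break
  }
  expect_length(decisions, 6)
  expect_true(decisions[[1]]$improved)
  expect_true(decisions[[5]]$reduce_lr)
  expect_false(decisions[[5]]$stop)
  expect_true(decisions[[6]]$stop)
  # strictly decreasing loss never stops
  st <- thalscreen:::early_stop_state()
  for (epoch in 1:15) st <- thalscreen:::early_stop_update(st, 1 / epoch, 4, 5)
  expect_false(st$stop)
  expect_equal(st$n_bad, 0L)
})

test_that("training history is consistent with the stopping policy", {
  fx <- get_trained_fit()
  h <- fx$fit$history
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in% names(h)))
  expect_lte(nrow(h), 6)
  expect_equal(fx$fit$stopped_epoch, nrow(h))
  # replay the recorded validation losses through the policy: the run must
  # stop exactly where the policy says (or at max_epochs)
  st <- thalscreen:::early_stop_state()
  stop_at <- NA
  for (e in seq_len(nrow(h))) {
    st <- thalscreen:::early_stop_update(st, h$val_loss[e], 4, 5)
    if (st$stop) { stop_at <- e; break }
  }
  if (!is.na(stop_at)) expect_equal(stop_at, nrow(h))
  expect_error(train_tinycnn(list(), character(0), list(), character(0)),
               class = "thalscreen_contract_error")
})

test_that("prediction records are well-formed softmax outputs", {
  fx <- get_trained_fit()
  lanes <- fx$data$lanes[1:10]
  rec <- predict_lanes(fx$fit, lanes, ids = names(lanes),
                       truth = fx$data$labels[1:10], fold = 1)
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$score >= 0 & rec$score <= 1))
  expect_identical(rec$pred,
                   ifelse(rec$score > 0.5, "thalassaemia", "normal"))
  # purity: a duplicated lane gets an identical score
  rec2 <- predict_lanes(fx$fit, c(lanes[1], lanes[1]))
  expect_equal(rec2$score[1], rec2$score[2])
  # batch inference agrees with one-at-a-time inference
  singles <- vapply(lanes, function(l)
    predict_lanes(fx$fit, list(l))$score, numeric(1))
  expect_equal(unname(singles), rec$score, tolerance = 1e-12)
})

test_that("cross-validation pools disjoint test folds over every lane", {
  d <- build_lane_set(5, seed = 900)           # 40 lanes
  cv <- cross_validate(d$lanes, d$labels,
                       cfg = train_config(max_epochs = 2, seed = 5),
                       k = 5, val_per_class = 2)
  counts <- table(d$labels)
  expected <- sum(5 * (counts %/% 5))          # rotation coverage per class
  expect_equal(nrow(cv$records), expected)
  expect_equal(anyDuplicated(cv$records$lane_id), 0)
  cm <- confusion(cv$records)
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, expected)
  # augmentation multiplies only the training partitions, after the split
  expect_true(all(cv$records$lane_id %in% names(d$lanes)))
})

test_that("an unregistered architecture is rejected", {
  d <- build_lane_set(2, seed = 950)
  expect_error(
    cross_validate(d$lanes, d$labels, spec = model_spec("resnet18"),
                   cfg = train_config(max_epochs = 1), k = 2,
                   val_per_class = 1),
    class = "thalscreen_parameter_error")
  expect_error(model_spec("tinycnn", pretrained = TRUE),
               class = "thalscreen_parameter_error")
})
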