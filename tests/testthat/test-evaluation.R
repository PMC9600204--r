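test_that("confusion counting follows the screening conventions", {
  rec <- data.frame(
    truth = c("thalassaemia", "thalassaemia", "normal", "normal", "normal"),
    pred  = c("thalassaemia", "normal", "normal", "normal", "thalassaemia"))
  cm <- confusion(rec)
  expect_equal(c(cm$TP, cm$FN, cm$TN, cm$FP), c(1, 1, 2, 1))
  # all-correct records
  ok <- data.frame(truth = c("normal", "thalassaemia"),
                   pred = c("normal", "thalassaemia"))
  cm_ok <- confusion(ok)
  expect_equal(cm_ok$FP + cm_ok$FN, 0)
  # swapping the positive class swaps TP<->TN and FP<->FN
  cm_n <- confusion(rec, positive = "normal")
  expect_equal(c(cm_n$TP, cm_n$TN, cm_n$FP, cm_n$FN),
               c(cm$TN, cm$TP, cm$FN, cm$FP))
  expect_error(confusion(rec, positive = "other"),
               class = "thalscreen_parameter_error")
})

test_that("the published confusion counts yield the published metrics", {
  # best model: 15 of 262 thalassaemia and 7 of 262 normal lanes missed
  cm <- confusion_matrix(TP = 247, TN = 255, FP = 7, FN = 15)
  m <- metrics(cm)
  expect_equal(m["macro", "accuracy"], 100 * 502 / 524, tolerance = 1e-10)
  expect_equal(round(m["macro", "accuracy"], 2), 95.80)
  expect_equal(round(m["macro", "precision"], 2), 95.84)
  expect_equal(round(m["macro", "recall"], 2), 95.80)
  expect_equal(round(m["macro", "f1"], 2), 95.80)
  expect_equal(round(m["macro", "specificity"], 2), 95.80)
  # macro precision is the unweighted mean of the per-class precisions
  expect_equal(m["macro", "precision"],
               (100 * 247 / 254 + 100 * 255 / 270) / 2, tolerance = 1e-10)
  # perfect classifier: everything 100
  perf <- metrics(confusion_matrix(50, 50, 0, 0))
  expect_true(all(abs(unlist(perf["macro", ]) - 100) < 1e-12))
  # zero denominators give NA, not an error
  degen <- metrics(confusion_matrix(0, 5, 0, 0))
  expect_true(is.na(degen["positive", "recall"]))
})

test_that("confidence half-widths reproduce the published +/- values", {
  expect_equal(round(confidence_interval(95.80, 524), 2), 1.72)
  expect_equal(round(confidence_interval(95.80, 262), 2), 2.43)
  expect_equal(round(confidence_interval(95.84, 262), 2), 2.42)
  expect_equal(confidence_interval(100, 50), 0)
  expect_equal(confidence_interval(0, 50), 0)
  # decreasing in N, maximal at 50% for fixed N
  ns <- c(10, 50, 200, 1000)
  expect_true(all(diff(sapply(ns, confidence_interval, metric = 80)) < 0))
  expect_true(all(sapply(ns, function(n) {
    r50 <- confidence_interval(50, n)
    all(r50 >= sapply(c(5, 25, 75, 95), confidence_interval, N = n))
  })))
  expect_error(confidence_interval(50, 0),
               class = "thalscreen_parameter_error")
})

test_that("metric_report pairs each metric with its operative N", {
  cm <- confusion_matrix(TP = 247, TN = 255, FP = 7, FN = 15)
  rep <- metric_report(cm)
  expect_equal(rep$N[rep$metric == "accuracy"], 524)
  expect_equal(rep$N[rep$metric == "precision"], 262)
  expect_equal(round(rep$ci_half_width[rep$metric == "accuracy"], 2), 1.72)
  expect_equal(round(rep$ci_half_width[rep$metric == "recall"], 2), 2.43)
  expect_equal(round(rep$ci_half_width[rep$metric == "precision"], 2), 2.42)
})

test_that("ROC analysis matches the all-pairs concordance oracle", {
  # trivial extremes
  sep <- data.frame(truth = rep(c("normal", "thalassaemia"), each = 4),
                    score = c(0.1, 0.2, 0.15, 0.3, 0.7, 0.9, 0.8, 0.95))
  expect_equal(roc_auc(sep)$auc, 1.0)
  flat <- data.frame(truth = rep(c("normal", "thalassaemia"), each = 4),
                     score = rep(0.5, 8))
  expect_equal(roc_auc(flat)$auc, 0.5)
  # six-record hand example with a tie across classes
  hand <- data.frame(truth = c("thalassaemia", "thalassaemia", "thalassaemia",
                               "normal", "normal", "normal"),
                     score = c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1))
  expect_equal(roc_auc(hand)$auc, auc_oracle(hand$truth, hand$score))
  # random small instances, scores rounded to force ties
  set.seed(53)
  for (t in 1:30) {
    n <- sample(6:50, 1)
    rec <- data.frame(
      truth = sample(c("normal", "thalassaemia"), n, replace = TRUE),
      score = round(runif(n), 1))
    if (length(unique(rec$truth)) < 2) next
    expect_equal(roc_auc(rec)$auc, auc_oracle(rec$truth, rec$score),
                 tolerance = 1e-12, info = paste("instance", t))
  }
  # curve contracts
  rc <- roc_auc(hand)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(all(rc$fpr >= 0 & rc$fpr <= 1 & rc$tpr >= 0 & rc$tpr <= 1))
  expect_error(roc_auc(data.frame(truth = "normal", score = 0.2)),
               class = "thalscreen_contract_error")
})

test_that("ROC sweep agrees with an established implementation", {
  set.seed(59)
  rec <- data.frame(
    truth = sample(c("normal", "thalassaemia"), 80, replace = TRUE),
    score = round(runif(80), 2))
  ours <- roc_auc(rec)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rec$truth, predictor = rec$score,
    levels = c("normal", "thalassaemia"), direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("fold-averaged ROC uses the fixed grid", {
  set.seed(61)
  rec <- do.call(rbind, lapply(1:3, function(f) data.frame(
    truth = sample(c("normal", "thalassaemia"), 30, replace = TRUE),
    score = runif(30), fold = f)))
  avg <- roc_average_folds(rec)
  expect_length(avg$fpr, 101)
  expect_true(all(diff(avg$tpr) >= -1e-12))
  per_fold <- sapply(1:3, function(f)
    roc_auc(rec[rec$fold == f, ])$auc)
  expect_equal(avg$auc, mean(per_fold))
})

test_that("per-image elapsed time divides the span by the batch size", {
  expect_equal(elapsed_per_image(0, 10, 10), 1.0)
  expect_equal(elapsed_per_image(5, 5, 3), 0)
  # additive over concatenated batches
  expect_equal(elapsed_per_image(0, 6, 3) * 3 + elapsed_per_image(0, 4, 2) * 2,
               elapsed_per_image(0, 10, 5) * 5)
  expect_error(elapsed_per_image(10, 5), class = "thalscreen_clock_error")
})
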