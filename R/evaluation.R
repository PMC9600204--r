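#' Confusion matrix from prediction records
#'
#' Counts true/false positives and negatives with respect to a designated
#' positive class. For the thalassaemia screen, TP is a thalassaemia lane
#' called thalassaemia, TN a normal lane called normal, FP a normal lane
#' called thalassaemia, FN a thalassaemia lane called normal.
#'
#' @param records Data frame with `truth` and `pred` columns (as produced
#'   by [predict_lanes()]), or vectors via `truth`/`pred`.
#' @param positive The positive class.
#' @return A `confusion_matrix` list with `TP`, `TN`, `FP`, `FN`,
#'   `positive`.
#' @export
confusion <- function(records, positive = "thalassaemia") {
  if (nrow(records) == 0L) {
    ts_error("no prediction records", "thalscreen_contract_error")
  }
  classes <- unique(c(records$truth, records$pred))
  if (!positive %in% classes) {
    ts_error(sprintf("unknown positive class '%s'", positive),
             "thalscreen_parameter_error")
  }
  tp <- sum(records$truth == positive & records$pred == positive)
  tn <- sum(records$truth != positive & records$pred != positive)
  fp <- sum(records$truth != positive & records$pred == positive)
  fn <- sum(records$truth == positive & records$pred != positive)
  confusion_matrix(tp, tn, fp, fn, positive = positive)
}

#' @rdname confusion
#' @param TP,TN,FP,FN Non-negative counts.
#' @export
confusion_matrix <- function(TP, TN, FP, FN, positive = "thalassaemia") {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != floor(counts))) {
    ts_error("counts must be non-negative integers",
             "thalscreen_parameter_error")
  }
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix, positive = %s>\n", x$positive))
  print(matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
               dimnames = list(truth = c("positive", "negative"),
                               predicted = c("positive", "negative"))))
  invisible(x)
}

swap_positive <- function(cm) {
  confusion_matrix(cm$TN, cm$TP, cm$FN, cm$FP,
                   positive = paste0("not:", cm$positive))
}

metric_or_na <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

class_metrics <- function(cm) {
  c(recall      = metric_or_na(cm$TP, cm$TP + cm$FN),
    specificity = metric_or_na(cm$TN, cm$TN + cm$FP),
    precision   = metric_or_na(cm$TP, cm$TP + cm$FP),
    f1          = metric_or_na(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN))
}

#' Classification metrics from a confusion matrix
#'
#' Evaluates accuracy, recall (sensitivity), specificity, precision and
#' F1, in percent, for the positive class and for the complementary class
#' (obtained by swapping the positive designation), plus their
#' unweighted (macro) average. Accuracy is computed once on the pooled
#' counts and is invariant to which class is positive. Zero denominators
#' yield `NA` rather than an error.
#'
#' @param cm A `confusion_matrix` (from [confusion()] or
#'   [confusion_matrix()]).
#' @return A data frame with rows `positive`, `negative`, `macro` and
#'   columns `accuracy`, `recall`, `specificity`, `precision`, `f1` (all
#'   percent).
#' @export
metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    ts_error("expected a confusion_matrix", "thalscreen_parameter_error")
  }
  pos <- class_metrics(cm)
  neg <- class_metrics(swap_positive(cm))
  acc <- metric_or_na(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
  out <- rbind(positive = pos, negative = neg,
               macro = (pos + neg) / 2)
  data.frame(accuracy = acc, out)
}

#' Normal-approximation confidence half-width for a percentage metric
#'
#' The half-width is `z * sqrt(metric * (100 - metric) / N)` percentage points: the
#' binomial proportion half-width at significance multiplier `z` (1.96
#' for 95%). It is zero at 0% or 100%, maximal at 50%, and strictly
#' decreasing in `N`.
#'
#' @param metric Metric value in percent (0--100).
#' @param N Number of evaluated samples.
#' @param z Significance multiplier.
#' @return Half-width in percentage points.
#' @export
confidence_interval <- function(metric, N, z = 1.96) {
  if (!is_count(N)) {
    ts_error("N must be a positive integer", "thalscreen_parameter_error")
  }
  if (any(metric < 0 | metric > 100)) {
    ts_error("metric must lie in [0, 100]", "thalscreen_parameter_error")
  }
  z * sqrt(metric * (100 - metric) / N)
}

#' Metric estimates with confidence half-widths
#'
#' Convenience wrapper pairing [metrics()] with [confidence_interval()].
#' Accuracy uses the total evaluated count; per-class and macro metrics
#' use the per-class count (the counts that reproduce the published-style
#' `metric +/- r` reporting).
#'
#' @param cm A `confusion_matrix`.
#' @param z Significance multiplier.
#' @return A data frame: `metric`, `value`, `ci_half_width`, `N`.
#' @export
metric_report <- function(cm, z = 1.96) {
  m <- metrics(cm)
  n_total <- cm$TP + cm$TN + cm$FP + cm$FN
  n_class <- cm$TP + cm$FN            # positives; equals negatives when balanced
  vals <- c(accuracy = m["macro", "accuracy"],
            precision = m["macro", "precision"],
            recall = m["macro", "recall"],
            f1 = m["macro", "f1"],
            specificity = m["macro", "specificity"])
  ns <- c(n_total, n_class, n_class, n_class, n_class)
  data.frame(metric = names(vals), value = unname(vals),
             ci_half_width = mapply(confidence_interval, unname(vals), ns,
                                    MoreArgs = list(z = z)),
             N = ns, row.names = NULL)
}

#' ROC curve and AUC from prediction records
#'
#' Sweeps all score thresholds, computing the true- and false-positive
#' rates for the positive class, and integrates the curve by the
#' trapezoidal rule. Tied scores receive half credit, so the AUC equals
#' the Mann-Whitney concordance probability.
#'
#' @param records Data frame with `truth` and `score` (probability of the
#'   positive class).
#' @param positive Positive class.
#' @return An `roc_curve` list: `fpr`, `tpr` (non-decreasing, in
#'   `[0, 1]`), `auc`.
#' @export
roc_auc <- function(records, positive = "thalassaemia") {
  y <- records$truth == positive
  if (!any(y) || all(y)) {
    ts_error("ROC requires both classes present",
             "thalscreen_contract_error")
  }
  s <- records$score
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  # pool tied scores so ties get half credit under the trapezoid rule
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' Vertically average per-fold ROC curves
#'
#' Interpolates each fold's curve onto a fixed 101-point FPR grid and
#' averages the TPR values, the conventional way to pool per-fold ROC
#' curves into one report.
#'
#' @param records Pooled prediction records with a `fold` column.
#' @param positive Positive class.
#' @return An `roc_curve` on the 101-point grid with the mean AUC of the
#'   folds.
#' @export
roc_average_folds <- function(records, positive = "thalassaemia") {
  grid <- seq(0, 1, length.out = 101)
  folds <- sort(unique(records$fold))
  tprs <- sapply(folds, function(f) {
    rc <- roc_auc(records[records$fold == f, , drop = FALSE], positive)
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  })
  aucs <- vapply(folds, function(f) {
    roc_auc(records[records$fold == f, , drop = FALSE], positive)$auc
  }, numeric(1))
  structure(list(fpr = grid, tpr = rowMeans(tprs), auc = mean(aucs)),
            class = "roc_curve")
}

#' Elapsed processing time per image
#'
#' `delta_te = t2 - t1`, divided by the number of images processed in the
#' batch; reported in seconds.
#'
#' @param t1,t2 Start and end times in seconds, `t2 >= t1`.
#' @param n_images Number of images processed.
#' @return Seconds per image.
#' @export
elapsed_per_image <- function(t1, t2, n_images = 1) {
  if (t2 < t1) ts_error("end time precedes start time",
                        "thalscreen_clock_error")
  if (!is_count(n_images)) {
    ts_error("n_images must be a positive integer",
             "thalscreen_parameter_error")
  }
  (t2 - t1) / n_images
}
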