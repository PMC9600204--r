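#' Training configuration
#'
#' Defaults follow the study protocol: batch size 16, learning rate 0.001,
#' at most 15 epochs, Adam optimization, learning-rate reduction after 4
#' epochs without validation-loss improvement, and early stopping after 5.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial Adam step size.
#' @param max_epochs Maximum number of epochs.
#' @param lr_patience Non-improving epochs before the learning rate is
#'   multiplied by `lr_factor`.
#' @param stop_patience Non-improving epochs before training halts.
#' @param lr_factor Learning-rate reduction factor.
#' @param seed Integer seed for weight initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16, learning_rate = 0.001,
                         max_epochs = 15, lr_patience = 4,
                         stop_patience = 5, lr_factor = 0.1, seed = 1) {
  for (v in c(batch_size, max_epochs, lr_patience, stop_patience)) {
    if (!is_count(v)) ts_error("training sizes must be positive integers",
                               "thalscreen_parameter_error")
  }
  if (learning_rate <= 0 || lr_factor <= 0 || lr_factor >= 1) {
    ts_error("invalid learning-rate settings", "thalscreen_parameter_error")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 lr_factor = lr_factor, seed = as.integer(seed)),
            class = "train_config")
}

#' Build stratified five-fold cross-validation splits
#'
#' Per class, ids are shuffled once with the seed; each fold takes a
#' contiguous rotation of `floor(n/k)` ids as its test set (so the k test
#' sets are disjoint and any remainder beyond `k * floor(n/k)` is never
#' tested), then `val_per_class` validation ids from the remaining pool,
#' and the rest for training. With 262 images per class, `k = 5` and 21
#' validation images this yields 52 test, 21 validation and 189 training
#' images per class per fold.
#'
#' @param labels Named character vector mapping sample ids to class
#'   labels.
#' @param k Number of folds.
#' @param val_per_class Validation samples per class per fold.
#' @param seed Shuffle seed.
#' @return A list of `k` fold splits, each with `fold_id`, `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_folds <- function(labels, k = 5, val_per_class, seed = 1) {
  if (!is_count(k) || k < 2) {
    ts_error("k must be an integer >= 2", "thalscreen_parameter_error")
  }
  if (is.null(names(labels))) {
    names(labels) <- as.character(seq_along(labels))
  }
  classes <- sort(unique(labels))
  per_class <- lapply(classes, function(cl) names(labels)[labels == cl])
  n_min <- min(vapply(per_class, length, integer(1)))
  if (n_min < k) {
    ts_error("need at least k samples per class", "thalscreen_parameter_error")
  }
  k <- as.integer(k)
  m <- vapply(per_class, function(ids) length(ids) %/% k, integer(1))
  if (any(vapply(per_class, length, integer(1)) - m - val_per_class <= 0)) {
    ts_error("val_per_class leaves no training samples",
             "thalscreen_parameter_error")
  }
  shuffled <- with_seed(seed, function() lapply(per_class, sample))
  lapply(seq_len(k), function(f) {
    test <- character(0); val <- character(0); train <- character(0)
    for (ci in seq_along(classes)) {
      ids <- shuffled[[ci]]
      mt <- m[ci]
      te <- ids[((f - 1) * mt + 1):(f * mt)]
      rest <- setdiff(ids, te)
      va <- rest[seq_len(val_per_class)]
      tr <- setdiff(rest, va)
      test <- c(test, te); val <- c(val, va); train <- c(train, tr)
    }
    list(fold_id = f, train_ids = train, val_ids = val, test_ids = test)
  })
}
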