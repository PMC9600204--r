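# Small convolutional classifier for 150 x 30 RGB lane crops: two 3x3
# convolution blocks (ReLU + 2x2 max pooling) and a linear softmax head.
# Forward/backward convolution and pooling run in compiled code; the Adam
# optimizer, scheduling and early stopping live here.

CLASS_LEVELS <- c("normal", "thalassaemia")

#' Classifier model specification
#'
#' Names a registered architecture. The package ships `tinycnn`, a compact
#' two-block convolutional network trained from scratch; further
#' backbones can be plugged in with [register_model()].
#'
#' @param name Architecture name.
#' @param pretrained Whether to load pretrained weights (`tinycnn` is
#'   always trained from scratch).
#' @param n_classes Number of output classes.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name = "tinycnn", pretrained = FALSE, n_classes = 2) {
  if (name == "tinycnn" && pretrained) {
    ts_error("tinycnn has no pretrained weights", "thalscreen_parameter_error")
  }
  structure(list(name = name, pretrained = pretrained,
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

model_registry <- new.env(parent = emptyenv())

#' Register a model constructor
#'
#' @param name Architecture name used in [model_spec()].
#' @param constructor Function `(spec, input_h, input_w, seed)` returning
#'   an object supporting [nn_forward()] and `nn_backward`.
#' @return `name`, invisibly.
#' @export
register_model <- function(name, constructor) {
  assign(name, constructor, envir = model_registry)
  invisible(name)
}

get_model_constructor <- function(name) {
  if (!exists(name, envir = model_registry, inherits = FALSE)) {
    ts_error(sprintf(
      "no model registered under '%s'; add one with register_model()", name),
      "thalscreen_parameter_error")
  }
  get(name, envir = model_registry, inherits = FALSE)
}

#' Initialize a tinycnn model
#'
#' Two convolution blocks (3x3 kernels, ReLU, 2x2 max pooling; 8 then 16
#' channels) followed by a linear layer and softmax over two classes.
#' Weights use He-normal initialization from the given seed.
#'
#' @param input_h,input_w Input rows and columns (the lane crop is
#'   150 x 30).
#' @param c1,c2 Channel counts of the two blocks.
#' @param n_classes Output classes.
#' @param seed Initialization seed.
#' @return A `tinycnn_model` list of weights and geometry.
#' @export
tinycnn_init <- function(input_h = 150, input_w = 30, c1 = 8, c2 = 16,
                         n_classes = 2, seed = 1) {
  h1 <- input_h %/% 2L; w1 <- input_w %/% 2L
  h2 <- h1 %/% 2L; w2 <- w1 %/% 2L
  d_flat <- h2 * w2 * c2
  with_seed(seed, function() {
    he <- function(dims, fan_in) {
      array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
    }
    structure(list(
      input_h = as.integer(input_h), input_w = as.integer(input_w),
      c1 = as.integer(c1), c2 = as.integer(c2),
      n_classes = as.integer(n_classes), d_flat = as.integer(d_flat),
      params = list(
        W1 = he(c(3, 3, 3, c1), 27),
        b1 = numeric(c1),
        W2 = he(c(3, 3, c1, c2), 9 * c1),
        b2 = numeric(c2),
        Wfc = matrix(rnorm(d_flat * n_classes, 0, sqrt(2 / d_flat)),
                     d_flat, n_classes),
        bfc = numeric(n_classes))),
      class = "tinycnn_model")
  })
}

# stack a list of H x W x 3 integer lane images into a normalized
# H x W x 3 x N double array
stack_lanes <- function(lanes) {
  d <- dim(lanes[[1]])
  x <- array(0, dim = c(d, length(lanes)))
  for (t in seq_along(lanes)) x[, , , t] <- lanes[[t]] / 255
  x
}

#' Forward pass of a tinycnn model
#'
#' @param model A `tinycnn_model`.
#' @param x Normalized input array `c(H, W, 3, N)` with values in
#'   `[0, 1]`.
#' @param keep Keep intermediate activations (needed for the backward
#'   pass and for Score-CAM).
#' @return A list with `probs` (`n_classes` x N matrix of softmax
#'   scores), `logits`, and, when `keep = TRUE`, the per-layer
#'   activations `conv1`, `pool1`, `conv2`, `pool2`.
#' @export
nn_forward <- function(model, x, keep = FALSE) {
  p <- model$params
  z1 <- .cpp_conv2d_forward(x, p$W1, p$b1)
  a1 <- pmax(z1, 0); dim(a1) <- dim(z1)
  mp1 <- .cpp_maxpool_forward(a1, 2L)
  z2 <- .cpp_conv2d_forward(mp1$out, p$W2, p$b2)
  a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
  mp2 <- .cpp_maxpool_forward(a2, 2L)
  n <- dim(x)[4]
  flat <- matrix(mp2$out, nrow = model$d_flat, ncol = n)
  logits <- crossprod(p$Wfc, flat) + p$bfc
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  out <- list(probs = probs, logits = logits)
  if (keep) {
    out$x <- x; out$conv1 <- a1; out$pool1 <- mp1; out$conv2 <- a2
    out$pool2 <- mp2; out$flat <- flat
  }
  out
}

# Backward pass: gradient of mean cross-entropy wrt all parameters.
# fw must come from nn_forward(..., keep = TRUE); y is a 1-based class
# index vector.
nn_backward <- function(model, fw, y) {
  p <- model$params
  n <- length(y)
  dlogits <- fw$probs
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  dlogits <- dlogits / n
  gWfc <- fw$flat %*% t(dlogits)
  gbfc <- rowSums(dlogits)
  dflat <- p$Wfc %*% dlogits
  dp2 <- array(dflat, dim = dim(fw$pool2$out))
  da2 <- .cpp_maxpool_backward(dp2, fw$pool2$argmax, dim(fw$conv2))
  da2 <- da2 * (fw$conv2 > 0)
  bw2 <- .cpp_conv2d_backward(fw$pool1$out, p$W2, da2)
  dp1 <- bw2$gx
  da1 <- .cpp_maxpool_backward(dp1, fw$pool1$argmax, dim(fw$conv1))
  da1 <- da1 * (fw$conv1 > 0)
  bw1 <- .cpp_conv2d_backward(fw$x, p$W1, da1)
  list(W1 = bw1$gw, b1 = bw1$gb, W2 = bw2$gw, b2 = bw2$gb,
       Wfc = gWfc, bfc = gbfc)
}

# --- early stopping / LR schedule -----------------------------------------

early_stop_state <- function() list(best = Inf, n_bad = 0L)

# Returns the updated state plus `improved`, `reduce_lr` (true exactly when
# the bad-epoch count hits a multiple of lr_patience) and `stop`.
early_stop_update <- function(state, val_loss, lr_patience, stop_patience) {
  if (val_loss < state$best - 1e-10) {
    state$best <- val_loss
    state$n_bad <- 0L
    state$improved <- TRUE
  } else {
    state$n_bad <- state$n_bad + 1L
    state$improved <- FALSE
  }
  state$reduce_lr <- state$n_bad > 0L && state$n_bad %% lr_patience == 0L
  state$stop <- state$n_bad >= stop_patience
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

eval_loss_acc <- function(model, x, y, batch = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0L
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    xb <- x[, , , s:e, drop = FALSE]
    fw <- nn_forward(model, xb)
    pr <- fw$probs[cbind(y[s:e], seq_len(e - s + 1L))]
    loss <- loss + sum(-log(pmax(pr, 1e-12)))
    correct <- correct + sum(apply(fw$probs, 2, which.max) == y[s:e])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train a tinycnn lane classifier
#'
#' Minimizes cross-entropy with Adam at the configured learning rate.
#' After each epoch the validation loss drives the schedule: the learning
#' rate is multiplied by `cfg$lr_factor` once `cfg$lr_patience`
#' consecutive epochs fail to improve it, and training halts after
#' `cfg$stop_patience` non-improving epochs or `cfg$max_epochs`. The
#' weights with the best validation loss are returned.
#'
#' @param train_lanes,train_labels Training images (list of H x W x 3
#'   arrays) and their labels (`"normal"`/`"thalassaemia"`).
#' @param val_lanes,val_labels Validation images and labels (never
#'   augmented).
#' @param cfg A [train_config()].
#' @param model Optionally, an initialized model to continue from.
#' @return A `tinycnn_fit` list: `model` (best weights), `history` (one
#'   row per epoch: losses, accuracies, learning rate), `stopped_epoch`.
#' @export
train_tinycnn <- function(train_lanes, train_labels, val_lanes, val_labels,
                          cfg = train_config(), model = NULL) {
  if (length(train_lanes) == 0L || length(val_lanes) == 0L) {
    ts_error("training and validation sets must be non-empty",
             "thalscreen_contract_error")
  }
  y_tr <- match(train_labels, CLASS_LEVELS)
  y_va <- match(val_labels, CLASS_LEVELS)
  if (anyNA(y_tr) || anyNA(y_va)) {
    ts_error("labels must be 'normal' or 'thalassaemia'",
             "thalscreen_parameter_error")
  }
  x_tr <- stack_lanes(train_lanes)
  x_va <- stack_lanes(val_lanes)
  d <- dim(x_tr)
  if (is.null(model)) {
    model <- tinycnn_init(input_h = d[1], input_w = d[2], seed = cfg$seed)
  }
  opt <- adam_init(model$params)
  es <- early_stop_state()
  lr <- cfg$learning_rate
  best_params <- model$params
  history <- vector("list", cfg$max_epochs)
  stopped <- cfg$max_epochs
  n <- d[4]
  shuffles <- with_seed(cfg$seed + 1L, function() {
    lapply(seq_len(cfg$max_epochs), function(e) sample(n))
  })
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- shuffles[[epoch]]
    for (s in seq(1L, n, by = cfg$batch_size)) {
      b <- idx[s:min(s + cfg$batch_size - 1L, n)]
      xb <- x_tr[, , , b, drop = FALSE]
      fw <- nn_forward(model, xb, keep = TRUE)
      grads <- nn_backward(model, fw, y_tr[b])
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
    }
    tr_m <- eval_loss_acc(model, x_tr, y_tr)
    va_m <- eval_loss_acc(model, x_va, y_va)
    es <- early_stop_update(es, va_m[["loss"]], cfg$lr_patience,
                            cfg$stop_patience)
    if (es$improved) best_params <- model$params
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_m[["loss"]], train_acc = tr_m[["acc"]],
      val_loss = va_m[["loss"]], val_acc = va_m[["acc"]], lr = lr)
    if (es$reduce_lr) lr <- lr * cfg$lr_factor
    if (es$stop) { stopped <- epoch; break }
  }
  model$params <- best_params
  structure(list(model = model,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          logical(1))]),
                 stopped_epoch = stopped),
            class = "tinycnn_fit")
}

#' Predict lane classes
#'
#' @param fit A `tinycnn_fit` (or a bare `tinycnn_model`).
#' @param lanes List of lane images.
#' @param ids Optional sample ids.
#' @param truth Optional true labels to carry into the records.
#' @param fold Fold id recorded with each prediction.
#' @return A data frame of prediction records: `lane_id`, `truth`,
#'   `pred`, `score` (probability of the thalassaemia class), `fold`.
#' @export
predict_lanes <- function(fit, lanes, ids = NULL, truth = NULL, fold = NA) {
  model <- if (inherits(fit, "tinycnn_fit")) fit$model else fit
  if (length(lanes) == 0L) {
    ts_error("no lanes to predict", "thalscreen_contract_error")
  }
  d <- dim(lanes[[1]])
  if (d[1] != model$input_h || d[2] != model$input_w) {
    ts_error("lane dimensions do not match the model input",
             "thalscreen_format_error")
  }
  x <- stack_lanes(lanes)
  probs <- NULL
  for (s in seq(1L, length(lanes), by = 64L)) {
    e <- min(s + 63L, length(lanes))
    fw <- nn_forward(model, x[, , , s:e, drop = FALSE])
    probs <- cbind(probs, fw$probs)
  }
  pred <- CLASS_LEVELS[apply(probs, 2, which.max)]
  data.frame(
    lane_id = if (is.null(ids)) as.character(seq_along(lanes)) else ids,
    truth = if (is.null(truth)) NA_character_ else truth,
    pred = pred,
    score = probs[2, ],
    fold = fold,
    stringsAsFactors = FALSE)
}

# register the shipped architecture
register_model("tinycnn", function(spec, input_h, input_w, seed) {
  tinycnn_init(input_h = input_h, input_w = input_w,
               n_classes = spec$n_classes, seed = seed)
})

#' Cross-validate a lane classifier
#'
#' Trains one model per fold under the five-fold protocol and pools the
#' test-set predictions, so every retained lane is tested exactly once.
#' Augmentation, when requested, is applied strictly after splitting and
#' only to the training ids; validation and test images are never
#' augmented.
#'
#' @param lanes Named list of lane images (names are sample ids).
#' @param labels Named label vector aligned with `lanes`.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()]; fold f trains with seed
#'   `cfg$seed + f`.
#' @param aug Optional [augment_spec()] applied to training images.
#' @param k Number of folds.
#' @param val_per_class Validation images per class per fold.
#' @return A `thalscreen_cv` list: pooled `records`, per-fold
#'   `histories`, `folds`, and `fits`.
#' @export
cross_validate <- function(lanes, labels, spec = model_spec("tinycnn"),
                           cfg = train_config(), aug = NULL, k = 5,
                           val_per_class = NULL) {
  if (is.null(names(lanes))) names(lanes) <- as.character(seq_along(lanes))
  if (is.null(names(labels))) names(labels) <- names(lanes)
  if (is.null(val_per_class)) {
    # ~10% of the non-test pool per class, at least 1
    n_min <- min(table(labels))
    val_per_class <- max(1L, round(0.1 * (n_min - n_min %/% k)))
  }
  folds <- make_folds(labels, k = k, val_per_class = val_per_class,
                      seed = cfg$seed)
  ctor <- get_model_constructor(spec$name)
  d <- dim(lanes[[1]])
  records <- vector("list", k)
  histories <- vector("list", k)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    tr_imgs <- lanes[fold$train_ids]
    tr_labs <- labels[fold$train_ids]
    if (!is.null(aug)) {
      aug_f <- aug
      aug_f$seed <- aug$seed + f
      tr_imgs <- augment_set(tr_imgs, aug_f, labels = tr_labs)
      tr_labs <- attr(tr_imgs, "labels")
    }
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + f
    model0 <- ctor(spec, d[1], d[2], cfg_f$seed)
    fit <- train_tinycnn(tr_imgs, tr_labs, lanes[fold$val_ids],
                         labels[fold$val_ids], cfg = cfg_f, model = model0)
    records[[f]] <- predict_lanes(fit, lanes[fold$test_ids],
                                  ids = fold$test_ids,
                                  truth = unname(labels[fold$test_ids]),
                                  fold = f)
    histories[[f]] <- fit$history
    fits[[f]] <- fit
  }
  structure(list(records = do.call(rbind, records), histories = histories,
                 folds = folds, fits = fits),
            class = "thalscreen_cv")
}
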