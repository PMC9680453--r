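# Classifier architectures and the training protocol.
#
# Five variants are constructible:
#   cnn     - per-image head on frozen features: dense(256) + ReLU +
#             dropout(0.5) + dense(5) + softmax
#   2-lstm  - two stacked unidirectional LSTM layers (128 units each), then
#             the same head applied at every time step (many-to-many)
#   bi-lstm - one bidirectional LSTM layer, 128 units per direction
#   2-gru   - two stacked unidirectional GRU layers (128 units each)
#   bi-gru  - one bidirectional GRU layer, 128 units per direction
# Loss is categorical cross-entropy averaged over valid (unmasked) steps;
# optimisation is Adam at its conventional defaults.

MODEL_VARIANTS <- c("cnn", "2-lstm", "bi-lstm", "2-gru", "bi-gru")

#' Head configuration for all classifier variants
#'
#' @param hidden_units units of the fully connected layer (default 256).
#' @param dropout_rate dropout rate between the two dense layers, applied at
#'   training time only (default 0.5).
#' @param n_classes number of output classes (5 slice levels).
#' @return A validated list of class `head_config`.
#' @export
head_config <- function(hidden_units = 256L, dropout_rate = 0.5, n_classes = 5L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  if (n_classes != 5L) stopf("the slice-level task has 5 classes")
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
            class = "head_config")
}

#' Construct the per-image classifier head
#'
#' Dense layer (256 units) + ReLU + dropout (0.5) + dense layer (5 units) +
#' softmax, on top of frozen backbone features. Predicting from the returned
#' (untrained) model already satisfies the probability contract.
#'
#' @param feature_dim length of the input feature vectors.
#' @param head a [head_config()].
#' @param seed seed for weight initialisation.
#' @return Object of class `slice_model`.
#' @export
build_cnn_head <- function(feature_dim, head = head_config(), seed = 1L) {
  build_model("cnn", feature_dim, head = head, seed = seed)
}

#' Construct a cascaded sequence classifier (CNN features + RNN)
#'
#' Builds one of the four recurrent variants on top of frozen features:
#' two-layer LSTM, bidirectional LSTM, two-layer GRU, bidirectional GRU, each
#' with 128 units per layer/direction and 25 time steps, followed by the
#' per-step classifier head. The model is many-to-many: it emits one 5-class
#' probability row per time step, and masked (padded) steps never influence
#' valid-step outputs or the loss (inputs are multiplied by the validity mask
#' before the first recurrent layer).
#'
#' @param feature_dim length of the per-slice feature vectors.
#' @param variant one of `"2-lstm"`, `"bi-lstm"`, `"2-gru"`, `"bi-gru"`.
#' @param hidden_units recurrent units per layer/direction (default 128).
#' @param time_steps sequence length (default 25, the maximum slice count).
#' @param head a [head_config()].
#' @param seed seed for weight initialisation.
#' @return Object of class `slice_model`.
#' @export
build_cnn_rnn <- function(feature_dim, variant = c("2-lstm", "bi-lstm", "2-gru", "bi-gru"),
                          hidden_units = 128L, time_steps = 25L,
                          head = head_config(), seed = 1L) {
  variant <- match.arg(variant)
  build_model(variant, feature_dim, hidden_units, time_steps, head, seed)
}

build_model <- function(variant, feature_dim, hidden_units = 128L,
                        time_steps = 25L, head = head_config(), seed = 1L) {
  stopifnot(variant %in% MODEL_VARIANTS, feature_dim >= 1L)
  D <- as.integer(feature_dim); H <- as.integer(hidden_units)
  cell <- if (grepl("lstm", variant)) "lstm" else "gru"
  init_cell <- if (cell == "lstm") init_lstm else init_gru
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    head_in <- D
    if (variant %in% c("2-lstm", "2-gru")) {
      l1 <- init_cell(D, H); l2 <- init_cell(H, H)
      p <- c(p, list(l1.Wx = l1$Wx, l1.Wh = l1$Wh, l1.b = l1$b,
                     l2.Wx = l2$Wx, l2.Wh = l2$Wh, l2.b = l2$b))
      head_in <- H
    } else if (variant %in% c("bi-lstm", "bi-gru")) {
      fw <- init_cell(D, H); bw <- init_cell(D, H)
      p <- c(p, list(fw.Wx = fw$Wx, fw.Wh = fw$Wh, fw.b = fw$b,
                     bw.Wx = bw$Wx, bw.Wh = bw$Wh, bw.b = bw$b))
      head_in <- 2L * H
    }
    d1 <- init_dense(head_in, head$hidden_units)
    d2 <- init_dense(head$hidden_units, head$n_classes)
    c(p, list(head.W1 = d1$W, head.b1 = d1$b, head.W2 = d2$W, head.b2 = d2$b))
  })
  structure(list(variant = variant, cell = if (variant == "cnn") NA_character_ else cell,
                 feature_dim = D, hidden_units = H,
                 time_steps = if (variant == "cnn") 1L else as.integer(time_steps),
                 head = head, params = params, seed = as.integer(seed)),
            class = "slice_model")
}

#' Closed-form trainable-parameter count
#'
#' Counts trainable parameters of a variant from the layer dimensions alone
#' (the frozen backbone contributes none). Used to check capacity parity
#' between the bidirectional and two-layer arrangements of the same cell.
#'
#' @inheritParams build_cnn_rnn
#' @return Integer parameter count.
#' @export
count_parameters <- function(variant, feature_dim, hidden_units = 128L,
                             head = head_config()) {
  stopifnot(variant %in% MODEL_VARIANTS)
  D <- feature_dim; H <- hidden_units
  gates <- if (grepl("lstm", variant)) 4L else 3L
  rnn <- switch(variant,
                cnn = 0,
                `2-lstm` = , `2-gru` =
                  gates * (D * H + H * H + H) + gates * (H * H + H * H + H),
                `bi-lstm` = , `bi-gru` = 2L * gates * (D * H + H * H + H))
  head_in <- switch(variant, cnn = D, `2-lstm` = , `2-gru` = H,
                    `bi-lstm` = , `bi-gru` = 2L * H)
  rnn + head_in * head$hidden_units + head$hidden_units +
    head$hidden_units * head$n_classes + head$n_classes
}

# ---- forward/backward assembly --------------------------------------------

# x: B x T x D array, mask: B x T logical/numeric. Returns list of T masked
# B x D matrices. Multiplying inputs by the mask is what guarantees padded-row
# invariance for every variant, including the reverse direction.
masked_step_list <- function(x, mask) {
  B <- dim(x)[1]; T_ <- dim(x)[2]
  lapply(seq_len(T_), function(t)
    matrix(x[, t, ], nrow = B) * mask[, t])
}

rnn_stack_forward <- function(model, X) {
  p <- model$params
  if (model$cell == "lstm") { fwd <- lstm_forward } else { fwd <- gru_forward }
  if (model$variant %in% c("2-lstm", "2-gru")) {
    l1 <- fwd(X, list(Wx = p$l1.Wx, Wh = p$l1.Wh, b = p$l1.b))
    l2 <- fwd(l1$out, list(Wx = p$l2.Wx, Wh = p$l2.Wh, b = p$l2.b))
    list(out = l2$out, cache = list(l1 = l1$cache, l2 = l2$cache))
  } else {
    fw <- fwd(X, list(Wx = p$fw.Wx, Wh = p$fw.Wh, b = p$fw.b))
    bw <- fwd(X, list(Wx = p$bw.Wx, Wh = p$bw.Wh, b = p$bw.b), reverse = TRUE)
    out <- mapply(cbind, fw$out, bw$out, SIMPLIFY = FALSE)
    list(out = out, cache = list(fw = fw$cache, bw = bw$cache))
  }
}

rnn_stack_backward <- function(model, dOut, cache) {
  p <- model$params; H <- model$hidden_units
  bwd <- if (model$cell == "lstm") lstm_backward else gru_backward
  if (model$variant %in% c("2-lstm", "2-gru")) {
    g2 <- bwd(dOut, cache$l2, list(Wx = p$l2.Wx, Wh = p$l2.Wh, b = p$l2.b))
    g1 <- bwd(g2$dX, cache$l1, list(Wx = p$l1.Wx, Wh = p$l1.Wh, b = p$l1.b))
    list(l1.Wx = g1$dWx, l1.Wh = g1$dWh, l1.b = g1$db,
         l2.Wx = g2$dWx, l2.Wh = g2$dWh, l2.b = g2$db)
  } else {
    d_fw <- lapply(dOut, function(d) d[, seq_len(H), drop = FALSE])
    d_bw <- lapply(dOut, function(d) d[, H + seq_len(H), drop = FALSE])
    gf <- bwd(d_fw, cache$fw, list(Wx = p$fw.Wx, Wh = p$fw.Wh, b = p$fw.b))
    gb <- bwd(d_bw, cache$bw, list(Wx = p$bw.Wx, Wh = p$bw.Wh, b = p$bw.b),
              reverse = TRUE)
    list(fw.Wx = gf$dWx, fw.Wh = gf$dWh, fw.b = gf$db,
         bw.Wx = gb$dWx, bw.Wh = gb$dWh, bw.b = gb$db)
  }
}

# Full forward pass. For sequence variants `x` is B x T x D and `mask` B x T;
# for the cnn variant `x` is n x D and mask is implicit. Head rows are stacked
# time-major: row (t-1)*B + b.
model_forward <- function(model, x, mask = NULL, train = FALSE) {
  p <- model$params
  if (model$variant == "cnn") {
    Hmat <- x
    rnn_cache <- NULL
    B <- nrow(x); T_ <- 1L
  } else {
    B <- dim(x)[1]; T_ <- dim(x)[2]
    if (T_ != model$time_steps)
      stopf("sequence length %d does not match the model's %d time steps",
            T_, model$time_steps)
    if (is.null(mask)) mask <- matrix(TRUE, B, T_)
    X <- masked_step_list(x, mask)
    rnn <- rnn_stack_forward(model, X)
    Hmat <- do.call(rbind, rnn$out)
    rnn_cache <- rnn$cache
  }
  Z1 <- sweep(Hmat %*% p$head.W1, 2L, p$head.b1, "+")
  A1 <- pmax(Z1, 0)
  drop_mask <- NULL
  if (train && model$head$dropout_rate > 0) {
    keep <- 1 - model$head$dropout_rate
    drop_mask <- matrix(stats::runif(length(A1)) < keep, nrow(A1), ncol(A1)) / keep
    A1 <- A1 * drop_mask
  }
  logits <- sweep(A1 %*% p$head.W2, 2L, p$head.b2, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, B = B, T_ = T_,
       cache = list(Hmat = Hmat, Z1 = Z1, A1 = A1, drop_mask = drop_mask,
                    rnn = rnn_cache))
}

model_backward <- function(model, fwd, dlogits) {
  p <- model$params; cc <- fwd$cache
  dW2 <- crossprod(cc$A1, dlogits)
  db2 <- colSums(dlogits)
  dA1 <- tcrossprod(dlogits, p$head.W2)
  if (!is.null(cc$drop_mask)) dA1 <- dA1 * cc$drop_mask
  dZ1 <- dA1 * (cc$Z1 > 0)
  dW1 <- crossprod(cc$Hmat, dZ1)
  db1 <- colSums(dZ1)
  grads <- list(head.W1 = dW1, head.b1 = db1, head.W2 = dW2, head.b2 = db2)
  if (model$variant != "cnn") {
    dHmat <- tcrossprod(dZ1, p$head.W1)
    B <- fwd$B
    dOut <- lapply(seq_len(fwd$T_), function(t)
      dHmat[(t - 1L) * B + seq_len(B), , drop = FALSE])
    grads <- c(grads, rnn_stack_backward(model, dOut, cc$rnn))
  }
  grads[names(model$params)]
}

batch_loss <- function(model, batch, train = FALSE) {
  if (model$variant == "cnn") {
    fwd <- model_forward(model, batch$x, train = train)
    y <- batch$y; w <- rep(1, length(y))
  } else {
    fwd <- model_forward(model, batch$x, batch$mask, train = train)
    # head rows are stacked time-major, row (t-1)*B + b, which is exactly the
    # column-major flattening of the B x T label/mask matrices
    y <- as.integer(batch$y)
    w <- as.numeric(batch$mask)
  }
  ce <- masked_ce(fwd$probs, y, w)
  if (!is.finite(ce$loss)) stopf("non-finite loss; aborting (check inputs/learning rate)")
  acc <- {
    pred <- max.col(fwd$probs, ties.method = "first") - 1L
    ok <- w > 0
    mean(pred[ok] == y[ok])
  }
  list(fwd = fwd, loss = ce$loss, dlogits = ce$dlogits, accuracy = acc, n_valid = sum(w))
}

#' Fit a slice-level classifier
#'
#' Trains one model variant with Adam (conventional default rates) on masked
#' categorical cross-entropy, recording per-epoch training and validation
#' loss and accuracy, and keeping the weights of the best-validation-loss
#' epoch (earliest on ties) alongside the final weights. Default batch sizes
#' follow the study protocol: 32 for the per-image head, 2 for the sequence
#' models; the default epoch budget is 50.
#'
#' For sequence variants, `train` and `val` are lists of
#' [build_sequences()] objects (or prebuilt `list(x, mask, y)` batches). For
#' the `cnn` variant they are `list(x = <n x D matrix>, y = <ordinals>)`.
#'
#' @param train,val training and validation data (see Details).
#' @param variant one of `"cnn"`, `"2-lstm"`, `"bi-lstm"`, `"2-gru"`,
#'   `"bi-gru"`.
#' @param epochs number of epochs (default 50).
#' @param batch_size minibatch size; default 32 for `cnn`, 2 otherwise.
#' @param learning_rate Adam step size (default 1e-3).
#' @param hidden_units recurrent units per layer/direction.
#' @param time_steps sequence length (default 25).
#' @param head a [head_config()].
#' @param seed seed controlling initialisation, shuffling and dropout; the
#'   same seed reproduces the history exactly.
#' @param model optionally a prebuilt [build_cnn_rnn()]/[build_cnn_head()]
#'   model to train (overrides `variant`).
#' @param verbose print per-epoch progress.
#' @return Object of class `slice_fit`: the trained model (best-epoch
#'   weights), `final_params`, `history` (data frame with epoch, loss,
#'   accuracy, val_loss, val_accuracy), `selected_epoch` and the training
#'   configuration. Methods: `print`, `summary`, `predict`, `plot`, `coef`.
#' @export
fit_slice_model <- function(train, val, variant = MODEL_VARIANTS,
                            epochs = 50L, batch_size = NULL,
                            learning_rate = 1e-3, hidden_units = 128L,
                            time_steps = 25L, head = head_config(), seed = 1L,
                            model = NULL, verbose = FALSE) {
  variant <- match.arg(variant)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stopf("epochs must be >= 1")
  tr <- coerce_training_data(train, variant)
  va <- coerce_training_data(val, variant)
  n_train <- if (variant == "cnn") nrow(tr$x) else dim(tr$x)[1]
  n_val <- if (variant == "cnn") nrow(va$x) else dim(va$x)[1]
  if (n_train == 0L || n_val == 0L) stopf("empty training or validation set")
  if (is.null(batch_size)) batch_size <- if (variant == "cnn") 32L else 2L
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (is.null(model)) {
    D <- if (variant == "cnn") ncol(tr$x) else dim(tr$x)[3]
    model <- if (variant == "cnn")
      build_cnn_head(D, head, seed = derive_seed(seed, 1))
    else
      build_cnn_rnn(D, variant, hidden_units, time_steps, head,
                    seed = derive_seed(seed, 1))
  }
  stopifnot(inherits(model, "slice_model"), model$variant == variant)

  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL)
  opt <- adam_init(model$params)

  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample(n_train)
      ep_loss <- 0; ep_acc <- 0; ep_n <- 0
      for (start in seq(1L, n_train, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, n_train)]
        bl <- batch_loss(model, slice_batch(tr, take, variant), train = TRUE)
        grads <- model_backward(model, bl$fwd, bl$dlogits)
        upd <- adam_step(model$params, grads, opt, lr = learning_rate)
        model$params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + bl$loss * bl$n_valid
        ep_acc <- ep_acc + bl$accuracy * bl$n_valid
        ep_n <- ep_n + bl$n_valid
      }
      vl <- batch_loss(model, va, train = FALSE)
      history[ep, ] <- list(ep, ep_loss / ep_n, ep_acc / ep_n, vl$loss, vl$accuracy)
      if (vl$loss < best$loss) {
        best$loss <- vl$loss; best$epoch <- ep; best$params <- model$params
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                        ep, history$loss[ep], history$accuracy[ep], vl$loss, vl$accuracy))
    }
  })

  final_params <- model$params
  model$params <- best$params
  structure(list(model = model, variant = variant, history = history,
                 selected_epoch = select_epoch(history),
                 final_params = final_params,
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate, seed = as.integer(seed))),
            class = "slice_fit")
}

coerce_training_data <- function(data, variant) {
  if (variant == "cnn") {
    stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
    list(x = data$x, y = as.integer(data$y))
  } else if (is.list(data) && !is.null(data$x) && length(dim(data$x)) == 3L) {
    data
  } else {
    sequence_batch(data)
  }
}

slice_batch <- function(data, take, variant) {
  if (variant == "cnn")
    list(x = data$x[take, , drop = FALSE], y = data$y[take])
  else
    list(x = data$x[take, , , drop = FALSE],
         mask = data$mask[take, , drop = FALSE],
         y = data$y[take, , drop = FALSE])
}

#' Select the reporting epoch from a training history
#'
#' Returns the epoch with minimal validation loss; ties are broken toward the
#' earliest epoch. This automates the protocol of choosing the epoch where
#' the validation loss curve is near its minimum.
#'
#' @param history data frame with a `val_loss` column (one row per epoch), or
#'   a numeric vector of validation losses.
#' @return 1-based epoch index.
#' @export
select_epoch <- function(history) {
  v <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  if (!length(v)) stopf("empty history")
  which.min(v)  # which.min returns the first (earliest) minimum
}

#' Predict per-slice labels for one stack
#'
#' Runs the many-to-many forward pass on a feature sequence and returns the
#' argmax label of each valid step (argmax ties resolve to the lowest class
#' ordinal). Masked steps are excluded from the outputs.
#'
#' @param object a `slice_fit` or `slice_model` (sequence variant).
#' @param sequence a [build_sequences()] object.
#' @return List with `ordinals`, `labels` (tokens) for the valid steps and
#'   `probs`, the `n x 5` probability matrix over valid steps.
#' @export
predict_stack <- function(object, sequence) {
  model <- if (inherits(object, "slice_fit")) object$model else object
  stopifnot(inherits(model, "slice_model"), inherits(sequence, "feature_sequence"))
  if (model$variant == "cnn") {
    probs <- model_forward(model, sequence$x[sequence$mask, , drop = FALSE])$probs
  } else {
    b <- sequence_batch(list(sequence))
    fwd <- model_forward(model, b$x, b$mask)
    probs <- fwd$probs[as.vector(b$mask), , drop = FALSE]  # time-major, B = 1
  }
  ord <- max.col(probs, ties.method = "first") - 1L
  colnames(probs) <- label_levels()
  list(ordinals = ord, labels = ordinal_to_label(ord), probs = probs)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.slice_model <- function(x, ...) {
  cat(sprintf("Slice-level classifier '%s': %d features -> %s -> dense(%d)+dropout(%.1f) -> 5-class softmax\n",
              x$variant, x$feature_dim,
              if (x$variant == "cnn") "(per image)" else
                sprintf("%s(%d units, %d steps)", x$variant, x$hidden_units, x$time_steps),
              x$head$hidden_units, x$head$dropout_rate))
  cat(sprintf("  trainable parameters: %d\n",
              sum(vapply(x$params, length, 1L))))
  invisible(x)
}

#' @export
print.slice_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  trained %d epochs (batch %d); selected epoch %d (val loss %.4f, val acc %.3f)\n",
              nrow(x$history), x$config$batch_size, x$selected_epoch,
              x$history$val_loss[x$selected_epoch],
              x$history$val_accuracy[x$selected_epoch]))
  invisible(x)
}

#' @export
summary.slice_fit <- function(object, ...) {
  h <- object$history
  out <- list(variant = object$variant, epochs = nrow(h),
              selected_epoch = object$selected_epoch,
              best_val_loss = h$val_loss[object$selected_epoch],
              best_val_accuracy = h$val_accuracy[object$selected_epoch],
              final_train_loss = h$loss[nrow(h)],
              final_train_accuracy = h$accuracy[nrow(h)],
              n_parameters = sum(vapply(object$model$params, length, 1L)))
  class(out) <- "summary.slice_fit"
  out
}

#' @export
print.summary.slice_fit <- function(x, ...) {
  cat(sprintf("Variant %s: %d parameters, %d epochs\n", x$variant, x$n_parameters, x$epochs))
  cat(sprintf("  selected epoch %d: val loss %.4f, val accuracy %.3f\n",
              x$selected_epoch, x$best_val_loss, x$best_val_accuracy))
  cat(sprintf("  final train loss %.4f, train accuracy %.3f\n",
              x$final_train_loss, x$final_train_accuracy))
  invisible(x)
}

#' @export
coef.slice_fit <- function(object, ...) object$model$params

#' Plot learning curves of a fitted classifier
#'
#' Two panels: loss and accuracy, training and validation, with the selected
#' epoch marked.
#'
#' @param x a `slice_fit`.
#' @param ... passed to `matplot`.
#' @export
plot.slice_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch", ylab = "loss",
                    main = sprintf("%s learning curves", x$variant), ...)
  graphics::abline(v = x$selected_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), col = c("black", "red"), lty = 1)
  graphics::matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch", ylab = "accuracy", ...)
  graphics::abline(v = x$selected_epoch, lty = 3)
  invisible(x)
}

#' Predict method for fitted slice classifiers
#'
#' @param object a `slice_fit`.
#' @param newdata a `feature_sequence`, a list of them, or (for the `cnn`
#'   variant) a feature matrix.
#' @param type `"class"` for ordinal labels, `"prob"` for probability rows.
#' @param ... unused.
#' @return For a single sequence, the [predict_stack()] result; for a list, a
#'   list of such results; for a matrix, a vector of ordinals or a
#'   probability matrix.
#' @export
predict.slice_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_sequence")) {
    out <- predict_stack(object, newdata)
    return(if (type == "prob") out$probs else out$ordinals)
  }
  if (is.list(newdata) && all(vapply(newdata, inherits, TRUE, "feature_sequence")))
    return(lapply(newdata, function(s) predict.slice_fit(object, s, type)))
  if (is.matrix(newdata)) {
    probs <- model_forward(object$model, newdata)$probs
    colnames(probs) <- label_levels()
    return(if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L)
  }
  stopf("unsupported newdata type")
}
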