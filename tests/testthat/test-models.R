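# The analytic gradients are the load-bearing part of the training code, so
# every variant is checked against central finite differences on small
# dimensions before anything else relies on them.

variant_batch <- function(variant, D = 3L, T_ = 5L) {
  if (variant == "cnn")
    withr::with_seed(11, list(x = matrix(rnorm(2 * D), 2, D), y = c(0L, 3L)))
  else
    withr::with_seed(11, list(
      x = array(rnorm(2 * T_ * D), dim = c(2, T_, D)),
      mask = rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE), rep(TRUE, T_)),
      y = rbind(c(0L, 1L, 2L, NA, NA), c(0L, 2L, 3L, 4L, 4L))))
}

test_that("analytic gradients match finite differences for every variant", {
  ns <- asNamespace("saxlevel")
  for (variant in c("cnn", "2-lstm", "bi-lstm", "2-gru", "bi-gru")) {
    m <- ns$build_model(variant, 3L, hidden_units = 4L, time_steps = 5L,
                        head = head_config(hidden_units = 6L, dropout_rate = 0),
                        seed = 9)
    batch <- variant_batch(variant)
    bl <- ns$batch_loss(m, batch)
    g <- ns$model_backward(m, bl$fwd, bl$dlogits)
    eps <- 1e-5
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      picks <- withr::with_seed(13, sample(length(p), min(5, length(p))))
      for (k in picks) {
        m2 <- m
        m2$params[[nm]][k] <- p[k] + eps
        lp <- ns$batch_loss(m2, batch)$loss
        m2$params[[nm]][k] <- p[k] - eps
        lm <- ns$batch_loss(m2, batch)$loss
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[[nm]][k]) / max(1e-6, abs(num) + abs(g[[nm]][k])),
                  1e-5, label = sprintf("%s grad %s[%d]", variant, nm, k))
      }
    }
  }
})

test_that("every emitted class distribution sums to one", {
  fs <- random_sequence(12, d = 8, seed = 21)
  for (variant in c("2-lstm", "bi-lstm", "2-gru", "bi-gru")) {
    m <- build_cnn_rnn(8, variant, hidden_units = 16, seed = 2)
    p <- predict_stack(m, fs)
    expect_equal(nrow(p$probs), 12)
    expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6))
    expect_true(all(p$probs >= 0))
  }
  head_m <- build_cnn_head(8, seed = 2)
  probs <- predict(structure(list(model = head_m), class = "slice_fit"),
                   matrix(rnorm(40), 5, 8), type = "prob")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})

test_that("closed-form parameter counts equal the materialised parameters", {
  for (variant in c("cnn", "2-lstm", "bi-lstm", "2-gru", "bi-gru"))
    for (D in c(16L, 64L)) {
      m <- saxlevel:::build_model(variant, D, hidden_units = 32L, seed = 1)
      expect_equal(count_parameters(variant, D, 32L),
                   sum(vapply(m$params, length, 1L)),
                   label = sprintf("%s at D=%d", variant, D))
    }
  # the per-image head on 1024 features: two dense layers
  expect_equal(count_parameters("cnn", 1024L),
               1024 * 256 + 256 + 256 * 5 + 5)
})

test_that("bidirectional and two-layer arrangements have near-equal capacity", {
  D <- backbone_spec("TinyTest")$feature_dim
  for (cell in c("lstm", "gru")) {
    two <- count_parameters(sprintf("2-%s", cell), D)
    bi <- count_parameters(sprintf("bi-%s", cell), D)
    expect_lt(abs(two - bi) / max(two, bi), 0.15)
  }
})

test_that("padded-row content cannot influence loss or valid-step predictions", {
  ns <- asNamespace("saxlevel")
  fs <- random_sequence(8, d = 6, seed = 31)
  for (variant in c("2-lstm", "bi-lstm", "2-gru", "bi-gru")) {
    m <- build_cnn_rnn(6, variant, hidden_units = 8, seed = 3)
    base <- predict_stack(m, fs)
    perturbed <- fs
    perturbed$x[!fs$mask, ] <- withr::with_seed(32, rnorm(sum(!fs$mask) * 6, 0, 50))
    alt <- predict_stack(m, perturbed)
    expect_lt(max(abs(base$probs - alt$probs)), 1e-6)
    b1 <- ns$batch_loss(m, ns$sequence_batch(list(fs)))
    b2 <- ns$batch_loss(m, ns$sequence_batch(list(perturbed)))
    expect_lt(abs(b1$loss - b2$loss), 1e-12)
  }
})

test_that("only bidirectional variants propagate late-slice evidence backward", {
  fs <- random_sequence(10, d = 6, seed = 41)
  flipped <- fs
  flipped$x[9, ] <- -5 * flipped$x[9, ]  # a late valid slice
  for (variant in c("2-lstm", "2-gru")) {
    m <- build_cnn_rnn(6, variant, hidden_units = 8, seed = 4)
    expect_equal(predict_stack(m, fs)$probs[1:3, ],
                 predict_stack(m, flipped)$probs[1:3, ], tolerance = 1e-12)
  }
  for (variant in c("bi-lstm", "bi-gru")) {
    m <- build_cnn_rnn(6, variant, hidden_units = 8, seed = 4)
    expect_gt(max(abs(predict_stack(m, fs)$probs[1:3, ] -
                      predict_stack(m, flipped)$probs[1:3, ])), 1e-8)
  }
})

test_that("epoch selection takes the earliest validation-loss minimum", {
  expect_equal(select_epoch(c(0.9, 0.5, 0.7)), 2L)  # 1-based indexing
  expect_equal(select_epoch(c(0.5, 0.5)), 1L)
  expect_equal(select_epoch(c(0.9, 0.7, 0.5, 0.3)), 4L)
  h <- data.frame(epoch = 1:3, val_loss = c(1, 0.2, 0.4))
  expect_equal(select_epoch(h), 2L)
})

test_that("argmax prediction resolves ties toward the lower ordinal", {
  fs <- random_sequence(4, d = 6, seed = 51)
  m <- build_cnn_rnn(6, "2-gru", hidden_units = 8, seed = 5)
  # zero head weights give exactly uniform rows: all ties resolve to oap
  m$params$head.W1[] <- 0; m$params$head.b1[] <- 0
  m$params$head.W2[] <- 0; m$params$head.b2[] <- 0
  p <- predict_stack(m, fs)
  expect_true(all(p$probs == 0.2))
  expect_true(all(p$ordinals == 0L))
  expect_true(all(p$labels == "oap"))
  expect_length(p$ordinals, 4)
})

test_that("training learns a separable task and honours the epoch contract", {
  # features linearly separable by class: training loss must fall
  make_set <- function(n, seed) withr::with_seed(seed, {
    y <- sample(0:4, n, TRUE)
    x <- matrix(rnorm(n * 10, 0, 0.3), n, 10)
    for (i in seq_len(n)) x[i, y[i] + 1] <- x[i, y[i] + 1] + 2
    list(x = x, y = y)
  })
  fit <- fit_slice_model(make_set(120, 1), make_set(40, 2), "cnn",
                         epochs = 6, seed = 7)
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_lt(h$loss[6], h$loss[1])
  expect_gt(h$accuracy[6], 0.2)
  expect_true(all(is.finite(unlist(h[-1]))))

  one <- fit_slice_model(make_set(40, 3), make_set(20, 4), "cnn",
                         epochs = 1, seed = 7)
  expect_equal(nrow(one$history), 1)
})

test_that("training is reproducible under a fixed seed", {
  seqs <- lapply(1:6, function(i) random_sequence(6 + i, d = 6, seed = 60 + i))
  a <- fit_slice_model(seqs[1:4], seqs[5:6], "2-gru", epochs = 2,
                       hidden_units = 8, seed = 99)
  b <- fit_slice_model(seqs[1:4], seqs[5:6], "2-gru", epochs = 2,
                       hidden_units = 8, seed = 99)
  expect_identical(a$history, b$history)
  expect_identical(coef(a), coef(b))
  c <- fit_slice_model(seqs[1:4], seqs[5:6], "2-gru", epochs = 2,
                       hidden_units = 8, seed = 100)
  expect_false(identical(a$history, c$history))
})

test_that("fit objects expose the classic accessor methods", {
  seqs <- lapply(1:4, function(i) random_sequence(5 + i, d = 6, seed = 70 + i))
  fit <- fit_slice_model(seqs[1:3], seqs[4], "bi-gru", epochs = 2,
                         hidden_units = 8, seed = 1)
  expect_s3_class(fit, "slice_fit")
  expect_named(fit$history, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))
  expect_output(print(fit), "bi-gru")
  s <- summary(fit)
  expect_output(print(s), "selected epoch")
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  preds <- predict(fit, seqs[[4]])
  expect_length(preds, seqs[[4]]$n)
})
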