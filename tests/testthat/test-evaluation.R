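# Independent oracles: explicit nested loops for counting statistics, the
# pairwise-comparison definition for AUC. The implementation never shares
# code with these.

brute_confusion <- function(true, pred, k = 5L) {
  cm <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cm[i, j] <- sum(true == i - 1L & pred == j - 1L)
  cm
}

brute_sotd <- function(cm) {
  s <- 0
  for (i in 1:nrow(cm)) for (j in 1:ncol(cm))
    if (abs(i - j) >= 2) s <- s + cm[i, j]
  s
}

# AUC by counting pairwise comparisons (ties count half)
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

test_that("confusion matrix equals the brute-force nested count", {
  for (s in 1:10) {
    labs <- withr::with_seed(s, list(t = sample(0:4, 200, TRUE),
                                     p = sample(0:4, 200, TRUE)))
    cm <- confusion_matrix(labs$t, labs$p)
    expect_identical(unname(unclass(cm)), brute_confusion(labs$t, labs$p))
    expect_equal(sum(cm), 200)
  }
  diag_cm <- confusion_matrix(c(0, 1, 1, 4), c(0, 1, 1, 4))
  expect_equal(unname(diag(diag_cm)), c(1, 2, 0, 0, 1))
  expect_true(all(diag_cm[upper.tri(diag_cm) | lower.tri(diag_cm)] == 0))
  expect_true(all(confusion_matrix(integer(0), integer(0)) == 0))
  expect_error(confusion_matrix(c(0, 5), c(0, 0)), "ordinals")
})

test_that("one-vs-rest scores follow the precision/recall/F1 formulas", {
  perfect <- confusion_matrix(rep(0:4, 3), rep(0:4, 3))
  for (c in 0:4)
    expect_equal(unname(one_vs_rest_scores(perfect, c)), c(1, 1, 1))
  # TP = 3, FP = 1, FN = 1 for class mid
  cm <- matrix(0L, 5, 5)
  cm[3, 3] <- 3L; cm[2, 3] <- 1L; cm[3, 2] <- 1L
  expect_equal(unname(one_vs_rest_scores(cm, 2L)), c(0.75, 0.75, 0.75))
  # class absent from truth and predictions
  absent <- confusion_matrix(c(0, 1, 1), c(0, 1, 1))
  w <- capture_warnings(sc <- one_vs_rest_scores(absent, 4L))
  expect_length(w, 2)  # precision and recall are both degenerate
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(unname(sc), c(0, 0, 0))
})

test_that("accuracy is trace over total and permutation invariant", {
  expect_equal(accuracy(confusion_matrix(0:4, 0:4)), 1)
  expect_equal(accuracy(matrix(1L, 5, 5)), 0.2)
  for (s in 1:10) {
    cm <- random_cm(s)
    expect_equal(accuracy(cm), sum(diag(cm)) / sum(cm))
    perm <- withr::with_seed(s, sample(5))
    expect_equal(accuracy(cm[perm, perm]), accuracy(cm))
  }
  expect_error(accuracy(matrix(0L, 5, 5)), "empty")
})

test_that("weighted AUC agrees with the pairwise-comparison oracle", {
  for (s in 1:10) {
    dat <- withr::with_seed(s, {
      true <- sample(0:4, 50, TRUE)
      raw <- matrix(runif(50 * 5), 50, 5)
      list(true = true, probs = raw / rowSums(raw))
    })
    got <- weighted_auc(dat$true, dat$probs)
    present <- sort(unique(dat$true))
    oracle <- sum(vapply(present, function(c)
      pairwise_auc(dat$probs[, c + 1], dat$true == c) * sum(dat$true == c), 0)) /
      length(dat$true)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("weighted AUC hits the perfect and uninformative anchors", {
  true <- rep(0:4, each = 4)
  perfect <- diag(5)[true + 1, ] * 0.95 + 0.01
  expect_equal(weighted_auc(true, perfect), 1)
  flat <- matrix(0.2, 20, 5)
  expect_equal(weighted_auc(true, flat), 0.5)
  expect_error(weighted_auc(rep(2L, 8), matrix(0.2, 8, 5)), "single class")
  expect_warning(weighted_auc(c(0, 0, 1, 1), matrix(0.2, 4, 5)), "absent")
})

test_that("weighted AUC matches an external ROC implementation", {
  skip_if_not_installed("pROC")
  dat <- withr::with_seed(77, {
    true <- sample(0:2, 60, TRUE)  # three classes present
    raw <- matrix(runif(60 * 5), 60, 5)
    list(true = true, probs = raw / rowSums(raw))
  })
  got <- suppressWarnings(weighted_auc(dat$true, dat$probs))
  ref <- sum(vapply(0:2, function(c) {
    r <- pROC::roc(dat$true == c, dat$probs[, c + 1], quiet = TRUE,
                   direction = "<")
    as.numeric(pROC::auc(r)) * sum(dat$true == c)
  }, 0)) / length(dat$true)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("SOTD equals the brute-force band sum and its edge anchors", {
  expect_equal(sotd(diag(5L) * 3L), 0)
  tri <- matrix(0L, 5, 5)
  tri[abs(row(tri) - col(tri)) <= 1] <- 7L
  expect_equal(sotd(tri), 0)
  for (s in 1:20) {
    cm <- random_cm(s)
    expect_equal(sotd(cm), brute_sotd(cm))
    expect_gte(sotd(cm), 0)
    expect_lte(sotd(cm), sum(cm))
  }
})

test_that("three-class merge matches the relabel-and-recount oracle", {
  merge_oracle <- function(cm) {
    # expand to labels, remap {1,2,3} -> in, recount
    g <- c(1L, 2L, 2L, 2L, 3L)
    out <- matrix(0L, 3, 3)
    for (i in 1:5) for (j in 1:5) out[g[i], g[j]] <- out[g[i], g[j]] + cm[i, j]
    out
  }
  perfect <- confusion_matrix(rep(0:4, 2), rep(0:4, 2))
  expect_equal(merge_to_three_class(perfect)$error_rate, 0)
  # confusions entirely inside ap/mid/bs vanish
  inner <- matrix(0L, 5, 5)
  inner[2:4, 2:4] <- 3L
  expect_equal(merge_to_three_class(inner)$error_rate, 0)
  for (s in 1:20) {
    cm <- random_cm(s + 100)
    m <- merge_to_three_class(cm)
    expect_identical(unname(unclass(m$cm3)), merge_oracle(cm))
    expect_equal(sum(m$cm3), sum(cm))
    expect_lte(m$error_rate, 1 - accuracy(cm))
  }
})

test_that("the pooled evaluation report is consistent and conserves counts", {
  dat <- withr::with_seed(9, {
    true <- sample(0:4, 120, TRUE)
    raw <- matrix(runif(120 * 5), 120, 5)
    list(true = true, pred = sample(0:4, 120, TRUE), probs = raw / rowSums(raw))
  })
  rep_ <- evaluate_predictions(dat$true, dat$pred, dat$probs)
  expect_equal(rep_$n, 120)
  expect_equal(sum(rep_$cm), 120)
  expect_equal(sum(rep_$per_class$support), 120)
  expect_true(all(rep_$per_class$f1 >= 0 & rep_$per_class$f1 <= 1))
  expect_gte(rep_$accuracy, 0); expect_lte(rep_$accuracy, 1)
  expect_output(print(rep_), "SOTD")

  ideal <- evaluate_predictions(dat$true, dat$true, diag(5)[dat$true + 1, ] * 0.95 + 0.01)
  expect_equal(ideal$accuracy, 1)
  expect_equal(ideal$sotd, 0)
  expect_equal(ideal$weighted_auc, 1)
  expect_true(all(ideal$per_class$f1 == 1))
  expect_equal(ideal$merged$error_rate, 0)
})
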