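# Evaluation suite: confusion matrix, one-vs-rest precision/recall/F1,
# accuracy, support-weighted one-vs-rest AUC, SOTD, and the merged
# three-class error rate.
#
# Convention throughout: rows of the confusion matrix are the true class
# ordinal, columns the predicted class ordinal, in the fixed order
# oap < ap < mid < bs < obs.

#' Five-class confusion matrix
#'
#' `counts[i, j]` is the number of slices with true ordinal `i - 1` predicted
#' as ordinal `j - 1`.
#'
#' @param true,predicted equal-length integer vectors of class ordinals 0..4.
#' @param n_classes number of classes (default 5).
#' @return Integer `n_classes x n_classes` matrix with class-token dimnames.
#' @export
confusion_matrix <- function(true, predicted, n_classes = 5L) {
  if (length(true) != length(predicted)) stopf("label vectors differ in length")
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) && (min(true, predicted) < 0L || max(true, predicted) >= n_classes))
    stopf("ordinals must lie in 0..%d", n_classes - 1L)
  cm <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(true))
    cm[true[k] + 1L, predicted[k] + 1L] <- cm[true[k] + 1L, predicted[k] + 1L] + 1L
  if (n_classes == 5L) dimnames(cm) <- list(true = label_levels(), predicted = label_levels())
  cm
}

#' One-vs-rest precision, recall and F1 for one class
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean. A zero denominator (class absent from truth and/or predictions)
#' yields 0 with a warning.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param class class ordinal 0..4 (or token).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
one_vs_rest_scores <- function(cm, class) {
  if (is.character(class)) class <- label_to_ordinal(class)
  i <- class + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %s (zero denominator); returning 0",
                      what, rownames(cm)[i] %||% as.character(class)), call. = FALSE)
      0
    } else num / den
  }
  p <- safe(tp, tp + fp, "precision")
  r <- safe(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Per-class one-vs-rest scores for all classes
#'
#' @param cm confusion matrix.
#' @return Data frame with one row per class: `class`, `support`,
#'   `precision`, `recall`, `f1`.
#' @export
class_scores <- function(cm) {
  k <- nrow(cm)
  out <- do.call(rbind, lapply(seq_len(k) - 1L, function(c)
    as.data.frame(as.list(one_vs_rest_scores(cm, c)))))
  data.frame(class = rownames(cm) %||% as.character(seq_len(k) - 1L),
             support = rowSums(cm), out, row.names = NULL)
}

#' Overall accuracy from a confusion matrix
#'
#' Correctly predicted cases divided by all cases (trace over total).
#'
#' @param cm confusion matrix with at least one count.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  sum(diag(cm)) / total
}

# One-vs-rest AUC for scores `s` against binary truth, by the rank statistic
# (equivalent to the normalised Mann-Whitney U; ties get average rank).
binary_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Support-weighted one-vs-rest AUC
#'
#' For each class present in the truth, computes the one-vs-rest AUC of its
#' probability column (rank statistic, average ranks on ties), then averages
#' with weights proportional to class support. Classes absent from the truth
#' are excluded from the average with a warning; a single-class truth is an
#' error, since AUC is undefined.
#'
#' @param true integer ordinals 0..4.
#' @param probs `n x 5` matrix of class probabilities (rows sum to 1).
#' @return Weighted AUC in `[0, 1]`.
#' @export
weighted_auc <- function(true, probs) {
  true <- as.integer(true)
  stopifnot(is.matrix(probs), nrow(probs) == length(true))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stopf("probability rows must sum to 1")
  present <- sort(unique(true))
  if (length(present) < 2L)
    stopf("AUC is undefined: the truth contains a single class")
  all_classes <- seq_len(ncol(probs)) - 1L
  absent <- setdiff(all_classes, present)
  if (length(absent))
    warning(sprintf("class(es) %s absent from truth; excluded from the weighted AUC",
                    paste(absent, collapse = ", ")), call. = FALSE)
  aucs <- vapply(present, function(c) binary_auc(probs[, c + 1L], true == c), 0)
  support <- vapply(present, function(c) sum(true == c), 0)
  sum(aucs * support) / sum(support)
}

#' SOTD: sum of confusion-matrix entries outside the tridiagonal band
#'
#' Counts predictions that miss the true level by two or more ordinal steps:
#' the sum of `counts[i, j]` over all `|i - j| >= 2`. Entries on the diagonal
#' and the two first off-diagonals (the tridiagonal band, confusions between
#' adjacent levels) do not count. Lower is better; 0 means every error, if
#' any, confused adjacent levels only.
#'
#' @param cm square confusion matrix (rows true, columns predicted).
#' @return Non-negative integer.
#' @export
sotd <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  idx <- abs(row(cm) - col(cm)) >= 2L
  sum(cm[idx])
}

#' Merge the three in-ventricle levels and recompute the error rate
#'
#' Merges `ap`, `mid` and `bs` into a single `in` class, producing a 3x3
#' confusion matrix over `{oap, in, obs}`, and returns its error rate
#' (1 - trace/total). Confusions inside the merged group vanish, so the
#' merged error rate is never larger than the five-class error rate.
#'
#' @param cm 5x5 confusion matrix.
#' @return List with `cm3` (3x3 integer matrix) and `error_rate`.
#' @export
merge_to_three_class <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 5L))
  groups <- c(1L, 2L, 2L, 2L, 3L)  # oap | ap+mid+bs | obs
  cm3 <- matrix(0L, 3L, 3L, dimnames = list(true = c("oap", "in", "obs"),
                                            predicted = c("oap", "in", "obs")))
  for (i in 1:5) for (j in 1:5)
    cm3[groups[i], groups[j]] <- cm3[groups[i], groups[j]] + cm[i, j]
  list(cm3 = cm3, error_rate = 1 - sum(diag(cm3)) / sum(cm3))
}

#' Full evaluation report over pooled test predictions
#'
#' Pools all valid slices into one confusion matrix and derives per-class
#' one-vs-rest precision/recall/F1, support-weighted AUC, accuracy, SOTD and
#' the merged three-class error rate.
#'
#' @param true integer ordinals of all valid test slices.
#' @param predicted integer ordinals predicted for the same slices.
#' @param probs optional `n x 5` probability matrix (required for AUC).
#' @return Object of class `slice_eval` with fields `cm`, `per_class`,
#'   `accuracy`, `weighted_auc` (or `NA` when `probs` is missing), `sotd`,
#'   `merged` and `n`.
#' @export
evaluate_predictions <- function(true, predicted, probs = NULL) {
  if (length(true) != length(predicted)) stopf("label vectors differ in length")
  if (!length(true)) stopf("no predictions to evaluate")
  cm <- confusion_matrix(true, predicted)
  structure(list(
    cm = cm,
    per_class = class_scores(cm),
    accuracy = accuracy(cm),
    weighted_auc = if (is.null(probs)) NA_real_ else weighted_auc(true, probs),
    sotd = sotd(cm),
    merged = merge_to_three_class(cm),
    n = length(true)), class = "slice_eval")
}

#' @export
print.slice_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Slice-level evaluation over %d slices\n", x$n))
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("accuracy %.3f | weighted AUC %s | SOTD %d | merged 3-class error %.3f\n",
              x$accuracy,
              if (is.na(x$weighted_auc)) "NA" else sprintf("%.3f", x$weighted_auc),
              x$sotd, x$merged$error_rate))
  cat("\nConfusion matrix (rows true, columns predicted):\n")
  print(x$cm)
  invisible(x)
}
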