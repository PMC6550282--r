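# Metrics and uncertainty: confusion matrices, per-class accuracy,
# precision/recall/F1, sensitivity/specificity and percentile bootstrap
# confidence intervals.

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`
#' (0-based classes). With `normalized = TRUE` rows are divided by their
#' sums; a class absent from the truth yields a zero row and a warning,
#' never `NaN`.
#'
#' @param y_true,y_pred Integer vectors of 0-based class labels.
#' @param k Number of classes.
#' @param normalized Row-normalise the matrix.
#' @return A `k x k` matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, k, normalized = FALSE) {
  cm <- matrix(0, k, k, dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1
  }
  if (normalized) {
    rs <- rowSums(cm)
    if (any(rs == 0)) warning("empty true class: its row is left as zeros")
    nz <- rs > 0
    cm[nz, ] <- cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Precision, recall and F1 for one positive class
#'
#' F1 is the harmonic mean `2pr / (p + r)`, defined as 0 (with a warning)
#' when `p + r` is 0 or when there are neither positive predictions nor
#' positives.
#'
#' @param y_true,y_pred 0-based label vectors.
#' @param positive_class The class treated as positive.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(y_true, y_pred, positive_class = 1L) {
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  if (tp + fp + fn == 0) {
    warning("no positives and no positive predictions: F1 defined as 0")
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

macro_f1 <- function(y_true, y_pred, k) {
  mean(vapply(0:(k - 1), function(cl) {
    suppressWarnings(precision_recall_f1(y_true, y_pred, cl)[["f1"]])
  }, numeric(1)))
}

#' Sensitivity and specificity for a binary task
#'
#' Sensitivity is `TP / (TP + FN)`; specificity `TN / (TN + FP)`. Class 1 is
#' positive.
#'
#' @param y_true,y_pred 0/1 label vectors.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Percentile bootstrap confidence interval for a paired metric
#'
#' Resamples `(y_true, y_pred)` pairs with replacement `n_boot` times and
#' returns the percentile interval of the metric at the requested level.
#' Pair-level (not study-level) resampling; see the methods vignette for the
#' implied independence assumption.
#'
#' @param y_true,y_pred Label vectors.
#' @param metric Function of `(y_true, y_pred)` returning a scalar; defaults
#'   to accuracy.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed.
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_ci <- function(y_true, y_pred, metric = function(t, p) mean(t == p),
                         n_boot = 1000L, level = 0.95, seed = 1L) {
  n <- length(y_true)
  if (n == 0) stop("empty inputs", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(y_true[idx], y_pred[idx])
  }, numeric(1))
  q <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE,
                       type = 7)
  c(low = q[1], high = q[2])
}

#' Full evaluation report for a classification result
#'
#' Accuracy, per-class accuracy, row-normalised confusion matrix, F1
#' (positive-class F1 for binary tasks with class 1 positive, macro F1
#' otherwise), sensitivity/specificity (binary only) and a bootstrap CI for
#' accuracy, reported both as `(low, high)` and as a half-width.
#'
#' @param y_true,y_pred 0-based label vectors.
#' @param k Number of classes (inferred if missing).
#' @param n_boot,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return An `eval_report` object; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
eval_report <- function(y_true, y_pred, k = max(c(y_true, y_pred)) + 1L,
                        n_boot = 1000L, level = 0.95, seed = 1L) {
  cm <- confusion_matrix(y_true, y_pred, k)
  cmn <- suppressWarnings(confusion_matrix(y_true, y_pred, k, normalized = TRUE))
  acc <- mean(y_true == y_pred)
  per_class <- vapply(0:(k - 1), function(cl) {
    idx <- y_true == cl
    if (!any(idx)) return(NA_real_)
    mean(y_pred[idx] == cl)
  }, numeric(1))
  binary <- k == 2
  f1 <- if (binary) {
    suppressWarnings(precision_recall_f1(y_true, y_pred, 1L)[["f1"]])
  } else {
    macro_f1(y_true, y_pred, k)
  }
  ci <- bootstrap_ci(y_true, y_pred, n_boot = n_boot, level = level, seed = seed)
  structure(list(
    accuracy = acc, per_class_accuracy = per_class, confusion = cmn,
    confusion_counts = cm, f1 = f1,
    sensitivity = if (binary) sensitivity_specificity(y_true, y_pred)[["sensitivity"]] else NA_real_,
    specificity = if (binary) sensitivity_specificity(y_true, y_pred)[["specificity"]] else NA_real_,
    ci = ci, ci_half_width = (ci[["high"]] - ci[["low"]]) / 2,
    level = level, n = length(y_true), k = k
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d, K = %d)\n", x$n, x$k))
  cat(sprintf("  accuracy: %.4f  (%.0f%% CI %.4f-%.4f, half-width %.4f)\n",
              x$accuracy, 100 * x$level, x$ci[["low"]], x$ci[["high"]],
              x$ci_half_width))
  cat(sprintf("  F1: %.4f\n", x$f1))
  if (x$k == 2) {
    cat(sprintf("  sensitivity: %.4f  specificity: %.4f\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}
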