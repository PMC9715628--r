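#' Area under the ROC curve
#'
#' Computes the ROC AUC via the Mann-Whitney identity: the fraction of
#' (case, control) pairs in which the case receives the higher score,
#' counting tied pairs as 1/2. Chance level is 0.5.
#'
#' @param scores Numeric vector; higher values indicate the case class.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return A single number in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  sl <- check_scored_labels(scores, labels, need_both = TRUE)
  n1 <- sum(sl$labels == 1L)
  n0 <- sum(sl$labels == 0L)
  r <- rank(sl$scores, ties.method = "average")
  (sum(r[sl$labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over the descending-score sweep,
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}, with tied scores processed as a single
#' block. No linear interpolation between PR points is used, since
#' interpolating precision is known to be optimistic. The chance level of
#' this metric equals the positive-class prevalence.
#'
#' @inheritParams roc_auc
#' @return Average precision in \[0, 1\].
#' @examples
#' prc_auc(c(0.9, 0.8, 0.7), c(1, 0, 1)) # 0.8333
#' @export
prc_auc <- function(scores, labels) {
  sl <- check_scored_labels(scores, labels)
  n_pos <- sum(sl$labels == 1L)
  if (n_pos == 0L) stop("prc_auc() requires at least one positive label")
  o <- order(sl$scores, decreasing = TRUE)
  s <- sl$scores[o]
  y <- sl$labels[o]
  # block boundaries: last index of each run of tied scores
  n <- length(s)
  block_end <- c(which(s[-n] != s[-1L]), n)
  tp <- cumsum(y)[block_end]
  pred_pos <- block_end
  recall <- tp / n_pos
  precision <- tp / pred_pos
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Dichotomizes scores at `threshold` and reports precision, recall,
#' specificity and F1. When no sample is predicted positive, precision
#' (and F1) are undefined and returned as `NA` with `precision_defined =
#' FALSE`, rather than silently coerced to 0.
#'
#' @inheritParams roc_auc
#' @param threshold Probability cutoff in (0, 1); scores >= threshold are
#'   called positive. Default 0.5.
#' @return A list with `precision`, `recall`, `specificity`, `f1`, the
#'   four confusion counts, `threshold`, and `precision_defined`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single probability in (0, 1)")
  }
  sl <- check_scored_labels(scores, labels)
  pred <- as.integer(sl$scores >= threshold)
  tp <- sum(pred == 1L & sl$labels == 1L)
  fp <- sum(pred == 1L & sl$labels == 0L)
  fn <- sum(pred == 0L & sl$labels == 1L)
  tn <- sum(pred == 0L & sl$labels == 0L)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else NA_real_
  recall <- if ((tp + fn) > 0L) tp / (tp + fn) else NA_real_
  specificity <- if ((tn + fp) > 0L) tn / (tn + fp) else NA_real_
  f1 <- if (precision_defined && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, specificity = specificity,
       f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn,
       threshold = threshold, precision_defined = precision_defined)
}

# shared input validation for scored-label pairs
check_scored_labels <- function(scores, labels, need_both = FALSE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(scores) || !is.numeric(labels)) {
    stop("scores and labels must be numeric")
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores/labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  labels <- as.integer(labels)
  if (need_both && length(unique(labels)) < 2L) {
    stop("both classes must be present")
  }
  list(scores = as.numeric(scores), labels = labels)
}
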