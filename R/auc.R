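#' Empirical (rank-based) area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — i.e. the Mann-Whitney U
#' statistic divided by `n1 * n0`.  This is the selection metric used
#' throughout the model-search framework.
#'
#' @param scores Numeric vector of continuous scores.
#' @param labels Binary 0/1 (or logical) vector, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0))  # 0.75
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_invalid("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels))
    stop_invalid("scores and labels must not contain NA")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' Empirical ROC as a monotone step curve from (0,0) to (1,1), one row
#' per distinct score threshold (classify positive when
#' `score >= threshold`).
#'
#' @inheritParams empirical_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("both classes must be present to compute a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(diff(s) != 0, TRUE)  # last row per distinct threshold
  tpr <- cumsum(y)[keep] / n1
  fpr <- cumsum(1 - y)[keep] / n0
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion counts at a probability threshold
#'
#' @inheritParams empirical_auc
#' @param threshold Classify positive when `score > threshold`
#'   (default 0.5).
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  c(tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    tn = sum(pred == 0L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L))
}
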