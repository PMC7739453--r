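#' Confusion counts, precision/recall/accuracy, PR curve and auPR
#'
#' Thresholds scores at `threshold` (score >= threshold predicts an
#' interaction; ties count as positive) to obtain the confusion counts, then
#' computes precision = TP / (TP + FP), recall = TP / (TP + FN) and
#' accuracy = (TP + TN) / (TP + TN + FP + FN). When a denominator is zero
#' the metric is reported as `NA` (undefined), never silently 0.
#'
#' The precision-recall curve sweeps every distinct score as a threshold
#' (highest first). auPR uses step-wise interpolation — precision held
#' constant between consecutive recall points, area accumulated as a
#' rectangle sum — which matches exhaustive threshold enumeration exactly;
#' linear interpolation of PR curves overestimates the area and is not used.
#'
#' @param scores Numeric interaction scores, one per labeled pair.
#' @param labels Binary labels (0/1), same length as `scores`.
#' @param threshold Classification threshold; default 0.5.
#' @return An `eval_report`: list with `counts` (TP/TN/FP/FN), `precision`,
#'   `recall`, `accuracy`, `pr_curve` (data.frame `threshold`, `recall`,
#'   `precision` ordered by decreasing threshold), and `auPR`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)), all(is.finite(scores)))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  TN <- sum(pred == 0L & labels == 0L)
  FP <- sum(pred == 1L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  precision <- if (TP + FP == 0L) NA_real_ else TP / (TP + FP)
  recall <- if (TP + FN == 0L) NA_real_ else TP / (TP + FN)
  accuracy <- (TP + TN) / length(labels)
  pr <- pr_curve(scores, labels)
  structure(list(counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
                 precision = precision, recall = recall, accuracy = accuracy,
                 threshold = threshold, pr_curve = pr,
                 auPR = attr(pr, "auPR")),
            class = "eval_report")
}

#' Precision-recall curve by threshold sweep
#'
#' One point per distinct score value, thresholds descending (so recall is
#' non-decreasing along the curve). At each threshold `t`, pairs with
#' score >= t are predicted positive. The `auPR` attribute holds the
#' rectangle-sum area `sum((R_k - R_{k-1}) * P_k)` with `R_0 = 0`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return Data.frame `threshold`, `recall`, `precision` with attribute
#'   `auPR`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y == 1L)
  cum_fp <- cumsum(y == 0L)
  # last index of each distinct score = everything at or above that threshold
  last_of_value <- which(!duplicated(s, fromLast = TRUE))
  thr <- s[last_of_value]
  TP <- cum_tp[last_of_value]
  FP <- cum_fp[last_of_value]
  precision <- ifelse(TP + FP == 0L, NA_real_, TP / (TP + FP))
  recall <- if (n_pos == 0L) rep(NA_real_, length(TP)) else TP / n_pos
  auPR <- if (n_pos == 0L) NA_real_ else {
    sum(diff(c(0, recall)) * ifelse(is.na(precision), 0, precision))
  }
  out <- data.frame(threshold = thr, recall = recall, precision = precision)
  attr(out, "auPR") <- auPR
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\n")
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$counts["TP"], x$counts["TN"], x$counts["FP"], x$counts["FN"]))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("  precision:", fmt(x$precision), "\n")
  cat("  recall:   ", fmt(x$recall), "\n")
  cat("  accuracy: ", fmt(x$accuracy), "\n")
  cat("  auPR:     ", fmt(x$auPR), "\n")
  invisible(x)
}

#' Metrics from explicit confusion counts
#'
#' Direct substitution of TP/TN/FP/FN into the precision, recall and
#' accuracy definitions; undefined ratios (zero denominator) are `NA`.
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return Named list `precision`, `recall`, `accuracy`.
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN > 0)
  list(
    precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
    recall = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    accuracy = (TP + TN) / (TP + TN + FP + FN)
  )
}
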