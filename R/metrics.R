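# Two-stream ensemble and the evaluation suite.

#' Weighted ensemble score of the two streams
#'
#' `w * temporal + (1 - w) * spatial`, the convex combination of the two
#' stream probabilities.
#'
#' @param pt temporal stream score(s) in \[0, 1\].
#' @param ps spatial stream score(s) in \[0, 1\].
#' @param w weight of the temporal stream in \[0, 1\].
#' @return ensemble score(s) in \[0, 1\].
#' @export
ensemble_score <- function(pt, ps, w) {
  if (any(pt < 0 | pt > 1) || any(ps < 0 | ps > 1)) {
    stop("stream scores must lie in [0, 1]")
  }
  if (w < 0 || w > 1) stop("weight must lie in [0, 1]")
  w * pt + (1 - w) * ps
}

#' Binary call from a score
#'
#' @param score score(s) in \[0, 1\].
#' @param threshold decision threshold; calls are 1 iff `score >= threshold`.
#' @return integer 0/1 vector.
#' @export
classify_call <- function(score, threshold = 0.5) {
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  as.integer(score >= threshold)
}

#' Search the ensemble weight on the 0.01 grid
#'
#' Traverses the temporal-stream weight over 0, 0.01, ..., 1 and returns the
#' weight maximizing the thresholded ensemble accuracy; ties go to the
#' smallest weight so reports are deterministic.
#'
#' @param pt,ps stream scores, one pair per embryo.
#' @param labels binary labels.
#' @param threshold decision threshold for accuracy.
#' @return list with `weight` (temporal-stream weight), `accuracy`, and
#'   `grid` (data frame of all 101 weights and accuracies).
#' @export
search_weight <- function(pt, ps, labels, threshold = 0.5) {
  stopifnot(length(pt) == length(ps), length(pt) == length(labels))
  if (length(pt) == 0) stop("empty input")
  if (length(unique(labels)) < 2) {
    stop("weight search requires both labels present")
  }
  weights <- (0:100) / 100
  acc <- vapply(weights, function(w) {
    calls <- classify_call(ensemble_score(pt, ps, w), threshold)
    mean(calls == labels)
  }, numeric(1))
  best <- which.max(acc)  # which.max takes the first (smallest) on ties
  list(weight = weights[best], accuracy = acc[best],
       grid = data.frame(weight = weights, accuracy = acc))
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics report
#'
#' Computes the confusion counts and the standard ratios: sensitivity =
#' TP / real positives, specificity = TN / real negatives, PPV = TP /
#' predicted positives, NPV = TN / predicted negatives, accuracy =
#' (TP + TN) / total. Ratios with a zero denominator are reported as `NA`
#' (undefined), never as 0.
#'
#' @param calls binary 0/1 calls.
#' @param labels binary 0/1 true labels, same length.
#' @return object of class `metrics_report`: list with `tp`, `tn`, `fp`,
#'   `fn`, `n`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
compute_metrics <- function(calls, labels) {
  if (length(calls) != length(labels)) {
    stop("calls and labels differ in length")
  }
  if (length(calls) < 1) stop("empty input")
  stopifnot(all(calls %in% 0:1), all(labels %in% 0:1))
  tp <- sum(calls == 1 & labels == 1)
  tn <- sum(calls == 0 & labels == 0)
  fp <- sum(calls == 1 & labels == 0)
  fn <- sum(calls == 0 & labels == 1)
  n <- length(calls)
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
         sensitivity = ratio_or_na(tp, tp + fn),
         specificity = ratio_or_na(tn, tn + fp),
         ppv = ratio_or_na(tp, tp + fp),
         npv = ratio_or_na(tn, tn + fn),
         accuracy = (tp + tn) / n),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics: n=%d TP=%d TN=%d FP=%d FN=%d | acc=%.3f sens=%.3f spec=%.3f ppv=%.3f npv=%.3f>\n",
    x$n, x$tp, x$tn, x$fp, x$fn, x$accuracy, x$sensitivity, x$specificity,
    x$ppv, x$npv))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the observed scores, plotting
#' sensitivity against 1 - specificity, and integrates by the trapezoid rule;
#' with ties grouped per distinct score this equals the Mann-Whitney pair
#' statistic (ties counted one half).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return list with `roc` (data frame of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct score (call = score >= threshold)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l == 1)[last]
  fp <- cumsum(l == 0)[last]
  roc <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / nneg),
    tpr = c(0, tp / npos)
  )
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}
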