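#' Confusion counts for binary ASD/TD classification
#'
#' TP counts actual ASD (label 1) predicted ASD, TN actual TD predicted TD,
#' FN actual ASD predicted TD, FP actual TD predicted ASD. The four counts
#' partition the evaluated windows.
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return Object of class `"confusion_counts"`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("truth and predicted lengths differ")
  if (length(truth) && (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))) {
    stopf("labels must be 0 or 1")
  }
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 TN = sum(truth == 0 & predicted == 0),
                 FP = sum(truth == 0 & predicted == 1),
                 FN = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FN %d\nFP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy is the fraction of all windows classified correctly,
#' `(TP + TN) / (TP + TN + FP + FN)`; sensitivity is the true-positive rate
#' `TP / (TP + FN)`; specificity the true-negative rate `TN / (TN + FP)`;
#' precision `TP / (TP + FP)`. A metric with a zero denominator is reported
#' as `NaN` with a warning.
#'
#' @param cc A [confusion_counts()] object.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
classification_metrics <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stopf("no evaluated windows")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  list(accuracy = (cc$TP + cc$TN) / total,
       sensitivity = safe_div(cc$TP, cc$TP + cc$FN, "sensitivity"),
       specificity = safe_div(cc$TN, cc$TN + cc$FP, "specificity"),
       precision = safe_div(cc$TP, cc$TP + cc$FP, "precision"))
}

#' ROC curve and AUC
#'
#' In `"full"` mode every distinct score is used as a threshold; in
#' `"three_point"` mode only the maximum, minimum and mid-range
#' `(min + max) / 2` of the scores are used, each threshold contributing one
#' (false positive rate, true positive rate) point. Predictions are positive
#' when `score >= threshold`. The curve is closed with (0, 0) and (1, 1) and
#' the AUC is the trapezoidal area under the sorted points.
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1 true labels; both classes must be present.
#' @param mode `"full"` or `"three_point"`.
#' @return Object of class `"roc_points"`: list with `points` (data frame
#'   `fpr`, `tpr` sorted by fpr) and `auc`.
#' @export
roc_auc <- function(scores, labels, mode = c("full", "three_point")) {
  mode <- match.arg(mode)
  if (length(scores) != length(labels)) stopf("scores and labels lengths differ")
  if (length(unique(labels)) < 2L) stopf("both classes must be present for a ROC curve")
  thresholds <- if (mode == "full") sort(unique(scores))
                else unique(c(max(scores), (min(scores) + max(scores)) / 2, min(scores)))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  pts <- t(vapply(thresholds, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0) / neg, tpr = sum(pred & labels == 1) / pos)
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) + utils::tail(pts[, 2], -1)) / 2)
  structure(list(points = data.frame(fpr = pts[, 1], tpr = pts[, 2]),
                 auc = auc, mode = mode),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("<roc_points> %s mode, %d points, AUC %.4f\n",
              x$mode, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "b",
       xlab = "false positive rate", ylab = "true positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Evaluate a fitted model on a windowed dataset
#'
#' Window-level evaluation: scores, thresholded confusion counts, the scalar
#' metrics and a ROC curve. A subject-level majority-vote summary over each
#' subject's windows is included as an additional report.
#'
#' @param object Fitted [asgcn()] model.
#' @param data A [windowed_dataset()].
#' @param threshold Decision threshold (default 0.5).
#' @param roc_mode `"full"` or `"three_point"`.
#' @return List with `scores`, `confusion`, `metrics`, `roc`, and
#'   `subject_votes` (data frame of per-subject majority votes).
#' @export
asgcn_evaluate <- function(object, data, threshold = 0.5,
                           roc_mode = c("full", "three_point")) {
  roc_mode <- match.arg(roc_mode)
  scores <- predict(object, data)
  pred <- as.integer(scores >= threshold)
  cc <- confusion_counts(data$labels, pred)
  votes <- NULL
  if (length(unique(data$subject_ids)) >= 1L) {
    agg <- tapply(pred, data$subject_ids, function(p) as.integer(mean(p) >= 0.5))
    lab <- tapply(data$labels, data$subject_ids, function(l) l[1L])
    votes <- data.frame(subject_id = names(agg),
                        vote = as.integer(agg), label = as.integer(lab),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(scores = scores, confusion = cc,
       metrics = suppressWarnings(classification_metrics(cc)),
       roc = if (length(unique(data$labels)) == 2L) roc_auc(scores, data$labels, roc_mode) else NULL,
       subject_votes = votes)
}
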