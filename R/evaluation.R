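# Evaluation metrics for imbalanced binary classification: confusion counts,
# accuracy / F1 / Matthews correlation, and the ROC and precision-recall
# curves with their areas. Implemented from the defining formulas; note the
# ROC uses the standard false-positive rate FP / (FP + TN).

#' Confusion counts at a decision threshold
#'
#' A gene is predicted positive when its probability is >= `threshold`.
#'
#' @param y binary truth labels (0/1 vector).
#' @param probs scores aligned to `y`.
#' @param threshold decision threshold.
#' @return list of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y, probs, threshold = 0.5) {
  assert_that(length(y) == length(probs) && length(y) >= 1,
              "labels and scores must be non-empty and equal length")
  pred <- probs >= threshold
  structure(list(TP = sum(pred & y == 1), TN = sum(!pred & y == 0),
                 FP = sum(pred & y == 0), FN = sum(!pred & y == 1)),
            class = "confusion_counts")
}

#' Accuracy, F1 and Matthews correlation from confusion counts
#'
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`; `F1 = 2 P R / (P + R)` with
#' `P = TP/(TP+FP)` and `R = TP/(TP+FN)`;
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators yield 0 by convention.
#'
#' @param counts a [confusion_counts()] result.
#' @return list with ACC, F1, MCC.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den) else 0
  list(ACC = acc, F1 = f1, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) statistic, which handles tied scores
#' by half-credit; the returned curve is the standard threshold sweep with
#' `TPR = TP/(TP+FN)` and `FPR = FP/(FP+TN)`, starting at (0,0) and ending
#' at (1,1).
#'
#' @param y binary truth labels (0/1); both classes must be present.
#' @param scores numeric scores.
#' @return list with `auc` and `curve` (data.frame with columns fpr, tpr).
#' @export
auroc <- function(y, scores) {
  y <- as.numeric(y)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  assert_that(n_pos >= 1 && n_neg >= 1,
              "AUROC needs both classes present (%d positive, %d negative)",
              n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  last <- cumsum(rep(1, length(ss)))[!duplicated(ss, fromLast = TRUE)]
  # cumulative counts at each distinct threshold
  ctp <- cumsum(ys)[last]; cfp <- cumsum(1 - ys)[last]
  curve <- data.frame(fpr = c(0, cfp / n_neg), tpr = c(0, ctp / n_pos))
  list(auc = auc, curve = curve)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: `sum_k (R_k - R_(k-1)) P_k` over the
#' distinct score thresholds in decreasing order. With all scores tied this
#' reduces to the prevalence, the no-skill baseline.
#'
#' @param y binary truth labels (0/1); at least one positive required.
#' @param scores numeric scores.
#' @return list with `auc` and `curve` (data.frame with columns recall,
#'   precision).
#' @export
aupr <- function(y, scores) {
  y <- as.numeric(y)
  n_pos <- sum(y == 1)
  assert_that(n_pos >= 1, "AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  last <- cumsum(rep(1, length(ss)))[!duplicated(ss, fromLast = TRUE)]
  ctp <- cumsum(ys)[last]
  k <- last  # predicted-positive count at each threshold
  precision <- ctp / k
  recall <- ctp / n_pos
  auc <- sum(diff(c(0, recall)) * precision)
  list(auc = auc,
       curve = data.frame(recall = recall, precision = precision))
}

#' Full metric report for one evaluation set
#'
#' @param y binary truth labels (0/1).
#' @param probs probability scores.
#' @param threshold decision threshold for ACC/F1/MCC.
#' @return list with ACC, AUROC, AUPR, F1, MCC and the threshold used.
#' @export
metrics_report <- function(y, probs, threshold = 0.5) {
  cc <- confusion_counts(y, probs, threshold)
  cm <- classification_metrics(cc)
  list(ACC = cm$ACC,
       AUROC = auroc(y, probs)$auc,
       AUPR = aupr(y, probs)$auc,
       F1 = cm$F1,
       MCC = cm$MCC,
       threshold = threshold)
}

#' Write a metrics report as a one-row TSV
#' @param report a [metrics_report()] result (or a list of them, one row each,
#'   with names used as the first column).
#' @param path output path.
#' @export
write_metrics <- function(report, path) {
  if (!is.null(report$ACC)) report <- list(all = report)
  df <- do.call(rbind, lapply(report, function(r) {
    data.frame(ACC = r$ACC, AUROC = r$AUROC, AUPR = r$AUPR, F1 = r$F1,
               MCC = r$MCC)
  }))
  df <- cbind(set = names(report), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a curve as two-column TSV
#' @param curve data.frame from [auroc()] or [aupr()].
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
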