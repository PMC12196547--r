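#' Confusion counts for the binary PD/HC problem
#'
#' PD (label 1) is the positive class.
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @return A one-row tibble with columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tibble::tibble(
    TP = sum(pred == 1 & truth == 1),
    TN = sum(pred == 0 & truth == 0),
    FP = sum(pred == 1 & truth == 0),
    FN = sum(pred == 0 & truth == 1)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = harmonic mean of precision and recall; all
#' reported in percent. A metric with a zero denominator is reported as
#' `NA` and flagged in the `defined` column.
#'
#' @param counts a one-row tibble/list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble: `acc`, `prec`, `rec`, `f1` (percent),
#'   `defined` (logical).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP
  TN <- counts$TN
  FP <- counts$FP
  FN <- counts$FN
  total <- TP + TN + FP + FN
  acc <- if (total > 0) 100 * (TP + TN) / total else NA_real_
  prec <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  rec <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    f1_score(prec, rec)
  } else {
    NA_real_
  }
  tibble::tibble(
    acc = acc, prec = prec, rec = rec, f1 = f1,
    defined = !anyNA(c(acc, prec, rec, f1))
  )
}

#' F1 score from precision and recall
#'
#' `2 * prec * rec / (prec + rec)`, in the units of its inputs (percent
#' in, percent out).
#'
#' @param prec,rec precision and recall.
#' @export
f1_score <- function(prec, rec) 2 * prec * rec / (prec + rec)

#' Rank-based ROC AUC
#'
#' The probability that a random PD sample receives a higher score than a
#' random HC sample, ties counted one half — the Mann-Whitney statistic,
#' equal to trapezoidal integration of the ROC curve.
#'
#' @param scores PD-class scores/probabilities.
#' @param labels 0/1 labels, 1 = PD.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bundled reference five-fold evaluation report
#'
#' Per-fold validation metrics (accuracy, precision, recall, F1 in
#' percent, AUC) of a published dual-view gait screening evaluation on a
#' hospital cohort, as printed: one row per fold. Used to exercise the
#' metric arithmetic ([f1_score()], [aggregate_folds()]) against known
#' values.
#'
#' @return A tibble with columns `fold, train_acc, train_f1, acc, prec,
#'   rec, f1, auc`.
#' @export
reference_fold_report <- function() {
  readr::read_csv(
    system.file("extdata", "reference_fold_metrics.csv", package = "gaitscreen"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean of every numeric metric column across folds, the
#' cross-validated summary row.
#'
#' @param folds tibble with one row per fold and numeric metric columns
#'   (e.g. `acc`, `prec`, `rec`, `f1`, `auc`).
#' @return One-row tibble of means over folds.
#' @export
aggregate_folds <- function(folds) {
  stopifnot(nrow(folds) >= 1)
  folds <- dplyr::select(folds, -dplyr::any_of(c("fold", "defined")))
  dplyr::summarise(folds, dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)))
}
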