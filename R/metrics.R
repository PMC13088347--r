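# Evaluation metrics with explicit tie conventions.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from the rank sum.
#' Invariant under strictly monotone transforms of the scores; all-tied
#' scores give 0.5.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @return AUROC in `[0,1]`.
#' @examples
#' aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
aurocScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("length mismatch")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' F1 score at a probability threshold
#'
#' Harmonic mean of precision and recall with predictions
#' `score >= threshold`. Returns 0 when there are no positive predictions
#' while positives exist (precision undefined, recall zero).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (default 0.5).
#' @return F1 in `[0,1]`.
#' @export
f1Score <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stopf("length mismatch")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp + fp == 0 || tp + fn == 0 || tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
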