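#' Confusion counts at a score threshold
#'
#' A pair is predicted positive when its score is greater than or equal to
#' the threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels aligned with `scores`.
#' @param threshold decision threshold (default 0.5).
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty score vector")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  pred <- scores >= threshold
  list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
       TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Threshold classification metrics from confusion counts
#'
#' Precision, recall, accuracy, F1 and the Matthews correlation coefficient.
#' A metric whose denominator is zero is reported as 0 with a warning
#' (degenerate confusion tables keep sweep reports total).
#'
#' @param cc list with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_at_threshold()]).
#' @return named list with `precision`, `recall`, `acc`, `f1`, `mcc`.
#' @export
compute_metrics <- function(cc) {
  tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be non-negative")
  guarded <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- guarded(tp, tp + fp, "precision")
  recall <- guarded(tp, tp + fn, "recall")
  acc <- guarded(tp + tn, tp + fp + tn + fn, "accuracy")
  f1 <- guarded(2 * precision * recall, precision + recall, "F1")
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- guarded(tp * tn - fp * fn, mcc_den, "MCC")
  list(precision = precision, recall = recall, acc = acc, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the TPR-vs-FPR curve over the full threshold
#' sweep (tied scores are grouped), which equals the Mann-Whitney
#' concordance statistic with ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC AUC requires both classes to be present")
  }
  sw <- .threshold_sweep(scores, labels)
  tpr <- c(0, cumsum(sw$pos) / n_pos)
  fpr <- c(0, cumsum(sw$neg) / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Area under the precision-recall curve
#'
#' Step integration in descending score order (tied scores grouped):
#' each recall increment is weighted by the precision attained at that
#' cutoff, avoiding the optimistic linear interpolation of trapezoids on
#' PR curves.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR requires at least one positive")
  sw <- .threshold_sweep(scores, labels)
  tp <- cumsum(sw$pos)
  n_pred <- cumsum(sw$pos + sw$neg)
  precision <- tp / n_pred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# Counts of positives/negatives per unique score, in descending score
# order: the shared backbone of both curve integrations.
.threshold_sweep <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  list(pos = as.numeric(rowsum(as.numeric(y == 1), grp)),
       neg = as.numeric(rowsum(as.numeric(y == 0), grp)))
}

#' Two-tailed pooled-variance (equal variance) t-test
#'
#' Student's t with pooled variance and `n_a + n_b - 2` degrees of freedom,
#' as used to compare per-fold AUC/AUPR samples between methods. Two
#' identical constant samples give t = 0, p = 1 by convention.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df` and two-tailed `p`.
#' @export
equal_variance_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must have at least 2 observations")
  }
  df <- length(sample_a) + length(sample_b) - 2
  pooled <- ((length(sample_a) - 1) * stats::var(sample_a) +
             (length(sample_b) - 1) * stats::var(sample_b)) / df
  if (pooled == 0) {
    # degenerate: both samples constant
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
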