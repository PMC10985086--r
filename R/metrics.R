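#' Rank-statistic ROC-AUC
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic with midranks for ties.
#'
#' @param labels binary 0/1 vector.
#' @param probs scores.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(labels, probs) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: single-class input")
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(labels, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  c(TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0),
    FN = sum(pred == 0 & labels == 1))
}

#' Binary classification metrics at a threshold
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), F1 = harmonic mean of sensitivity and PPV, plus
#' rank-statistic ROC-AUC.
#'
#' @param labels binary 0/1 vector.
#' @param probs predicted probabilities.
#' @param threshold classification threshold (default 0.5).
#' @return named numeric vector (counts and rates).
#' @export
binary_metrics <- function(labels, probs, threshold = 0.5) {
  cc <- confusion_counts(labels, probs, threshold)
  sens <- cc["TP"] / (cc["TP"] + cc["FN"])
  spec <- cc["TN"] / (cc["TN"] + cc["FP"])
  ppv <- cc["TP"] / (cc["TP"] + cc["FP"])
  npv <- cc["TN"] / (cc["TN"] + cc["FN"])
  f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) 0 else
    2 / (1 / sens + 1 / ppv)
  c(cc, sensitivity = unname(sens), specificity = unname(spec),
    PPV = unname(ppv), NPV = unname(npv), F1 = unname(f1),
    AUC = auc_rank(labels, probs))
}

#' Evaluate out-of-fold predictions with fold-level confidence intervals
#'
#' Metrics are computed per outer fold at the given threshold, then averaged;
#' the 95% CI is a t-interval with `k - 1` degrees of freedom across the k
#' fold-level values. Pooled confusion counts over all subjects are also
#' reported.
#'
#' @param labels binary 0/1 labels.
#' @param probs out-of-fold probabilities.
#' @param folds `nested_folds` object or integer outer-fold vector.
#' @param threshold classification threshold (default 0.5).
#' @return list with `counts`, `per_fold` (data.frame), `mean`, `ci_lower`,
#'   `ci_upper`.
#' @export
evaluate <- function(labels, probs, folds, threshold = 0.5) {
  outer <- if (inherits(folds, "nested_folds")) folds$outer else folds
  stopifnot(length(outer) == length(labels), all(probs >= 0), all(probs <= 1))
  ids <- sort(unique(outer))
  per <- t(vapply(ids, function(f) {
    sel <- outer == f
    if (length(unique(labels[sel])) < 2L)
      stop("AUC undefined in single-class fold ", f)
    binary_metrics(labels[sel], probs[sel], threshold)
  }, binary_metrics(labels, probs, threshold)))
  per <- as.data.frame(per)
  per$fold <- ids
  rates <- c("sensitivity", "specificity", "PPV", "NPV", "F1", "AUC")
  m <- colMeans(per[rates])
  se <- vapply(per[rates], stats::sd, numeric(1)) / sqrt(length(ids))
  tq <- stats::qt(0.975, df = length(ids) - 1)
  list(counts = confusion_counts(labels, probs, threshold),
       per_fold = per,
       mean = m, ci_lower = m - tq * se, ci_upper = m + tq * se)
}
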