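# Power and ROC computation over simulated causal / null datasets.

#' Statistical power at a significance level
#'
#' Proportion of causal-dataset p-values strictly below `alpha`
#' (p-values exactly equal to `alpha` do not count as detections).
#'
#' @param pvalues_causal p-values of the causal (positive) datasets.
#' @param alpha significance level in (0, 1].
#' @return Scalar power in [0, 1].
#' @export
detection_power <- function(pvalues_causal, alpha = 0.05) {
  .assert(length(pvalues_causal) >= 1L, "empty p-value vector")
  .assert(is.numeric(alpha) && alpha > 0 && alpha <= 1,
          "alpha must be in (0, 1]")
  mean(pvalues_causal < alpha)
}

#' ROC points from causal and null p-values
#'
#' Sweeps the p-value threshold over all distinct pooled values:
#' TPR(t) = fraction of causal p <= t, FPR(t) = fraction of null p <= t;
#' endpoints (0, 0) and (1, 1) are appended.  Invariant under strictly
#' monotone transforms of all p-values.
#'
#' @param pvalues_causal p-values of causal (positive) datasets.
#' @param pvalues_null p-values of null (negative) datasets.
#' @return data.frame(fpr, tpr) of class `roc_curve`, both columns
#'   non-decreasing from (0, 0) to (1, 1).
#' @export
roc_points <- function(pvalues_causal, pvalues_null) {
  .assert(length(pvalues_causal) >= 1L && length(pvalues_null) >= 1L,
          "both p-value vectors must be non-empty")
  thr <- sort(unique(c(pvalues_causal, pvalues_null)))
  tpr <- vapply(thr, function(t) mean(pvalues_causal <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(pvalues_null <= t), numeric(1))
  out <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- out[!duplicated(out), ]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under an ROC curve
#'
#' Trapezoidal area under a [roc_points()] curve.
#'
#' @param roc a `roc_curve`.
#' @return Scalar AUC.
#' @export
roc_auc <- function(roc) {
  .assert(inherits(roc, "roc_curve"), "not a roc_curve")
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
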