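## Performance of an estimated network against a known ground truth.
## All measures exclude the diagonal, which the method leaves undefined.

offdiag <- function(M) M[row(M) != col(M)]

check_shapes <- function(G_est, G_true) {
  stopifnot(is.matrix(G_est), is.matrix(G_true))
  if (!all(dim(G_est) == dim(G_true)))
    stop("estimate and ground truth have different shapes")
}

#' Area under the ROC curve for edge detection
#'
#' Scores off-diagonal magnitudes `|G_est|` against the binary existence
#' of the true edges.  Computed by the Mann-Whitney rank formula with ties
#' averaged, equivalent to trapezoidal integration of the ROC curve.
#'
#' @param G_est estimated connectivity (only magnitudes are used).
#' @param G_true ground-truth connectivity; nonzero = edge.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(G_est, G_true) {
  check_shapes(G_est, G_true)
  scores <- abs(offdiag(G_est))
  truth <- offdiag(G_true) != 0
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("degenerate ground truth: need both present and absent edges")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision score (area under the precision-recall curve)
#'
#' Step-wise integral of precision over recall,
#' \eqn{\sum_k (R_k - R_{k-1}) P_k}, sweeping the decision threshold over
#' the distinct score values (ties handled as one block).
#'
#' @inheritParams roc_auc
#' @return average precision in \[0, 1\].
#' @export
precision_recall_score <- function(G_est, G_true) {
  check_shapes(G_est, G_true)
  scores <- abs(offdiag(G_est))
  truth <- offdiag(G_true) != 0
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("degenerate ground truth: need both present and absent edges")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  ## block boundaries where the score strictly drops: thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Pearson correlation of signed connection weights
#'
#' Correlates the vectorized off-diagonal entries of the estimate with the
#' truth, taking strength and sign into account (unlike AUC/average
#' precision, which only rank edge magnitudes).
#'
#' @inheritParams roc_auc
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(G_est, G_true) {
  check_shapes(G_est, G_true)
  a <- offdiag(G_est); b <- offdiag(G_true)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' Confusion counts and rates at a magnitude threshold
#'
#' Calls an edge wherever `|G_est| > threshold` and tabulates it against
#' the true edges.  Reported rates follow the ROC conventions: the miss
#' (false-negative) rate is \eqn{FN/(TP+FN)} and the false-positive rate
#' \eqn{FP/(FP+TN)}.  `sign_accuracy` is the fraction of true positives
#' whose estimated sign matches the true sign.
#'
#' @inheritParams roc_auc
#' @param threshold nonnegative magnitude cutoff.  Defaults to half the
#'   smallest true edge magnitude, the natural choice for ground truths
#'   with equal-strength connections.
#' @return an object of class `performance_report`: counts `tp`, `fp`,
#'   `tn`, `fn` plus `fn_rate`, `fp_rate`, `sign_accuracy` and the
#'   threshold used.
#' @export
confusion_at_threshold <- function(G_est, G_true, threshold = NULL) {
  check_shapes(G_est, G_true)
  e <- offdiag(G_est); g <- offdiag(G_true)
  if (is.null(threshold)) {
    mags <- abs(g[g != 0])
    if (!length(mags)) stop("ground truth has no edges")
    threshold <- min(mags) / 2
  }
  stopifnot(threshold >= 0)
  called <- abs(e) > threshold
  truth <- g != 0
  tp <- sum(called & truth); fp <- sum(called & !truth)
  fn <- sum(!called & truth); tn <- sum(!called & !truth)
  sign_ok <- if (tp > 0) mean(sign(e[called & truth]) ==
                                sign(g[called & truth])) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 fn_rate = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
                 fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 sign_accuracy = sign_ok, threshold = threshold),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("edge calls at |weight| > %.4g\n", x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  miss rate %.1f%%   false-positive rate %.1f%%   sign accuracy %.1f%%\n",
              100 * x$fn_rate, 100 * x$fp_rate, 100 * x$sign_accuracy))
  invisible(x)
}

#' All performance measures at once
#'
#' Convenience wrapper returning AUC, average precision, Pearson
#' correlation and the confusion rates in one list, the standard panel
#' used in the benchmark sweeps.
#'
#' @inheritParams confusion_at_threshold
#' @return a named list with `auc`, `prs`, `pcc`, `fn_rate`, `fp_rate`,
#'   `sign_accuracy`.
#' @export
performance_report <- function(G_est, G_true, threshold = NULL) {
  conf <- confusion_at_threshold(G_est, G_true, threshold)
  list(auc = roc_auc(G_est, G_true),
       prs = precision_recall_score(G_est, G_true),
       pcc = pearson(G_est, G_true),
       fn_rate = conf$fn_rate, fp_rate = conf$fp_rate,
       sign_accuracy = conf$sign_accuracy)
}
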