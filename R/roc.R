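#' ROC curve over attainable score values
#'
#' Builds a receiver-operating-characteristic curve for a score against a
#' binary class label. Thresholds are the sorted unique score values plus a
#' sentinel above the maximum (so the (Se, Sp) = (0, 1) corner is always on
#' the curve); a case is called positive when its score is greater than or
#' equal to the threshold. Sensitivity is TP/(TP+FN), specificity TN/(TN+FP).
#' AUC is computed by the trapezoidal rule over (1 - Sp, Se), which for a
#' score-threshold curve equals the pairwise concordance statistic
#' (concordant + half-tied pairs over n1*n0).
#'
#' @param scores numeric score per case.
#' @param labels binary class per case: 1/TRUE = positive (diseased),
#'   0/FALSE = negative. Pairs with a missing score or label are dropped.
#' @return An object of class `cavalus_roc`: list with `thresholds`
#'   (ascending), `sensitivity`, `specificity`, `youden_j`, `auc`, `n_pos`,
#'   `n_neg`, plus the optimal operating point fields `optimal_cutoff`,
#'   `j_at_optimal`, `se_at_optimal`, `sp_at_optimal` (chosen by
#'   [youden_optimal()]).
#' @export
roc_curve <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present among scored cases")
  }
  uq <- sort(unique(scores))
  thresholds <- c(uq, Inf)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  se <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  sp <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  fpr <- 1 - sp
  # thresholds ascending => fpr and se non-increasing; integrate the
  # staircase from (0,0) to (1,1), keeping se ascending within tied fpr
  o <- order(fpr, se)
  auc <- sum(diff(fpr[o]) * (utils::head(se[o], -1) + utils::tail(se[o], -1)) / 2)
  j <- se + sp - 1
  roc <- structure(list(thresholds = thresholds, sensitivity = se,
                        specificity = sp, youden_j = j, auc = auc,
                        n_pos = n_pos, n_neg = n_neg),
                   class = "cavalus_roc")
  opt <- youden_optimal(roc)
  roc$optimal_cutoff <- opt$cutoff
  roc$j_at_optimal <- opt$j
  roc$se_at_optimal <- opt$se
  roc$sp_at_optimal <- opt$sp
  roc
}

#' Youden's J from an operating point
#'
#' J = sensitivity + specificity - 1, the vertical distance of an ROC
#' operating point above the chance diagonal.
#'
#' @param se,sp sensitivity and specificity as fractions in \[0, 1\].
#' @return Youden's J in \[-1, 1\].
#' @examples
#' youden_j(0.74, 0.91)
#' @export
youden_j <- function(se, sp) {
  check_prob(se, "sensitivity"); check_prob(sp, "specificity")
  se + sp - 1
}

#' Optimal cutoff by Youden's J
#'
#' Selects the threshold maximizing J = Se + Sp - 1 on an ROC curve. Ties are
#' broken by the smallest cutoff, i.e. the most sensitive of the equally good
#' operating points.
#'
#' @param roc a `cavalus_roc` object.
#' @return List with `cutoff`, `j`, `se`, `sp`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "cavalus_roc"))
  j <- roc$youden_j
  best <- which(j >= max(j) - 1e-12)[1L]  # thresholds ascending: first = smallest
  list(cutoff = roc$thresholds[best], j = j[best],
       se = roc$sensitivity[best], sp = roc$specificity[best])
}

#' @export
print.cavalus_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  cat(sprintf("  Youden-optimal cutoff %s: J = %.3f (Se %.0f%%, Sp %.0f%%)\n",
              format(x$optimal_cutoff), x$j_at_optimal,
              100 * x$se_at_optimal, 100 * x$sp_at_optimal))
  invisible(x)
}

#' @export
plot.cavalus_roc <- function(x, ...) {
  fpr <- 1 - x$specificity
  o <- order(fpr, x$sensitivity)
  plot(fpr[o], x$sensitivity[o], type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  i <- which(x$thresholds == x$optimal_cutoff)[1L]
  graphics::points(1 - x$specificity[i], x$sensitivity[i], pch = 19)
  invisible(x)
}
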