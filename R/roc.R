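# Placement values ("structural components") behind the DeLong machinery:
# for each positive, the fraction of negatives it outranks (ties 0.5), and
# symmetrically for negatives.
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be present")
  v10 <- vapply(pos, function(s)
    (sum(s > neg) + 0.5 * sum(s == neg)) / n, numeric(1))
  v01 <- vapply(neg, function(s)
    (sum(pos > s) + 0.5 * sum(pos == s)) / m, numeric(1))
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance
#'
#' Area under the ROC curve as the Mann-Whitney estimator (fraction of
#' positive-negative pairs in which the positive scores higher, ties
#' counted 0.5), with its sampling variance from the DeLong placement
#' values: `var(V10)/m + var(V01)/n`.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Binary class labels (1 = positive/case).
#' @return A `roc_result` list: `auc`, `variance`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pv <- placement_values(scores, labels)
  auc <- mean(pv$v10)
  v <- stats::var(pv$v10) / pv$m + stats::var(pv$v01) / pv$n
  structure(list(auc = auc, variance = v, n_pos = pv$m, n_neg = pv$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (SE %.4f; %d positives, %d negatives)\n",
              x$auc, sqrt(x$variance), x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same
#' individuals.  The test statistic is
#' `z = (auc2 - auc1) / sqrt(var1 + var2 - 2 cov)`, where the variances
#' and the covariance come from the paired placement values, and the
#' p-value is two-sided normal.
#'
#' @param scores_1,scores_2 Numeric score vectors on the same
#'   individuals.
#' @param labels Binary class labels shared by both vectors.
#' @return A `delong_comparison` list: `auc_1`, `auc_2`, `z`, `p_value`,
#'   `var_diff`.
#' @export
delong_paired <- function(scores_1, scores_2, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores_1) == length(scores_2),
            length(scores_1) == length(labels),
            all(labels %in% c(0, 1)))
  p1 <- placement_values(as.numeric(scores_1), labels)
  p2 <- placement_values(as.numeric(scores_2), labels)
  a1 <- mean(p1$v10); a2 <- mean(p2$v10)
  vd <- stats::var(p1$v10) / p1$m + stats::var(p2$v10) / p2$m -
    2 * stats::cov(p1$v10, p2$v10) / p1$m +
    stats::var(p1$v01) / p1$n + stats::var(p2$v01) / p2$n -
    2 * stats::cov(p1$v01, p2$v01) / p1$n
  if (a1 == a2 && vd <= 0) {
    z <- 0
  } else {
    if (vd <= 0) stop("zero variance of the AUC difference")
    z <- (a2 - a1) / sqrt(vd)
  }
  structure(list(auc_1 = a1, auc_2 = a2, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 var_diff = max(vd, 0)),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_1, x$auc_2, x$z, x$p_value))
  invisible(x)
}

#' Compare the discrimination of two nested logistic models
#'
#' Fits both models, takes the in-sample fitted probabilities as
#' prediction scores, and applies the paired DeLong test to their ROC
#' curves.  In-sample (apparent) discrimination is used deliberately:
#' the question answered is whether adding predictors improves apparent
#' discrimination on the same cohort, not out-of-sample performance.
#'
#' @param design_base,design_full Design matrices (with intercept) for
#'   the smaller and larger model.
#' @param outcome Binary outcome vector.
#' @return A `delong_comparison`; the two fits are attached as
#'   attributes `"fit_base"` and `"fit_full"`.
#' @export
compare_nested_models <- function(design_base, design_full, outcome) {
  fb <- fit_logistic(design_base, outcome)
  ff <- fit_logistic(design_full, outcome)
  cmp <- delong_paired(fb$fitted, ff$fitted, outcome)
  attr(cmp, "fit_base") <- fb
  attr(cmp, "fit_full") <- ff
  cmp
}

#' ROC curve points
#'
#' Sensitivity and 1-specificity at every distinct score threshold, for
#' export and plotting.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `sensitivity`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(0, 1)))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = th,
             sensitivity = vapply(th, function(t)
               mean(scores[labels == 1] >= t), numeric(1)),
             fpr = vapply(th, function(t)
               mean(scores[labels == 0] >= t), numeric(1)))
}
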