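#' AUC with a DeLong confidence interval
#'
#' The area under the ROC curve is computed by the Mann-Whitney identity
#' (midranks, so tied positive/negative pairs count one half). The
#' confidence interval uses DeLong's placement-based variance
#' `var(V10)/n_pos + var(V01)/n_neg`, with bounds clipped to `[0, 1]`;
#' perfectly separated data have zero estimated variance and a degenerate
#' interval.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical, or coercible 0/1) with both
#'   classes present.
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.2, 0.4, 0.8, 0.9), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels, alpha = 0.05) {
  lab <- check_binary(scores, labels)
  pos <- scores[lab]
  neg <- scores[!lab]
  m <- length(pos)
  n <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placements: psi(X_i, Y_j) = 1, 1/2, 0 for X > Y, X = Y, X < Y
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt(var(v10) / m + var(v01) / n)
  zcrit <- qnorm(1 - alpha / 2)
  list(auc = auc,
       ci_low = max(0, auc - zcrit * se),
       ci_high = min(1, auc + zcrit * se),
       se = se, n_pos = m, n_neg = n)
}

check_binary <- function(scores, labels) {
  if (length(scores) != length(labels) || !all(is.finite(scores)))
    ueff_stop("invalid_input", "scores must be finite and match labels in length")
  lab <- as.logical(labels)
  if (anyNA(lab))
    ueff_stop("invalid_input", "labels must be binary (logical or 0/1)")
  if (!any(lab) || all(lab))
    ueff_stop("single_class", "both classes must be present")
  lab
}

#' Youden-optimal diagnostic cutoff
#'
#' Evaluates every candidate threshold — midpoints between adjacent
#' distinct scores plus -Inf and +Inf, with the decision rule
#' `score >= cutoff` = positive — and returns the one maximising Youden's
#' J = sensitivity + specificity - 1 (equivalently TPR - FPR). Ties are
#' broken toward the higher cutoff, i.e. toward higher specificity, which
#' also makes the result invariant to the input order. `j_definition =
#' "literal"` instead maximises TPR - FNR = 2 TPR - 1 for auditability; it
#' ignores specificity, so it always selects the most permissive tied
#' cutoff and is not recommended.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels with both classes present.
#' @param j_definition `"youden"` (default) or `"literal"`.
#' @return List with `cutoff` and the achieved `j`.
#' @export
best_cutoff_youden <- function(scores, labels,
                               j_definition = c("youden", "literal")) {
  j_definition <- match.arg(j_definition)
  lab <- check_binary(scores, labels)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  m <- sum(lab)
  n <- sum(!lab)
  j <- vapply(cand, function(cut) {
    tpr <- sum(lab & scores >= cut) / m
    if (j_definition == "youden") tpr - sum(!lab & scores >= cut) / n
    else 2 * tpr - 1
  }, numeric(1))
  best <- max(which(j >= max(j) - 1e-12))  # tie -> higher cutoff
  list(cutoff = cand[best], j = j[best])
}

#' Confusion-table metrics at a fixed cutoff
#'
#' The prediction rule is `score >= cutoff` = positive. Sensitivity,
#' specificity, predictive values and total accuracy come straight from the
#' 2x2 table; a predictive value with an empty denominator (no predicted
#' positives or negatives) is `NaN`.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels with both classes present.
#' @param cutoff Decision threshold (may be infinite, not `NA`).
#' @return List with `sn`, `sp`, `ppv`, `npv`, `ta` and the table counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(scores, labels, cutoff) {
  lab <- check_binary(scores, labels)
  if (length(cutoff) != 1 || is.na(cutoff))
    ueff_stop("invalid_input", "cutoff must be a single non-NA number")
  pred <- scores >= cutoff
  tp <- sum(pred & lab)
  fp <- sum(pred & !lab)
  tn <- sum(!pred & !lab)
  fn <- sum(!pred & lab)
  list(sn = tp / (tp + fn), sp = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       ta = (tp + tn) / length(lab),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Power of the AUC-vs-0.5 test at the observed effect
#'
#' Approximate power of the two-sided z-test of the null AUC = 0.5, with
#' variances from the Hanley-McNeil approximation evaluated at the null and
#' at the observed AUC. Used to check that each binary steatosis
#' classification is large enough to keep the type II error below
#' `beta_max`.
#'
#' @param auc Observed AUC in (0, 1).
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param alpha Two-sided significance level.
#' @param beta_max Maximum tolerated type II error (default 0.10).
#' @return List with `power` and `adequate` (`power >= 1 - beta_max`).
#' @export
power_auc <- function(auc, n_pos, n_neg, alpha = 0.05, beta_max = 0.10) {
  if (!is.finite(auc) || auc <= 0 || auc >= 1)
    ueff_stop("invalid_input", "auc must be strictly inside (0, 1)")
  if (n_pos < 1 || n_neg < 1)
    ueff_stop("invalid_input", "both class counts must be >= 1")
  hm_var <- function(a) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
      (n_pos * n_neg)
  }
  s0 <- sqrt(hm_var(0.5))
  s1 <- sqrt(hm_var(auc))
  zcrit <- qnorm(1 - alpha / 2)
  delta <- auc - 0.5
  power <- pnorm((delta - zcrit * s0) / s1) + pnorm((-delta - zcrit * s0) / s1)
  list(power = power, adequate = power >= 1 - beta_max)
}

#' Full ROC evaluation of a binary classification task
#'
#' Bundles [roc_auc()], [best_cutoff_youden()], [classification_metrics()]
#' at the selected cutoff, and [power_auc()] into the row format of a
#' diagnostic-performance table.
#'
#' @param scores Numeric classifier scores (e.g. UEFF in percent).
#' @param labels Binary labels (e.g. MRI-PDFF >= 5%).
#' @param alpha Two-sided level for the AUC CI and the power test.
#' @param beta_max Maximum tolerated type II error for the power check.
#' @param j_definition Passed to [best_cutoff_youden()].
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sn`, `sp`, `ppv`, `npv`, `ta`, `power`, `adequate`,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, alpha = 0.05, beta_max = 0.10,
                         j_definition = "youden") {
  a <- roc_auc(scores, labels, alpha = alpha)
  cut <- best_cutoff_youden(scores, labels, j_definition = j_definition)
  met <- classification_metrics(scores, labels, cut$cutoff)
  pw <- if (a$auc > 0 && a$auc < 1)
    power_auc(a$auc, a$n_pos, a$n_neg, alpha = alpha, beta_max = beta_max)
  else list(power = 1, adequate = TRUE)  # separation: test always rejects
  structure(list(auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
                 cutoff = cut$cutoff, j = cut$j,
                 sn = met$sn, sp = met$sp, ppv = met$ppv, npv = met$npv,
                 ta = met$ta, power = pw$power, adequate = pw$adequate,
                 n_pos = a$n_pos, n_neg = a$n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (CI %.3f-%.3f), cutoff = %.3g\n",
              x$auc, x$ci_low, x$ci_high, x$cutoff))
  cat(sprintf("SN %.2f SP %.2f PPV %.2f NPV %.2f TA %.2f, power %.2f (n+ %d, n- %d)\n",
              x$sn, x$sp, x$ppv, x$npv, x$ta, x$power, x$n_pos, x$n_neg))
  invisible(x)
}
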