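#' Pearson correlation with a Fisher-z confidence interval
#'
#' The confidence interval is
#' `tanh(atanh(rho) +/- z_(1-alpha/2) / sqrt(n - 3))` and the two-sided
#' p-value comes from the t transform `rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom. A perfectly linear relationship
#' (`|rho| = 1`) yields the degenerate interval `(rho, rho)`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), finite,
#'   non-constant.
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @param range_used Optional PDFF interval annotation (used by
#'   [subrange_correlation_scan()]).
#' @return An object of class `correlation_result`: `rho`, `ci_low`,
#'   `ci_high`, `n`, `p_value`, `range_used`.
#' @examples
#' set.seed(1)
#' x <- rnorm(90)
#' pearson_with_ci(x, x + rnorm(90))
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05, range_used = NULL) {
  if (length(x) != length(y) || !all(is.finite(x)) || !all(is.finite(y)))
    ueff_stop("invalid_input", "x and y must be finite vectors of equal length")
  n <- length(x)
  if (n < 4)
    ueff_stop("invalid_input", "at least 4 paired observations required")
  if (sd(x) == 0 || sd(y) == 0)
    ueff_stop("degenerate_input", "correlation is undefined for constant input")
  rho <- cor(x, y)
  if (abs(rho) >= 1 - 1e-14) {
    ci <- c(rho, rho)
    p <- 0
  } else {
    zcrit <- qnorm(1 - alpha / 2)
    ci <- tanh(atanh(rho) + c(-1, 1) * zcrit / sqrt(n - 3))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
                 p_value = p, range_used = range_used),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho = %.3f, CI = %.3f-%.3f, n = %d, p = %.3g%s\n",
              x$rho, x$ci_low, x$ci_high, x$n, x$p_value,
              if (!is.null(x$range_used))
                sprintf(" (PDFF range %.3g-%.3g)", x$range_used[1],
                        x$range_used[2]) else ""))
  invisible(x)
}

#' Find the PDFF sub-range where UEFF correlates most strongly
#'
#' Saturation of the ultrasound parameters at high fat fractions weakens the
#' UEFF-PDFF correlation in the upper range; this exploratory scan searches
#' all contiguous PDFF intervals whose endpoints are observed values and
#' which retain at least `min_fraction` of the records (and at least 4),
#' returning the interval that maximises the Pearson correlation. Ties
#' (within 1e-12) are broken toward the widest interval, so perfectly
#' linear data return the full range.
#'
#' @param pdff Observed MRI-PDFF values (the range variable).
#' @param ueff Predicted fat fraction values.
#' @param min_fraction Minimum fraction of records an interval must keep.
#' @param alpha CI level passed to [pearson_with_ci()].
#' @return A `correlation_result` with `range_used` set to the winning
#'   interval.
#' @export
subrange_correlation_scan <- function(pdff, ueff, min_fraction = 0.5,
                                      alpha = 0.05) {
  if (length(pdff) != length(ueff))
    ueff_stop("invalid_input", "pdff and ueff must have equal length")
  n <- length(pdff)
  min_n <- max(4, ceiling(min_fraction * n))
  if (min_n > n)
    ueff_stop("invalid_input", "no admissible interval: min_fraction too large")
  ends <- sort(unique(pdff))
  best <- NULL
  for (i in seq_along(ends)) {
    for (j in i:length(ends)) {
      inside <- pdff >= ends[i] & pdff <= ends[j]
      if (sum(inside) < min_n) next
      if (sd(pdff[inside]) == 0 || sd(ueff[inside]) == 0) next
      rho <- cor(pdff[inside], ueff[inside])
      width <- ends[j] - ends[i]
      if (is.null(best) || rho > best$rho + 1e-12 ||
          (abs(rho - best$rho) <= 1e-12 && width > best$width)) {
        best <- list(rho = rho, lo = ends[i], hi = ends[j], width = width,
                     inside = inside)
      }
    }
  }
  if (is.null(best))
    ueff_stop("invalid_input", "no admissible interval with non-degenerate data")
  pearson_with_ci(pdff[best$inside], ueff[best$inside], alpha = alpha,
                  range_used = c(best$lo, best$hi))
}

#' Simple linear regression of y on x
#'
#' Ordinary least squares with the slope p-value from its t-test; used to
#' report the slope and intercept of the UEFF-to-PDFF identity check.
#'
#' @param x,y Numeric vectors (n >= 3, x non-constant).
#' @return List with `slope`, `intercept`, `p_value`, `r2`.
#' @export
simple_linreg <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    ueff_stop("invalid_input", "need at least 3 paired observations")
  if (sd(x) == 0)
    ueff_stop("degenerate_input", "x is constant; slope undefined")
  fit <- lm(y ~ x)
  s <- summary_lm_quiet(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = s$coefficients[2, 4], r2 = s$r.squared)
}

#' Univariable and multivariable linear screening of PDFF predictors
#'
#' Reproduces the layout of a regression-screen table: each predictor is
#' first regressed alone against the outcome, then all predictors enter one
#' joint model. Every row reports the model's adjusted R-squared, overall F
#' statistic, the predictor's coefficient, and its t-test p-value; the
#' multivariable rows share the joint model's adjusted R-squared and F.
#'
#' @param x A [cohort()]; rows with missing values in the used columns are
#'   dropped (complete-case analysis).
#' @param predictors Column names to screen (default the four imaging /
#'   anthropometric candidates).
#' @param outcome Outcome column (default `"pdff"`).
#' @return A data frame of class `linreg_screen` with columns `analysis`
#'   (`"univariable"`/`"multivariable"`), `predictor`, `adj_r2`, `f_stat`,
#'   `beta`, `p_value`.
#' @export
fit_linear_models <- function(x, predictors = c("ac", "bscd", "ls", "bmi"),
                              outcome = "pdff") {
  stopifnot(inherits(x, "ueff_cohort"))
  missing_cols <- setdiff(c(predictors, outcome), names(x))
  if (length(missing_cols))
    ueff_stop("missing_column",
              sprintf("cohort lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  dat <- as.data.frame(x)[, c(outcome, predictors)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2)
    ueff_stop("invalid_input", "too few complete cases for the multivariable model")
  uni <- do.call(rbind, lapply(predictors, function(p) {
    fit <- lm(stats::reformulate(p, outcome), data = dat)
    s <- summary_lm_quiet(fit)
    data.frame(analysis = "univariable", predictor = p,
               adj_r2 = s$adj.r.squared, f_stat = unname(s$fstatistic[1]),
               beta = unname(coef(fit)[2]), p_value = s$coefficients[2, 4],
               stringsAsFactors = FALSE)
  }))
  multi_fit <- lm(stats::reformulate(predictors, outcome), data = dat)
  if (anyNA(coef(multi_fit)))
    ueff_stop("collinearity",
              "exact collinearity among predictors; multivariable model is rank-deficient")
  s <- summary_lm_quiet(multi_fit)
  multi <- data.frame(analysis = "multivariable", predictor = predictors,
                      adj_r2 = s$adj.r.squared,
                      f_stat = unname(s$fstatistic[1]),
                      beta = unname(coef(multi_fit)[predictors]),
                      p_value = s$coefficients[predictors, 4],
                      stringsAsFactors = FALSE)
  out <- rbind(uni, multi)
  rownames(out) <- NULL
  structure(out, class = c("linreg_screen", "data.frame"))
}

#' Kruskal-Wallis test with Dunn post hoc comparisons and Holm adjustment
#'
#' The omnibus H statistic uses the standard tie correction
#' (via [stats::kruskal.test()]) with a chi-square p-value on g - 1 degrees
#' of freedom. Pairwise Dunn z-tests compare mean ranks with the
#' tie-corrected pooled variance
#' `(N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tie groups; two-sided p-values are adjusted by
#' Holm's step-down method across all pairs. If every observation is equal,
#' the test is degenerate and reported as `H = 0`, `p = 1` by convention.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 non-empty groups, >= 3 observations).
#' @param alpha Significance level recorded on the result.
#' @return An object of class `group_test`: `H`, `df`, `p_value`, and
#'   `pairwise` (data frame with `group1`, `group2`, `z`, `p_raw`,
#'   `p_holm`).
#' @export
kruskal_wallis_dunn <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    ueff_stop("invalid_input", "at least two non-empty groups required")
  if (length(values) != length(groups) || length(values) < 3)
    ueff_stop("invalid_input", "need matching values/groups with >= 3 observations")
  g <- nlevels(groups)
  pairs <- utils::combn(levels(groups), 2)
  if (length(unique(values)) == 1) {
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           z = 0, p_raw = 1, p_holm = 1,
                           stringsAsFactors = FALSE)
    return(structure(list(H = 0, df = g - 1, p_value = 1,
                          pairwise = pairwise, alpha = alpha),
                     class = "group_test"))
  }
  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(base_var * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p_raw = p_raw,
                         p_holm = stats::p.adjust(p_raw, method = "holm"),
                         stringsAsFactors = FALSE)
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pairwise, alpha = alpha),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d), p = %.3g\n",
              x$H, x$df, x$p_value))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}


# summary.lm warns on exact fits ("essentially perfect fit"); such data are
# legitimate here (noiseless calibration checks), so that warning is muted.
summary_lm_quiet <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
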