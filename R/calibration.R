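#' Fit a single-predictor exponential calibration model
#'
#' Estimates `PDFF = b1 * exp(b2 * x) + b3` by iterative non-linear least
#' squares (Levenberg-Marquardt), the calibration law used to convert a
#' quantitative ultrasound parameter into a fat fraction. Start values are
#' deterministic and documented: `b3` starts at `min(y)`, then `b2` and
#' `b1` come from an ordinary least-squares line fitted to
#' `log(y - b3 + eps)` on `x`, with `eps = 1e-6 + 0.001 * diff(range(y))`
#' guarding the logarithm. Convergence is declared when the relative change
#' in the residual sum of squares falls below `1e-10`, with an iteration cap
#' of 500; both are recorded in `fit_meta`.
#'
#' @param x Numeric predictor (AC in dB/cm/MHz or BSC-D in a.u.).
#' @param y Observed MRI-PDFF in percent.
#' @param kind `"AC"` or `"BSCD"`; recorded on the model and used by
#'   [predict_ueff()] to pick the right cohort column.
#' @return An object of class `calibration_model`: `kind`, `coefficients`
#'   (`b1`, `b2`, `b3`), `n_predictors = 1`, and `fit_meta` (convergence
#'   flag, iterations, final SSE, start values).
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' m <- fit_single_model(x, 2 * exp(3 * x) + 1, kind = "AC")
#' coef(m)
#' @export
fit_single_model <- function(x, y, kind = c("AC", "BSCD")) {
  kind <- match.arg(kind)
  check_fit_inputs(list(x = x), y, min_n = 4)
  # Optimise on the standardised predictor (a pure reparameterisation:
  # b1' exp(b2' z) = b1 exp(b2 x) with z = (x - mx)/sx), which conditions
  # the Jacobian when the predictor scale is far from 1, then map back.
  mx <- mean(x)
  sx <- sd(x)
  z <- (x - mx) / sx
  start <- exp_start_values(z, y)
  fit <- lm_minimise(function(b) y - (b[1] * exp(b[2] * z) + b[3]),
                     unlist(start))
  b <- unscale_exp(fit$par[1], fit$par[2], mx, sx)
  new_calibration_model(kind, c(b1 = b$b1, b2 = b$b2, b3 = fit$par[3]),
                        n_predictors = 1L, fit = fit, start = start)
}

# Map coefficients of b1' * exp(b2' * (x - mx)/sx) back to b1 * exp(b2 * x).
unscale_exp <- function(b1s, b2s, mx, sx) {
  list(b1 = b1s * exp(-b2s * mx / sx), b2 = b2s / sx)
}

#' Fit the combined AC + BSC-D calibration model
#'
#' The two-predictor form is additive with a shared offset,
#' `PDFF = b1 * exp(b2 * AC) + b3 * exp(b4 * BSCD) + b5`, so each
#' predictor's marginal shape equals the single-predictor law while the
#' extra exponential term lets the second parameter absorb residual
#' structure. Start values chain the single-predictor heuristic: the AC-only
#' model is fitted first, then its residuals seed the BSC-D term. A
#' near-perfect linear dependence between the two predictors
#' (|correlation| > 0.999) is flagged in `fit_meta$collinear` and raised as
#' a warning, since the coefficients are then poorly identified.
#'
#' @param ac Attenuation coefficients (dB/cm/MHz).
#' @param bscd Backscatter-distribution coefficients (a.u.).
#' @param y Observed MRI-PDFF in percent.
#' @return A `calibration_model` with `kind = "COMBINED"`, coefficients
#'   `b1..b5`, and `n_predictors = 2`.
#' @export
fit_combined_model <- function(ac, bscd, y) {
  check_fit_inputs(list(ac = ac, bscd = bscd), y, min_n = 7)
  collinear <- abs(cor(ac, bscd)) > 0.999
  if (collinear)
    warning("fit_combined_model: AC and BSC-D are (near-)collinear; coefficients are ill-conditioned")
  ma <- mean(ac)
  sa <- sd(ac)
  mb <- mean(bscd)
  sb <- sd(bscd)
  za <- (ac - ma) / sa
  zb <- (bscd - mb) / sb
  start_a <- exp_start_values(za, y)
  m_ac <- lm_minimise(function(b) y - (b[1] * exp(b[2] * za) + b[3]),
                      unlist(start_a))
  resid_y <- y - m_ac$par[1] * exp(m_ac$par[2] * za)
  start_b <- tryCatch(exp_start_values(zb, resid_y),
                      error = function(e) list(b1 = 1, b2 = 0.5,
                                               b3 = min(resid_y)))
  start <- list(b1 = m_ac$par[1], b2 = m_ac$par[2],
                b3 = start_b$b1, b4 = start_b$b2, b5 = start_b$b3)
  fit <- lm_minimise(function(b)
    y - (b[1] * exp(b[2] * za) + b[3] * exp(b[4] * zb) + b[5]),
    unlist(start))
  bac <- unscale_exp(fit$par[1], fit$par[2], ma, sa)
  bbs <- unscale_exp(fit$par[3], fit$par[4], mb, sb)
  new_calibration_model("COMBINED",
                        c(b1 = bac$b1, b2 = bac$b2, b3 = bbs$b1,
                          b4 = bbs$b2, b5 = fit$par[5]),
                        n_predictors = 2L, fit = fit, start = start,
                        collinear = collinear)
}

# Levenberg-Marquardt least-squares driver. Overflowing residuals (huge
# exponents probed by a trial step) are capped so the step is rejected
# rather than poisoning the algorithm with non-finite values.
lm_minimise <- function(resid_fn, start) {
  safe <- function(b) {
    r <- resid_fn(b)
    r[!is.finite(r)] <- 1e150
    pmin(pmax(r, -1e150), 1e150)
  }
  minpack.lm::nls.lm(par = unname(start), fn = safe,
                     control = minpack.lm::nls.lm.control(
                       ftol = 1e-10, maxiter = 500, maxfev = 10000))
}

#' Fit a calibration model of a given kind directly on a cohort
#'
#' Thin dispatcher used by the cross-validation and pipeline stages.
#'
#' @param x A [cohort()] with observed `pdff`.
#' @param kind `"AC"`, `"BSCD"` or `"COMBINED"`.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(x, kind = c("COMBINED", "AC", "BSCD")) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "ueff_cohort"))
  switch(kind,
         AC = fit_single_model(x$ac, x$pdff, kind = "AC"),
         BSCD = fit_single_model(x$bscd, x$pdff, kind = "BSCD"),
         COMBINED = fit_combined_model(x$ac, x$bscd, x$pdff))
}

check_fit_inputs <- function(preds, y, min_n) {
  n <- length(y)
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (length(p) != n || !all(is.finite(p)))
      ueff_stop("invalid_input", sprintf("'%s' must be finite and match y in length", nm))
    if (sd(p) == 0)
      ueff_stop("degenerate_input",
                sprintf("predictor '%s' is constant; the exponential rate is unidentifiable", nm))
  }
  if (!all(is.finite(y)))
    ueff_stop("invalid_input", "y must be finite")
  if (n < min_n)
    ueff_stop("invalid_input",
              sprintf("at least %d observations required, got %d", min_n, n))
}

# Deterministic log-linearisation start values for y ~ b1*exp(b2*x) + b3.
exp_start_values <- function(x, y) {
  b3 <- min(y)
  eps <- 1e-6 + 0.001 * diff(range(y))
  ly <- log(y - b3 + eps)
  sl <- cov(x, ly) / var(x)
  list(b1 = exp(mean(ly) - sl * mean(x)), b2 = sl, b3 = b3)
}

new_calibration_model <- function(kind, coefs, n_predictors, fit, start,
                                  collinear = FALSE) {
  # nls.lm info codes 1-4 are proper convergence (ftol / xtol / both /
  # gtol); 5 and 9 are evaluation and iteration limits.
  meta <- list(converged = fit$info %in% 1:4, iterations = fit$niter,
               sse = fit$deviance, start = lapply(start, unname),
               message = fit$message, collinear = collinear,
               ftol = 1e-10, max_iterations = 500L)
  if (!meta$converged)
    ueff_stop("non_convergence",
              sprintf("non-linear least squares did not converge after %d iterations (SSE %.6g): %s",
                      meta$iterations, meta$sse, meta$message),
              fit_meta = meta)
  structure(list(kind = kind, coefficients = coefs,
                 n_predictors = n_predictors, fit_meta = meta),
            class = "calibration_model")
}

#' @export
coef.calibration_model <- function(object, ...) object$coefficients

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s (%d predictor%s)\n", x$kind,
              x$n_predictors, if (x$n_predictors > 1) "s" else ""))
  print(signif(x$coefficients, 6))
  cat(sprintf("converged in %d iterations, SSE = %.6g\n",
              x$fit_meta$iterations, x$fit_meta$sse))
  invisible(x)
}

#' Evaluate a calibration model on new predictor values
#'
#' @param object A `calibration_model`.
#' @param newdata Data frame (or cohort) with column `ac` and/or `bscd` as
#'   the model requires.
#' @param ... Unused.
#' @return Numeric vector of predicted fat fractions (percent). Predictions
#'   are not clipped: a slightly negative estimate for a very lean liver is
#'   a legitimate model output.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  b <- object$coefficients
  need <- switch(object$kind, AC = "ac", BSCD = "bscd",
                 COMBINED = c("ac", "bscd"))
  missing_cols <- setdiff(need, names(newdata))
  if (length(missing_cols))
    ueff_stop("missing_predictor",
              sprintf("newdata lacks predictor column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  switch(object$kind,
         AC = b[["b1"]] * exp(b[["b2"]] * newdata$ac) + b[["b3"]],
         BSCD = b[["b1"]] * exp(b[["b2"]] * newdata$bscd) + b[["b3"]],
         COMBINED = b[["b1"]] * exp(b[["b2"]] * newdata$ac) +
           b[["b3"]] * exp(b[["b4"]] * newdata$bscd) + b[["b5"]])
}

#' Fill the ultrasound-estimated fat fraction of a cohort
#'
#' Applies a fitted calibration model to every record and stores the result
#' in the `ueff` column. Record order is preserved and predictions are not
#' clipped (negative UEFF values are legal and occur in lean livers).
#'
#' @param model A converged `calibration_model`.
#' @param x A [cohort()] containing the predictors the model needs.
#' @return The cohort with its `ueff` column (re)filled.
#' @export
predict_ueff <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"), inherits(x, "ueff_cohort"))
  x$ueff <- predict(model, x)
  x
}

#' Goodness-of-fit diagnostics for a calibration model on a cohort
#'
#' Computes `r2 = 1 - SSres/SStot`, the adjusted R-squared
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` with `p` equal to the number of
#' ultrasound predictors (1 or 2, not the raw coefficient count), and the
#' root mean square error of prediction in percent PDFF. On external data
#' both R-squared values may be negative; they are returned unclamped.
#'
#' @param model A `calibration_model`.
#' @param x A [cohort()] with observed `pdff`.
#' @return An object of class `fit_diagnostics` (one-row data frame with
#'   columns `r2`, `adj_r2`, `rmse`, `n`, `p`).
#' @export
model_diagnostics <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"), inherits(x, "ueff_cohort"))
  y <- x$pdff
  n <- length(y)
  p <- model$n_predictors
  if (n <= p + 1)
    ueff_stop("invalid_input",
              sprintf("need n > p + 1 (= %d) observations for adjusted R2, got %d",
                      p + 1, n))
  res <- y - predict(model, x)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(data.frame(r2 = r2,
                       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                       rmse = sqrt(mean(res^2)), n = n, p = p),
            class = c("fit_diagnostics", "data.frame"))
}

#' Serialise / restore a calibration model as JSON
#'
#' Coefficients are written at 17 significant digits, so a round trip
#' reproduces the model bit-exactly.
#'
#' @param model A `calibration_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `model_to_json()`: JSON string or `path` invisibly;
#'   `model_from_json()`: a `calibration_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  json <- jsonlite::toJSON(list(kind = model$kind,
                                coefficients = as.list(model$coefficients),
                                n_predictors = model$n_predictors,
                                fit_meta = model$fit_meta),
                           auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json)
  structure(list(kind = lst$kind,
                 coefficients = unlist(lst$coefficients),
                 n_predictors = as.integer(lst$n_predictors),
                 fit_meta = lst$fit_meta),
            class = "calibration_model")
}
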