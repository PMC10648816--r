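#' Repeated k-fold cross-validation of a calibration model
#'
#' For each of `repeats` replications, a seeded shuffle partitions the
#' cohort into `k` disjoint folds whose sizes differ by at most one; the
#' model is refitted on the other `k - 1` folds and [model_diagnostics()]
#' are computed on the held-out fold. The default scheme (`k = 3`,
#' `repeats = 5`) yields 15 validation-fold diagnostics, summarised as the
#' mean and sample SD (n - 1 denominator) of the adjusted R-squared and
#' RMSE. Partitioning is plain random (not stratified by grade). A fold
#' whose refit fails to converge is excluded from the aggregate with a
#' warning, never silently.
#'
#' @param x A [cohort()] with observed `pdff`.
#' @param kind Model kind passed to [fit_calibration()].
#' @param k Number of folds (cohort must have at least `3 * k` records so
#'   every training set supports the fit).
#' @param repeats Number of repetitions.
#' @param seed Integer seed; per-repeat shuffles derive from it, so the same
#'   seed reproduces the fold assignment and the full result exactly.
#' @return An object of class `cv_result`: `folds` (data frame with one row
#'   per evaluated fold: `repeat_`, `fold`, `r2`, `adj_r2`, `rmse`, `n`),
#'   `mean_adj_r2`, `sd_adj_r2`, `mean_rmse`, `sd_rmse`, `n_excluded`, and
#'   `scheme`.
#' @export
repeated_kfold_cv <- function(x, kind = c("COMBINED", "AC", "BSCD"),
                              k = 3, repeats = 5, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "ueff_cohort"))
  n <- nrow(x)
  if (n < 3 * k)
    ueff_stop("invalid_input",
              sprintf("cross-validation needs n >= 3k (= %d), got %d", 3 * k, n))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  rows <- list()
  excluded <- 0L
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    perm <- sample.int(n)
    fold_of <- integer(n)
    fold_of[perm] <- rep(seq_len(k), length.out = n)
    for (f in seq_len(k)) {
      test_idx <- which(fold_of == f)
      fit <- tryCatch(fit_calibration(x[-test_idx, , drop = FALSE], kind),
                      ueff_error = function(e) e)
      if (inherits(fit, "ueff_error")) {
        excluded <- excluded + 1L
        warning(sprintf("repeated_kfold_cv: repeat %d fold %d excluded (%s)",
                        r, f, conditionMessage(fit)))
        next
      }
      d <- model_diagnostics(fit, x[test_idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, r2 = d$r2, adj_r2 = d$adj_r2,
                   rmse = d$rmse, n = d$n)
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean_adj_r2 = mean(folds$adj_r2),
                 sd_adj_r2 = sd(folds$adj_r2),
                 mean_rmse = mean(folds$rmse),
                 sd_rmse = sd(folds$rmse),
                 n_excluded = excluded,
                 scheme = list(k = k, repeats = repeats, seed = seed,
                               kind = kind)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s model, %d-fold CV x %d repeats (seed %d): %d folds%s\n",
              x$scheme$kind, x$scheme$k, x$scheme$repeats, x$scheme$seed,
              nrow(x$folds),
              if (x$n_excluded) sprintf(" (%d excluded)", x$n_excluded) else ""))
  cat(sprintf("adj R2 = %.3f +/- %.3f, RMSE = %.3f%% +/- %.3f%%\n",
              x$mean_adj_r2, x$sd_adj_r2, x$mean_rmse, x$sd_rmse))
  invisible(x)
}

#' Test a frozen calibration model on an external cohort
#'
#' The model is applied as-is (no refitting) to an independent cohort —
#' the design used to check that a model calibrated on one disease group
#' transfers to another. Returns both the goodness-of-fit diagnostics and
#' the Pearson correlation (with Fisher-z CI) between predicted and
#' observed fat fraction. Disjointness from the training data is the
#' caller's responsibility; cohort labels/provenance document it.
#'
#' @param model A converged `calibration_model`.
#' @param x The external test [cohort()] with observed `pdff`.
#' @param alpha Two-sided confidence level for the correlation CI.
#' @return A list of class `external_test`: `diagnostics`
#'   ([model_diagnostics()]) and `correlation` ([pearson_with_ci()]).
#' @export
external_test <- function(model, x, alpha = 0.05) {
  d <- model_diagnostics(model, x)
  corr <- pearson_with_ci(predict(model, x), x$pdff, alpha = alpha)
  structure(list(diagnostics = d, correlation = corr,
                 cohort = cohort_label(x)),
            class = "external_test")
}

#' Serialise a cross-validation result as JSON
#'
#' @param cv A `cv_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
cv_to_json <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  json <- jsonlite::toJSON(unclass(cv), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
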