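#' Severity-grade thresholds for steatosis and fibrosis
#'
#' Steatosis is graded from MRI-PDFF at 5, 10 and 20 percent (none, mild,
#' moderate, severe); fibrosis is staged from liver stiffness by the "rule
#' of four" at 5, 9 and 13 kPa (F2, F3, F4). All cuts are lower-inclusive:
#' a value equal to a threshold falls in the higher grade, matching the
#' ">=" convention of the dichotomised classification tasks.
#'
#' @param steatosis_cuts Strictly increasing positive cut points (% PDFF).
#' @param fibrosis_cuts Strictly increasing positive cut points (kPa).
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(steatosis_cuts = c(5, 10, 20),
                             fibrosis_cuts = c(5, 9, 13)) {
  for (cuts in list(steatosis_cuts, fibrosis_cuts))
    if (length(cuts) != 3 || any(cuts <= 0) || any(diff(cuts) <= 0))
      ueff_stop("invalid_thresholds",
                "cut points must be three strictly increasing positive values")
  structure(list(steatosis_cuts = steatosis_cuts, fibrosis_cuts = fibrosis_cuts),
            class = "grade_thresholds")
}

steatosis_levels <- c("S0", "S1", "S2", "S3")
fibrosis_levels <- c("F0/F1", "F2", "F3", "F4")

#' Grade hepatic steatosis from MRI-PDFF
#'
#' @param pdff Numeric vector of fat fractions in percent (non-negative).
#' @param thresholds A [grade_thresholds()] object.
#' @return Ordered factor with levels `S0 < S1 < S2 < S3`
#'   (none, mild, moderate, severe).
#' @examples
#' steatosis_grade(c(2, 5, 12.1, 44.6))
#' @export
steatosis_grade <- function(pdff, thresholds = grade_thresholds()) {
  if (any(!is.finite(pdff) | pdff < 0))
    ueff_stop("invalid_input", "pdff must be finite and >= 0")
  cut_ordinal(pdff, thresholds$steatosis_cuts, steatosis_levels)
}

#' Stage liver fibrosis from stiffness
#'
#' @param ls Numeric vector of liver stiffness in kPa (positive).
#' @param thresholds A [grade_thresholds()] object.
#' @return Ordered factor with levels `F0/F1 < F2 < F3 < F4`.
#' @export
fibrosis_grade <- function(ls, thresholds = grade_thresholds()) {
  if (any(!is.finite(ls) | ls <= 0))
    ueff_stop("invalid_input", "ls must be finite and > 0")
  cut_ordinal(ls, thresholds$fibrosis_cuts, fibrosis_levels)
}

# Lower-inclusive ordinal binning at three cuts.
cut_ordinal <- function(x, cuts, levels) {
  idx <- 1L + (x >= cuts[1]) + (x >= cuts[2]) + (x >= cuts[3])
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Grade counts and percentages for a cohort
#'
#' Tabulates steatosis grades (from `pdff`) and fibrosis grades (from `ls`)
#' including empty grades, with percentages of the cohort size.
#'
#' @param x A [cohort()].
#' @param thresholds A [grade_thresholds()] object.
#' @return A data frame with columns `scale`, `grade`, `n`, `pct`.
#' @export
grade_counts <- function(x, thresholds = grade_thresholds()) {
  stopifnot(inherits(x, "ueff_cohort"))
  tab <- function(scale, grades) {
    cnt <- table(grades)
    data.frame(scale = scale, grade = names(cnt), n = as.integer(cnt),
               pct = 100 * as.integer(cnt) / nrow(x),
               stringsAsFactors = FALSE)
  }
  rbind(tab("steatosis", steatosis_grade(x$pdff, thresholds)),
        tab("fibrosis", fibrosis_grade(x$ls, thresholds)))
}
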