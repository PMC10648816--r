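#' Aggregate repeated quantitative-ultrasound measurements into one value
#'
#' Applies the per-modality validity and aggregation rules used for liver
#' quantitative ultrasound:
#'
#' * `TAI` (tissue attenuation imaging, attenuation coefficient in
#'   dB/cm/MHz): readings whose regression fit quality (R-squared) is below
#'   0.6 are discarded; at least five valid readings must remain, and their
#'   arithmetic mean is returned.
#' * `TSI` (tissue scatter distribution imaging, backscatter-distribution
#'   coefficient, arbitrary units): no per-reading quality metric exists; at
#'   least five readings are required and their mean is returned.
#' * `SWE` (shear wave elastography, liver stiffness in kPa): readings with
#'   a reliable measure index (RMI) below 0.4 are discarded; at least five
#'   valid readings must remain and their interquartile-range-to-median
#'   ratio must be below 0.30 before the mean is returned.
#'
#' Quartiles for the IQR/median rule use linear interpolation between order
#' statistics (`stats::quantile()` type 7), so the dispersion rule is
#' reproducible across implementations.
#'
#' @param values Numeric vector of raw readings, all from the same modality.
#' @param quality Numeric vector of per-reading quality metrics in `[0, 1]`
#'   (fit R-squared for TAI, RMI for SWE). Ignored for TSI; mandatory for
#'   TAI and SWE.
#' @param modality One of `"TAI"`, `"TSI"`, `"SWE"`.
#' @return The aggregated (mean) value as a single number.
#' @examples
#' aggregate_measurements(c(0.80, 0.82, 0.81, 0.79, 0.83),
#'                        quality = rep(0.9, 5), modality = "TAI")
#' @export
aggregate_measurements <- function(values, quality = NULL,
                                   modality = c("TAI", "TSI", "SWE")) {
  modality <- match.arg(modality)
  if (!is.numeric(values) || length(values) == 0 || !all(is.finite(values)))
    ueff_stop("invalid_measurement", "all measurement values must be finite numbers")
  if (modality %in% c("TAI", "SWE")) {
    if (is.null(quality))
      ueff_stop("modality_mismatch",
                sprintf("%s measurements require a quality metric per reading", modality))
    if (length(quality) != length(values) || !all(is.finite(quality)) ||
        any(quality < 0 | quality > 1))
      ueff_stop("invalid_measurement", "quality metrics must be finite and in [0, 1]")
    cut <- if (modality == "TAI") 0.6 else 0.4
    keep <- values[quality >= cut]
  } else {
    keep <- values
  }
  if (length(keep) < 5)
    ueff_stop("insufficient_measurements",
              sprintf("%s: %d valid measurement(s), at least 5 required",
                      modality, length(keep)))
  if (modality == "SWE") {
    disp <- unname(stats::IQR(keep, type = 7) / median(keep))
    if (disp >= 0.30)
      ueff_stop("dispersion_too_high",
                sprintf("SWE IQR/median = %.3f, must be < 0.30", disp),
                dispersion = disp)
  }
  mean(keep)
}

#' Construct a validated patient cohort
#'
#' A cohort is a data frame of one row per subject carrying the aggregated
#' imaging parameters (AC, BSC-D, LS, MRI-PDFF) and clinical covariates,
#' with a label and a provenance string. Row-level invariants are enforced:
#' positive AC, BSC-D and LS; MRI-PDFF in `[0, 100]`; unique ids. A `ueff`
#' column (the model-predicted fat fraction, which may legitimately be
#' negative) is optional and filled by [predict_ueff()].
#'
#' @param records Data frame with at least the columns `id`, `group`
#'   (`"NAFLD"` or `"MAFLD"`), `ac`, `bscd`, `ls`, `pdff`; optional columns
#'   `age`, `sex`, `bmi`, `t2dm`, `etiology`, `ueff`.
#' @param label Short cohort label, e.g. `"NAFLD"`.
#' @param provenance Free-text origin (file path or generator description).
#' @return An object of class `ueff_cohort` (a data frame).
#' @export
cohort <- function(records, label = "cohort", provenance = "in-memory") {
  required <- c("id", "group", "ac", "bscd", "ls", "pdff")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    ueff_stop("missing_column",
              sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              columns = missing_cols)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    ueff_stop("empty_cohort", "a cohort must contain at least one record")
  for (col in c("ac", "bscd", "ls", "pdff"))
    if (!is.numeric(records[[col]]))
      ueff_stop("unparseable_numeric", sprintf("column '%s' is not numeric", col))
  records$id <- as.character(records$id)
  records$group <- as.character(records$group)
  if (anyDuplicated(records$id))
    ueff_stop("duplicate_id",
              sprintf("duplicate id(s): %s",
                      paste(unique(records$id[duplicated(records$id)]),
                            collapse = ", ")))
  bad <- record_violations(records)
  if (any(bad != ""))
    ueff_stop("invalid_record",
              sprintf("%d record(s) violate invariants, e.g. row %d: %s",
                      sum(bad != ""), which(bad != "")[1],
                      bad[bad != ""][1]))
  structure(records, class = c("ueff_cohort", "data.frame"),
            label = label, provenance = provenance)
}

# One diagnostic string per row; "" if the row satisfies every invariant.
record_violations <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    msgs <- character()
    if (!r$group %in% c("NAFLD", "MAFLD"))
      msgs <- c(msgs, sprintf("group '%s' not NAFLD/MAFLD", r$group))
    for (col in c("ac", "bscd", "ls"))
      if (!is.finite(r[[col]]) || r[[col]] <= 0)
        msgs <- c(msgs, sprintf("%s = %s not > 0", col, format(r[[col]])))
    if (!is.finite(r$pdff) || r$pdff < 0 || r$pdff > 100)
      msgs <- c(msgs, sprintf("pdff = %s outside [0, 100]", format(r$pdff)))
    paste(msgs, collapse = "; ")
  }, character(1))
}

#' @export
print.ueff_cohort <- function(x, ...) {
  cat(sprintf("<ueff_cohort> %s: %d records (provenance: %s)\n",
              attr(x, "label"), nrow(x), attr(x, "provenance")))
  NextMethod()
}

#' Cohort label and provenance accessors
#'
#' @param x A `ueff_cohort`.
#' @return A character scalar.
#' @export
cohort_label <- function(x) attr(x, "label")

#' @rdname cohort_label
#' @export
cohort_provenance <- function(x) attr(x, "provenance")

#' Read a patient cohort from a CSV file
#'
#' Expects a comma-separated, UTF-8, header-first file with "." as the
#' decimal mark and the columns described in [cohort()]. Rows violating the
#' record invariants are dropped with a warning that lists per-row
#' diagnostics; structural problems (missing columns, duplicate ids,
#' non-numeric measurement columns) are errors.
#'
#' @param path CSV file path.
#' @param label Cohort label; defaults to the file name.
#' @return A `ueff_cohort`. Rejected rows (with a `reason` column) are
#'   attached as attribute `"rejected"`.
#' @export
load_cohort <- function(path, label = basename(path)) {
  if (!file.exists(path))
    ueff_stop("io", sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("id", "group", "ac", "bscd", "ls", "pdff")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    ueff_stop("missing_column",
              sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              columns = missing_cols)
  for (col in intersect(c("ac", "bscd", "ls", "pdff", "bmi", "age", "ueff"),
                        names(raw))) {
    if (!is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(coerced) && !all(is.na(raw[[col]]) == is.na(coerced)))
        ueff_stop("unparseable_numeric",
                  sprintf("column '%s' contains unparseable numeric values", col))
      raw[[col]] <- coerced
    }
  }
  raw$id <- as.character(raw$id)
  if (anyDuplicated(raw$id))
    ueff_stop("duplicate_id",
              sprintf("duplicate id(s): %s",
                      paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  bad <- record_violations(raw)
  rejected <- raw[bad != "", , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- bad[bad != ""]
    warning(sprintf("load_cohort: rejected %d row(s): %s",
                    nrow(rejected),
                    paste(sprintf("id %s (%s)", rejected$id, rejected$reason),
                          collapse = "; ")))
    raw <- raw[bad == "", , drop = FALSE]
  }
  out <- cohort(raw, label = label, provenance = normalizePath(path))
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort to CSV
#'
#' Numeric columns are written at 15 significant digits so that
#' `load_cohort(write_cohort(x))` round-trips values to within 1e-12
#' relative error.
#'
#' @param x A `ueff_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "ueff_cohort"))
  out <- as.data.frame(x)
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- trimws(formatC(out[[col]], digits = 15, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
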