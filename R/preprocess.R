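# Preprocessing: below-detection substitution, label derivation, log
# transform, gender subsetting, median imputation. Pipeline order is
# substitution -> label -> log -> split -> impute (imputation last, within
# subset, so gender-specific markers never leak across subsets).

#' Derive the sick/healthy label from a final diagnosis category
#'
#' Patients with any identified cause of haematuria (chronic kidney disease,
#' infection, other benign diagnosis, bladder cancer, history of bladder
#' cancer, other cancer) are labelled `"sick"`; patients with no cause
#' identified are `"healthy"`.
#'
#' @param diagnosis character vector of diagnosis categories.
#' @return character vector in `{"sick", "healthy"}`.
#' @export
derive_label <- function(diagnosis) {
  ok <- diagnosis %in% c(SICK_CATEGORIES, HEALTHY_CATEGORY)
  if (!all(ok))
    stopf("unrecognized diagnosis category: %s (allowed: %s)",
          paste(unique(diagnosis[!ok]), collapse = ", "),
          paste(c(SICK_CATEGORIES, HEALTHY_CATEGORY), collapse = "; "))
  ifelse(diagnosis == HEALTHY_CATEGORY, "healthy", "sick")
}

#' Substitute below-detection measurements
#'
#' Measurements below the limit of detection (LOD) or mean detectable dose
#' carry no number; 90% of the LOD is used in lieu of the actual value.
#'
#' For a `cohort_table` every censored cell is filled with `0.9 * lod` of its
#' marker and the censored flag cleared. The default method substitutes a
#' scalar/vector: `value` entries flagged `censored` become `0.9 * lod`,
#' others pass through unchanged.
#'
#' @param value a `cohort_table`, or numeric vector of raw values.
#' @param lod limit(s) of detection (default method only).
#' @param censored logical vector flagging below-detection entries (default
#'   method only; a single `TRUE` with a missing `value` is allowed).
#' @return same shape as `value`, with censored entries substituted.
#' @export
substitute_below_detection <- function(value, lod = NULL, censored = NULL) {
  UseMethod("substitute_below_detection")
}

#' @export
substitute_below_detection.cohort_table <- function(value, lod = NULL,
                                                    censored = NULL) {
  cens <- attr(value, "censored")
  lods <- attr(value, "lod")
  vals <- marker_values(value)
  for (m in colnames(vals)) {
    if (any(cens[, m])) {
      if (is.na(lods[m]) || lods[m] <= 0)
        stopf("biomarker '%s' has censored values but no defined LOD", m)
      vals[cens[, m], m] <- 0.9 * lods[m]
    }
  }
  out <- set_marker_values(value, vals)
  attr(out, "censored")[] <- FALSE
  out
}

#' @export
substitute_below_detection.default <- function(value, lod = NULL,
                                               censored = NULL) {
  if (is.null(censored)) censored <- is.na(value)
  if (is.null(lod)) stopf("lod is required")
  lod <- rep_len(lod, length(value))
  if (any(censored & (is.na(lod) | lod <= 0)))
    stopf("censored value with undefined LOD")
  out <- ifelse(censored, 0.9 * lod, value)
  as.numeric(out)
}

#' Natural-log transform of all biomarker values
#'
#' Reduces the strong right skew of raw biomarker measurements. All
#' non-missing values must be strictly positive (guaranteed after
#' [substitute_below_detection()]); metadata columns are untouched.
#'
#' @param table a `cohort_table` on the raw scale.
#' @return the table with every biomarker value replaced by `ln(x)` and the
#'   `scale` attribute set to `"log"`.
#' @export
log_transform <- function(table) {
  if (identical(attr(table, "scale"), "log"))
    stopf("table is already on the log scale")
  vals <- marker_values(table)
  bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-positive value for patient %s, biomarker %s",
          table$patient_id[bad[1, 1]], colnames(vals)[bad[1, 2]])
  out <- set_marker_values(table, log(vals))
  attr(out, "scale") <- "log"
  out
}

#' Per-biomarker medians of a cohort
#'
#' @param table a `cohort_table`.
#' @return named numeric vector of medians over non-missing values.
#' @export
marker_medians <- function(table) {
  apply(marker_values(table), 2, stats::median, na.rm = TRUE)
}

#' Median-impute missing biomarker values
#'
#' Missing entries are replaced by the per-biomarker median of the non-missing
#' entries of the same table (computed on the current — normally log — scale).
#' In cross-validated evaluation, pass `medians` computed on the training
#' fold so no information leaks into test folds.
#'
#' @param table a `cohort_table`.
#' @param medians optional named vector of medians to apply (training-fold
#'   medians); defaults to medians of `table` itself.
#' @return the table with no missing biomarker values; non-missing values are
#'   never changed.
#' @export
impute_median <- function(table, medians = NULL) {
  vals <- marker_values(table)
  if (is.null(medians)) medians <- apply(vals, 2, stats::median, na.rm = TRUE)
  if (any(is.na(medians[colnames(vals)])))
    stopf("biomarker(s) with no non-missing values: %s",
          paste(colnames(vals)[is.na(medians[colnames(vals)])],
                collapse = ", "))
  for (m in colnames(vals)) {
    miss <- is.na(vals[, m])
    if (any(miss)) vals[miss, m] <- medians[[m]]
  }
  set_marker_values(table, vals)
}

#' Split a cohort into both/male/female subsets
#'
#' Analysis is run separately for male and female participants in addition to
#' the entire cohort. Markers that are constant within a subset (typically
#' gender-specific markers pinned at their LOD for the excluded gender) are
#' dropped from that subset with a message.
#'
#' @param table a `cohort_table`.
#' @return named list of `cohort_table`s: `both`, `male`, `female`.
#' @export
split_subsets <- function(table) {
  subsets <- list(both = table,
                  male = cohort_rows(table, table$gender == "M"),
                  female = cohort_rows(table, table$gender == "F"))
  for (nm in c("male", "female")) {
    sub <- subsets[[nm]]
    if (nrow(sub) == 0) {
      warnf("subset '%s' is empty", nm)
      next
    }
    vals <- marker_values(sub)
    const <- vapply(colnames(vals), function(m) {
      v <- vals[!is.na(vals[, m]), m]
      length(v) > 0 && length(unique(v)) == 1
    }, logical(1))
    if (any(const)) {
      message(sprintf("subset '%s': dropping constant marker(s): %s", nm,
                      paste(colnames(vals)[const], collapse = ", ")))
      subsets[[nm]] <- drop_markers(sub, colnames(vals)[const])
    }
  }
  subsets
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: below-detection substitution (90% of LOD), label
#' derivation from the diagnosis column, natural-log transform, gender
#' subsetting, and per-subset median imputation.
#'
#' @param table a raw-scale `cohort_table`.
#' @param impute impute medians per subset (set `FALSE` to keep missing flips
#'   or to handle imputation inside a cross-validation loop).
#' @return named list of preprocessed `cohort_table`s: `both`, `male`,
#'   `female`.
#' @export
preprocess_cohort <- function(table, impute = TRUE) {
  table <- substitute_below_detection(table)
  table$label <- derive_label(table$diagnosis)
  table <- log_transform(table)
  subsets <- split_subsets(table)
  if (impute) subsets <- lapply(subsets, impute_median)
  subsets
}
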