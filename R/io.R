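# Cohort CSV dialect: metadata columns (patient_id, gender, age, diagnosis,
# label) then one column per biomarker; empty cell = missing, "<LOD" =
# below-detection; a YAML sidecar stores per-biomarker LOD and units.

#' Write a cohort to CSV (with YAML sidecar)
#'
#' @param table a `cohort_table` (raw scale).
#' @param path CSV file path.
#' @param sidecar YAML sidecar path (default: `path` with `.yaml` appended);
#'   stores each biomarker's LOD and units.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path,
                             sidecar = paste0(path, ".yaml")) {
  df <- as.data.frame(table)
  cens <- attr(table, "censored")
  for (m in marker_names(table)) {
    col <- format(df[[m]], trim = TRUE, digits = 15)
    col[is.na(df[[m]])] <- ""
    col[cens[, m]] <- "<LOD"
    df[[m]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  lod <- attr(table, "lod")
  units <- attr(table, "units")
  meta <- lapply(marker_names(table), function(m)
    list(lod = unname(lod[[m]]),
         units = unname(units[m] %||% "")))
  names(meta) <- marker_names(table)
  yaml::write_yaml(list(biomarkers = meta), sidecar)
  invisible(path)
}

#' Read a cohort from CSV (with YAML sidecar)
#'
#' Parses the dialect written by [write_cohort_csv()]: `"<LOD"` tokens become
#' censored flags, empty cells become missing values. Schema violations are
#' reported with the offending column (and cell, for non-numeric values).
#'
#' @param path CSV file path.
#' @param lod_sidecar YAML sidecar path carrying per-biomarker `lod` and
#'   `units`; optional if no cell is censored.
#' @return a raw-scale `cohort_table`.
#' @export
read_cohort_csv <- function(path, lod_sidecar = paste0(path, ".yaml")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("patient_id", "gender", "age", "diagnosis", "label")
  absent <- setdiff(required, names(df))
  if (length(absent))
    stopf("missing required column(s): %s", paste(absent, collapse = ", "))
  markers <- setdiff(names(df), required)
  if (!length(markers)) stopf("no biomarker columns found")
  meta <- if (file.exists(lod_sidecar))
    yaml::read_yaml(lod_sidecar)$biomarkers else NULL
  lod <- vapply(markers, function(m)
    as.numeric(meta[[m]]$lod %||% NA_real_), 0)
  units <- vapply(markers, function(m) meta[[m]]$units %||% "", "")

  n <- nrow(df)
  values <- matrix(NA_real_, n, length(markers),
                   dimnames = list(NULL, markers))
  censored <- matrix(FALSE, n, length(markers),
                     dimnames = list(NULL, markers))
  for (m in markers) {
    raw <- trimws(df[[m]])
    cens <- raw == "<LOD"
    empty <- raw == "" | is.na(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!cens & !empty & is.na(num))
    if (length(bad))
      stopf("non-numeric value '%s' in column '%s', row %d",
            raw[bad[1]], m, bad[1])
    if (any(cens) && (is.na(lod[[m]]) || lod[[m]] <= 0))
      stopf("column '%s' has <LOD cells but the sidecar defines no LOD", m)
    values[, m] <- num
    censored[, m] <- cens
  }
  out <- data.frame(patient_id = df$patient_id, gender = df$gender,
                    age = as.numeric(df$age), diagnosis = df$diagnosis,
                    label = df$label, stringsAsFactors = FALSE)
  if (!all(out$gender %in% c("M", "F")))
    stopf("gender column must contain only 'M'/'F'")
  out <- cbind(out, as.data.frame(values))
  new_cohort_table(out, censored = censored,
                   lod = stats::setNames(lod, markers),
                   units = stats::setNames(units, markers), scale = "raw")
}
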