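# Flip abstraction: per-biomarker ROC-derived cut-off (Youden's J) and
# two-state U/D encoding of the quantitative values.

#' ROC-derived (Youden) cut-off for one biomarker
#'
#' Scans every candidate threshold — the midpoints between consecutive sorted
#' unique values, plus -Inf/+Inf sentinels — and picks the one maximizing
#' |J|, where J = sensitivity + specificity - 1 for the rule
#' "value > t => test-positive for sick". The absolute value makes the scan
#' direction-agnostic: markers may run lower in the sick class, and the
#' downstream classifier consumes both P(U|class) and P(D|class), so only
#' threshold placement matters. Ties are broken by the smallest threshold.
#'
#' @param values numeric vector of (typically log-scale) measurements;
#'   missing values are ignored.
#' @param labels parallel vector in `{"sick", "healthy"}`.
#' @param biomarker optional marker name recorded in the result.
#' @return an object of class `cutoff`: list with `biomarker`, `threshold`,
#'   `youden_j` (signed J of the "greater than" rule at the chosen
#'   threshold; `abs()` of it is the maximized objective), `direction`
#'   (which state is sick-enriched at the fit data: `"U_sick"` or
#'   `"D_sick"`), and `degenerate` (all values identical).
#' @export
youden_cutoff <- function(values, labels, biomarker = NA_character_) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  if (!all(labels %in% c("sick", "healthy")))
    stopf("labels must be 'sick' or 'healthy'")
  n_sick <- sum(labels == "sick")
  n_healthy <- sum(labels == "healthy")
  if (n_sick == 0 || n_healthy == 0)
    stopf("both classes must be present to fit a cut-off (sick=%d, healthy=%d)",
          n_sick, n_healthy)
  if (any(!is.finite(values)))
    stopf("values must be finite")

  u <- sort(unique(values))
  if (length(u) == 1) {
    warnf("biomarker '%s': all values identical; degenerate cut-off",
          biomarker)
    return(new_cutoff(biomarker, threshold = -Inf, j = 0, degenerate = TRUE))
  }
  candidates <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  # sens(t) = P(value > t | sick); spec(t) = P(value <= t | healthy)
  sick_vals <- values[labels == "sick"]
  healthy_vals <- values[labels == "healthy"]
  sens <- vapply(candidates, function(t) sum(sick_vals > t), 0) / n_sick
  spec <- vapply(candidates, function(t) sum(healthy_vals <= t), 0) / n_healthy
  j <- sens + spec - 1
  # ties (within fp noise) are broken by the smallest threshold
  best <- which(abs(j) >= max(abs(j)) - 1e-12)
  best <- best[which.min(candidates[best])]
  new_cutoff(biomarker, threshold = candidates[best], j = j[best])
}

new_cutoff <- function(biomarker, threshold, j, degenerate = FALSE) {
  structure(list(biomarker = biomarker, threshold = threshold,
                 youden_j = j,
                 direction = if (j >= 0) "U_sick" else "D_sick",
                 degenerate = degenerate),
            class = "cutoff")
}

#' @export
print.cutoff <- function(x, ...) {
  cat(sprintf("cutoff%s: threshold %.4g, |J| = %.3f (%s)%s\n",
              if (is.na(x$biomarker)) "" else paste0(" [", x$biomarker, "]"),
              x$threshold, abs(x$youden_j), x$direction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit cut-offs for every biomarker of a cohort
#'
#' @param table a preprocessed `cohort_table` with a populated `label` column.
#' @return named list of [youden_cutoff()] results, one per marker.
#' @export
fit_cutoffs <- function(table) {
  vals <- marker_values(table)
  cuts <- lapply(colnames(vals), function(m)
    youden_cutoff(vals[, m], table$label, biomarker = m))
  stats::setNames(cuts, colnames(vals))
}

#' Encode a cohort as a two-state flip matrix
#'
#' Each biomarker value is abstracted to `"U"` (up) when strictly above the
#' marker's cut-off and `"D"` (down) when at or below it (boundary convention:
#' equality is D). Missing values yield missing flips.
#'
#' @param table a `cohort_table` on the same scale the cut-offs were fit on.
#' @param cutoffs named list of `cutoff` objects covering every marker of
#'   `table`.
#' @return a `flip_matrix`: character matrix patients x markers with entries
#'   in `{"U", "D", NA}` and the cut-offs stored in the `cutoffs` attribute.
#' @export
abstract_flips <- function(table, cutoffs) {
  vals <- marker_values(table)
  missing_cut <- setdiff(colnames(vals), names(cutoffs))
  if (length(missing_cut))
    stopf("no cut-off provided for biomarker(s): %s",
          paste(missing_cut, collapse = ", "))
  thresholds <- vapply(cutoffs[colnames(vals)], `[[`, 0, "threshold")
  flips <- ifelse(sweep(vals, 2, thresholds, `>`), "U", "D")
  rownames(flips) <- table$patient_id
  structure(flips, cutoffs = cutoffs[colnames(vals)], class = "flip_matrix")
}

#' @export
print.flip_matrix <- function(x, ...) {
  cat(sprintf("flip_matrix: %d patients x %d biomarkers (U: %d, D: %d, missing: %d)\n",
              nrow(x), ncol(x), sum(x == "U", na.rm = TRUE),
              sum(x == "D", na.rm = TRUE), sum(is.na(x))))
  invisible(x)
}

#' Export fitted cut-offs as a data frame
#'
#' Reports each biomarker's decision boundary on the raw measurement scale
#' (`exp()` of the log-scale threshold) together with |J| — the flip-model
#' column of a decision-boundary comparison table.
#'
#' @param cutoffs named list of `cutoff` objects (or a `flip_matrix`).
#' @param log_scale were the cut-offs fit on log-transformed values (then raw
#'   boundaries are exponentiated)?
#' @return data.frame with columns `biomarker`, `threshold` (fit scale),
#'   `boundary_raw`, `youden_j`, `direction`.
#' @export
cutoff_table <- function(cutoffs, log_scale = TRUE) {
  if (inherits(cutoffs, "flip_matrix")) cutoffs <- attr(cutoffs, "cutoffs")
  data.frame(
    biomarker = vapply(cutoffs, `[[`, "", "biomarker"),
    threshold = vapply(cutoffs, `[[`, 0, "threshold"),
    boundary_raw = if (log_scale)
      exp(vapply(cutoffs, `[[`, 0, "threshold"))
    else vapply(cutoffs, `[[`, 0, "threshold"),
    youden_j = abs(vapply(cutoffs, `[[`, 0, "youden_j")),
    direction = vapply(cutoffs, `[[`, "", "direction"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
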