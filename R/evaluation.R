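# Evaluation: confusion counts, sensitivity/specificity/accuracy/balanced
# accuracy, chi-squared test against chance, pairwise McNemar tests, and the
# decision-boundary comparison table. Positive class = sick throughout.

#' Confusion counts from truth and predictions
#'
#' @param truth,pred parallel vectors in `{"sick", "healthy"}` (or containing
#'   `positive` and one other level).
#' @param positive positive-class label (default `"sick"`).
#' @return object of class `confusion`: list with counts `tp`, `fp`, `tn`,
#'   `fn` and `n`.
#' @export
confusion_counts <- function(truth, pred, positive = "sick") {
  stopifnot(length(truth) == length(pred))
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(list(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                 tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos),
                 n = length(truth), positive = positive),
            class = "confusion")
}

#' Confusion object from raw counts
#' @param tp,fp,tn,fn non-negative counts (positive class = sick).
#' @return a `confusion` object.
#' @export
confusion <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
                 positive = "sick"), class = "confusion")
}

#' Classification metrics from a confusion object
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, balanced accuracy = (sensitivity + specificity)/2 — the
#' headline metric, robust to class imbalance. Values are kept at full
#' precision; rounding (3 decimals, half away from zero) happens only in the
#' print method and CSV reports.
#'
#' @param conf a `confusion` object (or truth/pred vectors via
#'   [confusion_counts()] upstream).
#' @param chi2 also compute the chi-squared p-value against chance?
#' @return object of class `metrics_report`: list with `confusion` and
#'   numeric `sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`,
#'   plus `chi2_p` when requested.
#' @export
classification_metrics <- function(conf, chi2 = TRUE) {
  if (conf$tp + conf$fn == 0)
    stopf("positive class ('%s') absent from truth", conf$positive)
  if (conf$tn + conf$fp == 0)
    stopf("negative class absent from truth")
  sens <- conf$tp / (conf$tp + conf$fn)
  spec <- conf$tn / (conf$tn + conf$fp)
  structure(list(confusion = conf,
                 sensitivity = sens, specificity = spec,
                 accuracy = (conf$tp + conf$tn) / conf$n,
                 balanced_accuracy = (sens + spec) / 2,
                 chi2_p = if (chi2) chi2_vs_chance(conf) else NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  conf <- x$confusion
  cat(sprintf("metrics_report (n = %d; TP %d, FP %d, TN %d, FN %d)\n",
              conf$n, conf$tp, conf$fp, conf$tn, conf$fn))
  v <- round_half_up(c(accuracy = x$accuracy,
                       balanced_accuracy = x$balanced_accuracy,
                       sensitivity = x$sensitivity,
                       specificity = x$specificity), 3)
  print(v)
  if (!is.na(x$chi2_p))
    cat(sprintf("chi-squared vs chance: p = %.3g\n", x$chi2_p))
  invisible(x)
}

#' Chi-squared test of a classifier against chance
#'
#' Uncorrected Pearson chi-squared test of independence on the 2x2
#' prediction-vs-truth table (1 df): small p means the classification is
#' associated with the truth, i.e. better than random chance. A zero
#' marginal (e.g. every patient predicted sick) makes the test undefined;
#' p = 1 is reported with a warning.
#'
#' @param conf a `confusion` object.
#' @return the p-value.
#' @export
chi2_vs_chance <- function(conf) {
  o <- matrix(c(conf$tp, conf$fn, conf$fp, conf$tn), 2,
              dimnames = list(pred = c("sick", "healthy"),
                              truth = c("sick", "healthy")))
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    warnf("degenerate confusion table (zero marginal); chi-squared undefined, p = 1")
    return(1)
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' McNemar test between two classifiers
#'
#' Compares the per-patient correctness of two prediction vectors against the
#' same truth. With discordant counts b (A right, B wrong) and c (A wrong,
#' B right): exact two-sided binomial test at p = 0.5 when `b + c < 25`,
#' otherwise the continuity-corrected chi-squared
#' \eqn{(|b-c|-1)^2/(b+c)} on 1 df. `b + c = 0` gives p = 1 exactly.
#'
#' @param preds_a,preds_b aligned prediction vectors.
#' @param truth aligned truth vector.
#' @return list with `p.value`, discordant counts `b` and `c`, and `method`.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth) {
  stopifnot(length(preds_a) == length(truth),
            length(preds_b) == length(truth))
  right_a <- preds_a == truth
  right_b <- preds_b == truth
  b <- sum(right_a & !right_b)
  cc <- sum(!right_a & right_b)
  n <- b + cc
  if (n == 0) {
    p <- 1
    method <- "degenerate (no discordant pairs)"
  } else if (n < 25) {
    # exact two-sided binomial at p = 0.5: both tails at the observed extremity
    m <- min(b, cc)
    p <- min(1, stats::pbinom(m, n, 0.5) +
               stats::pbinom(n - m - 1, n, 0.5, lower.tail = FALSE))
    method <- "exact binomial"
  } else {
    x2 <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-squared"
  }
  list(p.value = p, b = b, c = cc, method = method)
}

#' Pairwise McNemar p-value matrix
#'
#' @param predictions named list of aligned prediction vectors (one per
#'   model).
#' @param truth aligned truth vector.
#' @return symmetric matrix of p-values (diagonal `NA`).
#' @export
mcnemar_matrix <- function(predictions, truth) {
  k <- length(predictions)
  out <- matrix(NA_real_, k, k,
                dimnames = list(names(predictions), names(predictions)))
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    p <- mcnemar_test(predictions[[i]], predictions[[j]], truth)$p.value
    out[i, j] <- out[j, i] <- p
  }
  out
}

#' Decision-boundary comparison table
#'
#' Collects the per-biomarker decision boundaries of fitted model artifacts
#' — flip-model cut-offs (back-transformed to the raw scale), decision-tree
#' split points, LIME-style explanation bins — into one wide table with a
#' `"-"` where a model did not select the biomarker.
#'
#' @param fitted named list (names become columns, e.g. `"cactus.male"`) of
#'   artifacts: `flip_model`, `rpart` fits, or `explanation_bins` data
#'   frames.
#' @param log_scale were models fit on log-transformed values (boundaries are
#'   then exponentiated back to raw units)?
#' @return data.frame with one row per biomarker selected by at least one
#'   model and one character column per artifact.
#' @export
boundary_table <- function(fitted, log_scale = TRUE) {
  per_model <- lapply(fitted, model_boundaries, log_scale = log_scale)
  markers <- sort(unique(unlist(lapply(per_model, names))))
  if (!length(markers))
    return(data.frame(biomarker = character(0), stringsAsFactors = FALSE))
  out <- data.frame(biomarker = markers, stringsAsFactors = FALSE)
  for (nm in names(per_model))
    out[[nm]] <- vapply(markers, function(m)
      per_model[[nm]][[m]] %||% "-", "")
  out
}

# Per-artifact named list biomarker -> boundary string.
model_boundaries <- function(artifact, log_scale = TRUE) {
  back <- if (log_scale) exp else identity
  if (inherits(artifact, "flip_model")) {
    if (is.null(artifact$cutoffs)) return(list())
    ct <- cutoff_table(artifact$cutoffs, log_scale = log_scale)
    ct <- ct[ct$youden_j > 0, , drop = FALSE]  # degenerate markers unselected
    stats::setNames(as.list(sprintf("%.4g", ct$boundary_raw)), ct$biomarker)
  } else if (inherits(artifact, "rpart")) {
    fr <- artifact$frame
    sp <- fr$var != "<leaf>"
    if (!any(sp)) return(list())
    splits <- data.frame(var = as.character(fr$var[sp]),
                         cut = artifact$splits[cumsum(fr$ncompete[sp] +
                                                        fr$nsurrogate[sp] + 1) -
                                                 (fr$ncompete[sp] +
                                                    fr$nsurrogate[sp]), "index"],
                         stringsAsFactors = FALSE)
    out <- lapply(split(splits$cut, splits$var), function(v)
      paste(sprintf("%.4g", sort(unique(back(v)))), collapse = "; "))
    out
  } else if (is.data.frame(artifact) &&
             all(c("feature", "lower", "upper") %in% names(artifact))) {
    out <- lapply(split(artifact, artifact$feature), function(d)
      paste(sprintf("(%.4g, %.4g]", back(d$lower), back(d$upper)),
            collapse = " "))
    out
  } else {
    stopf("unsupported artifact of class %s",
          paste(class(artifact), collapse = "/"))
  }
}

#' Metrics table in report column order
#'
#' Serializes a set of metrics reports with the column order Accuracy,
#' Balanced Accuracy, Sensitivity, Specificity, p-value, rounded to 3
#' decimals (half away from zero).
#'
#' @param reports named list of `metrics_report` objects (names like
#'   `"cactus.both"`).
#' @return data.frame, one row per report.
#' @export
metrics_table <- function(reports) {
  data.frame(
    model = names(reports),
    accuracy = round_half_up(vapply(reports, `[[`, 0, "accuracy")),
    balanced_accuracy =
      round_half_up(vapply(reports, `[[`, 0, "balanced_accuracy")),
    sensitivity = round_half_up(vapply(reports, `[[`, 0, "sensitivity")),
    specificity = round_half_up(vapply(reports, `[[`, 0, "specificity")),
    p_value = vapply(reports, `[[`, 0, "chi2_p"),
    row.names = NULL, stringsAsFactors = FALSE)
}
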