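# Study orchestration: config-driven end-to-end runs on synthetic or
# user-supplied cohorts, with per-stage seed derivation and CSV/JSON report
# bundles.

#' Fit and evaluate the flip-model classifier on one cohort subset
#'
#' Two evaluation modes:
#' * `"cv"` (default): stratified 10-fold cross-validation repeated 3 times.
#'   Inside every training fold the medians (imputation), cut-offs and flip
#'   model are re-fit and applied to the held-out fold, so no information
#'   leaks; per-patient predictions are pooled by majority vote over the
#'   repeats.
#' * `"resubstitution"`: cut-offs and model fit on the full subset and
#'   evaluated on it (the optimistic, fit-data view).
#'
#' The returned `model` is always the full-data fit (used for rank and
#' boundary reporting); `metrics` reflect the requested mode.
#'
#' @param table a log-scale `cohort_table` (imputation is handled
#'   internally; missing values are allowed).
#' @param mode `"cv"` or `"resubstitution"`.
#' @param alpha smoothing pseudocount for [fit_flip_model()].
#' @param seed RNG seed (folds).
#' @param k,repeats cross-validation geometry.
#' @param tie tie-break class.
#' @return list of class `cactus_eval`: `predictions`, `metrics`
#'   (a `metrics_report`), `model` (full-data `flip_model`), `mode`.
#' @export
cactus_evaluate <- function(table, mode = c("cv", "resubstitution"),
                            alpha = 0.5, seed = 1, k = 10, repeats = 3,
                            tie = "sick") {
  mode <- match.arg(mode)
  labels <- table$label
  fit_full <- function(tab) {
    tab <- impute_median(tab)
    cuts <- fit_cutoffs(tab)
    flips <- abstract_flips(tab, cuts)
    fit_flip_model(flips, tab$label, alpha = alpha)
  }
  full_model <- fit_full(table)

  if (mode == "resubstitution") {
    tab <- impute_median(table)
    preds <- classify(abstract_flips(tab, full_model$cutoffs), full_model,
                      tie = tie)
  } else {
    folds <- cv_folds(labels, k, repeats, seed)
    votes <- matrix(NA_character_, nrow(table), repeats)
    for (r in seq_len(repeats)) {
      for (fold in seq_len(k)) {
        test <- folds[, r] == fold
        train <- cohort_rows(table, !test)
        med <- marker_medians(train)
        train <- impute_median(train, med)
        cuts <- fit_cutoffs(train)
        model <- fit_flip_model(abstract_flips(train, cuts), train$label,
                                alpha = alpha)
        test_tab <- impute_median(cohort_rows(table, test), med)
        votes[test, r] <- classify(abstract_flips(test_tab, cuts), model,
                                   tie = tie)
      }
    }
    preds <- apply(votes, 1, function(v) {
      tab <- table(v)
      if ("sick" %in% names(tab) && tab[["sick"]] == max(tab)) "sick"
      else names(tab)[which.max(tab)]
    })
  }
  structure(list(predictions = unname(preds),
                 metrics = classification_metrics(
                   confusion_counts(labels, preds)),
                 model = full_model, mode = mode),
            class = "cactus_eval")
}

#' Study configuration
#'
#' @param input `"synthetic"` or a cohort CSV path.
#' @param generator a [generator_config()] (used when `input = "synthetic"`);
#'   defaults to [default_habio_config()].
#' @param subsets subset names to analyse, from `c("both","male","female")`.
#' @param models models to run, from
#'   `c("cactus","tree","forest","logit_scan","kmeans_scan")`.
#' @param mode `"cv"` or `"resubstitution"` (classifier evaluation mode).
#' @param alpha flip-model smoothing pseudocount.
#' @param seed global seed; per-stage seeds are derived from it by hashing
#'   the stage name, so stages can be rerun in isolation.
#' @param output_dir optional directory for the CSV/JSON report bundle.
#' @return list of class `study_config`.
#' @export
study_config <- function(input = "synthetic", generator = NULL,
                         subsets = c("both", "male", "female"),
                         models = c("cactus", "tree", "forest",
                                    "logit_scan", "kmeans_scan"),
                         mode = c("cv", "resubstitution"), alpha = 0.5,
                         seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  subsets <- match.arg(subsets, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  if (!length(models)) stopf("models must be non-empty")
  if (identical(input, "synthetic") && is.null(generator))
    generator <- default_habio_config()
  structure(list(input = input, generator = generator, subsets = subsets,
                 models = models, mode = mode, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

config_hash <- function(config) {
  fnv1a32(utils::capture.output(utils::str(
    config[setdiff(names(config), "output_dir")], vec.len = 1e6)))
}

#' Generate (and optionally write) a synthetic cohort
#'
#' @param config a [generator_config()]; default [default_habio_config()].
#' @param seed generation seed.
#' @param path optional CSV path passed to [write_cohort_csv()].
#' @return the `cohort_table`, invisibly when written.
#' @export
simulate_cohort <- function(config = default_habio_config(), seed = config$seed,
                            path = NULL) {
  cohort <- generate_cohort(config, seed)
  if (!is.null(path)) {
    write_cohort_csv(cohort, path)
    return(invisible(cohort))
  }
  cohort
}

#' Run a full stratification study
#'
#' Executes the whole workflow on a synthetic or CSV cohort: preprocessing
#' (below-detection substitution, label derivation, log transform, gender
#' subsetting, median imputation), then per subset the requested models —
#' the flip-model classifier ([cactus_evaluate()]), decision tree and random
#' forest under repeated CV, a single-marker logistic-regression scan, and a
#' k-means silhouette scan — and finally the shared evaluation: a metrics
#' table, pairwise McNemar matrices per subset, top-10 rank tables, forest
#' importances, and the decision-boundary comparison table. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config a [study_config()].
#' @return list of class `study_report` with elements `metrics` (data.frame),
#'   `reports` (nested per subset/model), `mcnemar` (per subset),
#'   `rank_tables`, `importances`, `logit_tables`, `kmeans`, `boundaries`,
#'   `predictions`, `truth`, and `meta` (config hash, seed, versions). When
#'   `config$output_dir` is set, the bundle is also written as CSV/JSON.
#' @export
run_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stopf("config must be a study_config")
  cohort <- if (identical(config$input, "synthetic"))
    generate_cohort(config$generator, derive_seed(config$seed, "generate"))
  else read_cohort_csv(config$input)

  subsets <- preprocess_cohort(cohort, impute = FALSE)[config$subsets]
  imputed <- lapply(subsets, impute_median)

  reports <- list()
  predictions <- list()
  rank_tables <- list()
  importances <- list()
  logit_tables <- list()
  kmeans_res <- list()
  artifacts <- list()

  for (sub in names(subsets)) {
    tab <- subsets[[sub]]
    if (length(unique(tab$label)) < 2)
      stopf("subset '%s' contains a single class; cannot evaluate", sub)
    for (model in config$models) {
      sseed <- derive_seed(config$seed, paste(model, sub))
      if (model == "cactus") {
        fit <- cactus_evaluate(tab, mode = config$mode,
                               alpha = config$alpha, seed = sseed)
        reports[[sub]][[model]] <- fit$metrics
        predictions[[sub]][[model]] <- fit$predictions
        rank_tables[[sub]] <- top_ranked(fit$model, 10)
        artifacts[[paste("cactus", sub, sep = ".")]] <- fit$model
      } else if (model == "tree") {
        fit <- tree_cv(imputed[[sub]], seed = sseed)
        reports[[sub]][[model]] <- fit$metrics
        predictions[[sub]][[model]] <- fit$predictions
        artifacts[[paste("tree", sub, sep = ".")]] <- fit$tree
      } else if (model == "forest") {
        fit <- forest_cv(imputed[[sub]], seed = sseed)
        reports[[sub]][[model]] <- fit$metrics
        predictions[[sub]][[model]] <- fit$predictions
        importances[[sub]] <- fit$top10
      } else if (model == "logit_scan") {
        logit_tables[[sub]] <- logit_scan(imputed[[sub]])
      } else if (model == "kmeans_scan") {
        kmeans_res[[sub]] <- silhouette_scan(marker_values(imputed[[sub]]),
                                             k_min = 1, k_max = 20,
                                             seed = sseed)
      }
    }
  }

  metrics <- list()
  mcnemar <- list()
  for (sub in names(reports)) {
    for (model in names(reports[[sub]]))
      metrics[[paste(model, sub, sep = ".")]] <- reports[[sub]][[model]]
    if (length(predictions[[sub]]) >= 2)
      mcnemar[[sub]] <- mcnemar_matrix(predictions[[sub]],
                                       subsets[[sub]]$label)
  }

  report <- structure(list(
    metrics = if (length(metrics)) metrics_table(metrics) else NULL,
    reports = reports, mcnemar = mcnemar, rank_tables = rank_tables,
    importances = importances, logit_tables = logit_tables,
    kmeans = lapply(kmeans_res, `[[`, "best_k"),
    kmeans_scores = lapply(kmeans_res, `[[`, "scores"),
    boundaries = if (length(artifacts)) boundary_table(artifacts) else NULL,
    predictions = predictions,
    truth = lapply(subsets, `[[`, "label"),
    meta = list(config_hash = config_hash(config), seed = config$seed,
                mode = config$mode, alpha = config$alpha,
                package_version = as.character(
                  utils::packageVersion("cactusflip")),
                r_version = as.character(getRversion()))),
    class = "study_report")
  report$artifacts <- artifacts

  if (!is.null(config$output_dir)) write_study_report(report, config)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report (seed %s, mode %s, config %s)\n",
              x$meta$seed, x$meta$mode, x$meta$config_hash))
  if (!is.null(x$metrics)) print(x$metrics)
  if (length(x$kmeans))
    cat("silhouette-selected k:",
        paste(sprintf("%s=%d", names(x$kmeans), unlist(x$kmeans)),
              collapse = ", "), "\n")
  invisible(x)
}

write_study_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  stamp <- function(path) {
    # prepend run metadata as a comment header
    lines <- readLines(path)
    writeLines(c(sprintf("# cactusflip config=%s seed=%d mode=%s",
                         report$meta$config_hash, report$meta$seed,
                         report$meta$mode), lines), path)
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    stamp(out(name))
  }
  if (!is.null(report$metrics)) wcsv(report$metrics, "metrics.csv")
  if (!is.null(report$boundaries)) wcsv(report$boundaries, "boundaries.csv")
  for (sub in names(report$rank_tables))
    wcsv(report$rank_tables[[sub]], sprintf("ranks_%s.csv", sub))
  for (sub in names(report$importances))
    wcsv(report$importances[[sub]], sprintf("importance_%s.csv", sub))
  for (sub in names(report$logit_tables))
    wcsv(report$logit_tables[[sub]], sprintf("logit_%s.csv", sub))
  for (sub in names(report$mcnemar)) {
    m <- as.data.frame(report$mcnemar[[sub]])
    m <- cbind(model = rownames(m), m)
    wcsv(m, sprintf("mcnemar_%s.csv", sub))
  }
  for (nm in names(report$artifacts)) {
    art <- report$artifacts[[nm]]
    if (inherits(art, "flip_model"))
      write_flip_model(art, out(sprintf("model_%s.json", nm)))
  }
  jsonlite::write_json(report$meta, out("meta.json"), auto_unbox = TRUE)
  invisible(config$output_dir)
}

#' Explain one patient's classification
#'
#' Breaks a patient's cost scores into per-biomarker contributions: for each
#' observed flip the log-ratio
#' `ln P(flip|sick) - ln P(flip|healthy)` (positive values push towards
#' sick). The contributions sum to the difference of the two log costs.
#'
#' @param model a fitted `flip_model`.
#' @param patient_flips named character vector of the patient's flips (one
#'   row of a `flip_matrix`).
#' @return data.frame (biomarker, flip, p_sick, p_healthy, log_lr), sorted
#'   by decreasing |log_lr|, with the patient's `cost_scores` in the
#'   `"scores"` attribute.
#' @export
explain_patient <- function(model, patient_flips) {
  sc <- cost_scores(patient_flips, model)
  obs <- !is.na(patient_flips)
  mk <- names(patient_flips)[obs]
  fl <- patient_flips[obs]
  p_s <- vapply(seq_along(mk), function(i)
    model$prob[[fl[i]]][mk[i], "sick"], 0)
  p_h <- vapply(seq_along(mk), function(i)
    model$prob[[fl[i]]][mk[i], "healthy"], 0)
  out <- data.frame(biomarker = mk, flip = unname(fl), p_sick = p_s,
                    p_healthy = p_h, log_lr = log(p_s) - log(p_h),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log_lr)), ]
  attr(out, "scores") <- sc
  out
}
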