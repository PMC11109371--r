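# Comparison methods: k-means silhouette scan, single-marker logistic
# regression with spline selection, decision tree and random forest under
# repeated stratified cross-validation, and a LIME-style local explainer.
# All their metrics flow through the evaluation module.

#' Select the number of k-means clusters by silhouette width
#'
#' Runs k-means for each candidate k (multiple restarts, fixed seed) and
#' picks the k maximizing the mean silhouette width. Silhouette is undefined
#' for a single cluster, so the scan effectively starts at k = 2; if
#' `k_min = 1` is requested, k = 1 is recorded with an undefined (`NA`)
#' score.
#'
#' @param X numeric feature matrix (no missing values).
#' @param k_min,k_max candidate cluster-count range (`k_max <= n - 1`).
#' @param seed RNG seed for the k-means restarts.
#' @param scale z-score the features first (80 biomarkers on wildly
#'   different scales otherwise dominate the distances)?
#' @return list with `best_k` and `scores` (data.frame of `k`,
#'   `mean_silhouette`).
#' @export
silhouette_scan <- function(X, k_min = 1, k_max = 20, seed = 1,
                            scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stopf("silhouette scan needs at least 3 rows")
  if (anyNA(X)) stopf("X must not contain missing values")
  k_max <- min(k_max, nrow(X) - 1)
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    X <- base::scale(X[, sds > 0, drop = FALSE])
  }
  d <- stats::dist(X)
  ks <- seq(max(k_min, 1), k_max)
  scores <- vapply(ks, function(k) {
    if (k < 2) return(NA_real_)
    cl <- with_seed(derive_seed(seed, paste0("kmeans", k)),
                    stats::kmeans(X, centers = k, nstart = 10,
                                  iter.max = 50))
    mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
  }, 0)
  best <- ks[which.max(scores)]  # NA (k=1) never wins
  list(best_k = best,
       scores = data.frame(k = ks, mean_silhouette = scores))
}

#' Single-marker logistic regression with spline selection
#'
#' Fits `label ~ marker` twice — linear, and with a natural cubic spline
#' (3 df) to allow a non-linear relationship — and keeps the spline only if
#' the deviance (ANOVA chi-squared) test prefers it at 0.05. Balanced
#' accuracy is computed from resubstitution predictions at probability
#' threshold 0.5; under heavy imbalance a weak marker collapses to the
#' majority class and scores 0.5.
#'
#' @param values numeric marker values.
#' @param labels parallel labels in `{"sick", "healthy"}`.
#' @return list with `chosen_form` (`"linear"`/`"spline"`),
#'   `balanced_accuracy`, `anova_p`, `separation` (perfect-separation flag)
#'   and the fitted `model`.
#' @export
single_marker_logit <- function(values, labels) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  y <- as.integer(labels == "sick")
  separation <- FALSE
  fits <- withCallingHandlers({
    f_lin <- stats::glm(y ~ values, family = stats::binomial())
    f_spl <- if (length(unique(values)) > 4)
      stats::glm(y ~ splines::ns(values, df = 3),
                 family = stats::binomial())
    else NULL
    list(lin = f_lin, spl = f_spl)
  }, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      separation <<- TRUE
    invokeRestart("muffleWarning")
  })
  anova_p <- NA_real_
  chosen <- "linear"
  fit <- fits$lin
  if (!is.null(fits$spl)) {
    a <- stats::anova(fits$lin, fits$spl, test = "Chisq")
    anova_p <- a[["Pr(>Chi)"]][2]
    if (!is.na(anova_p) && anova_p < 0.05) {
      chosen <- "spline"
      fit <- fits$spl
    }
  }
  pred <- ifelse(stats::fitted(fit) > 0.5, "sick", "healthy")
  met <- classification_metrics(confusion_counts(labels, pred), chi2 = FALSE)
  list(chosen_form = chosen, balanced_accuracy = met$balanced_accuracy,
       anova_p = anova_p, separation = separation, model = fit)
}

#' Scan every biomarker with single-marker logistic regression
#'
#' @param table a preprocessed `cohort_table`.
#' @return data.frame (biomarker, chosen_form, balanced_accuracy), sorted by
#'   descending balanced accuracy.
#' @export
logit_scan <- function(table) {
  vals <- marker_values(table)
  rows <- lapply(colnames(vals), function(m) {
    fit <- single_marker_logit(vals[, m], table$label)
    data.frame(biomarker = m, chosen_form = fit$chosen_form,
               balanced_accuracy = fit$balanced_accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$balanced_accuracy, out$biomarker), ]
}

#' Stratified repeated k-fold assignments
#'
#' Fold labels are assigned per class so every fold keeps (within one
#' patient) the cohort's class proportions; assignments are reproducible
#' from the seed.
#'
#' @param labels class label per patient.
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param seed RNG seed.
#' @return integer matrix `n x repeats` of fold ids in `1..k`.
#' @export
cv_folds <- function(labels, k = 10, repeats = 3, seed = 1) {
  n <- length(labels)
  folds <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    folds[, r] <- with_seed(derive_seed(seed, paste0("fold", r)), {
      f <- integer(n)
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
  }
  folds
}

# Shared harness: stratified 10-fold CV x repeats for a fit/predict pair.
# Imputation (and anything else passed in `fit`) happens inside each
# training fold. Per-patient predictions are pooled by majority vote over
# the repeats (ties -> "sick").
cv_harness <- function(X, labels, fit_predict, k = 10, repeats = 3,
                       seed = 1) {
  folds <- cv_folds(labels, k, repeats, seed)
  n <- length(labels)
  votes <- matrix(NA_character_, n, repeats)
  extras <- list()
  for (r in seq_len(repeats)) {
    for (fold in seq_len(k)) {
      test <- folds[, r] == fold
      if (length(unique(labels[!test])) < 2)
        stopf("training fold lost a class; use fewer folds")
      res <- fit_predict(X[!test, , drop = FALSE], labels[!test],
                         X[test, , drop = FALSE],
                         derive_seed(seed, sprintf("fit%d.%d", r, fold)))
      votes[test, r] <- res$pred
      if (!is.null(res$extra)) extras[[length(extras) + 1]] <- res$extra
    }
  }
  pooled <- apply(votes, 1, function(v) {
    tab <- table(v)
    if ("sick" %in% names(tab) && tab[["sick"]] == max(tab)) "sick"
    else names(tab)[which.max(tab)]
  })
  list(pooled = unname(pooled), votes = votes, extras = extras)
}

#' Decision tree under repeated stratified cross-validation
#'
#' Fits a cost-complexity-pruned classification tree (pruned at the
#' cross-validation-minimizing complexity within [rpart::rpart()]) in each of
#' 10 folds x 3 repeats; per-patient predictions are pooled by majority vote
#' over the repeats. A tree fit on the full data provides the reportable
#' rules and split boundaries.
#'
#' @param table a preprocessed `cohort_table` (or plain data.frame of
#'   features).
#' @param labels class label per patient (defaults to `table$label`).
#' @param seed RNG seed for folds and fits.
#' @param k,repeats cross-validation geometry.
#' @return list with `predictions` (pooled), `metrics` (a
#'   `metrics_report`), `tree` (full-data pruned `rpart` fit) and `folds`.
#' @export
tree_cv <- function(table, labels = table$label, seed = 1, k = 10,
                    repeats = 3) {
  X <- baseline_features(table)
  if (nrow(X) < 20) stopf("need at least 20 patients")
  fit_predict <- function(Xtr, ytr, Xte, s) {
    fit <- with_seed(s, prune_rpart(Xtr, ytr))
    list(pred = as.character(stats::predict(fit, Xte, type = "class")))
  }
  cv <- cv_harness(X, labels, fit_predict, k, repeats, seed)
  full <- with_seed(derive_seed(seed, "fulltree"), prune_rpart(X, labels))
  list(predictions = cv$pooled,
       metrics = classification_metrics(confusion_counts(labels, cv$pooled)),
       tree = full, folds = cv$votes)
}

prune_rpart <- function(X, y) {
  d <- data.frame(.y = factor(y), X, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                      control = rpart::rpart.control(cp = 0.001, xval = 10))
  cp <- fit$cptable
  best <- cp[which.min(cp[, "xerror"]), "CP"]
  rpart::prune(fit, cp = best)
}

#' Random forest under repeated stratified cross-validation
#'
#' 500-tree forests fit in each of 10 folds x 3 repeats with pooled
#' majority-vote predictions, mean-decrease-in-Gini importances averaged over
#' all fits, and the top importances reported. Under heavy class imbalance
#' bootstrap samples may contain few or no minority-class patients, which is
#' the documented failure mode (specificity collapse) this harness makes
#' visible.
#'
#' @inheritParams tree_cv
#' @param ntree trees per forest.
#' @return list with `predictions`, `metrics`, `importances` (named vector,
#'   descending), `top10` (data.frame) and `folds`.
#' @export
forest_cv <- function(table, labels = table$label, seed = 1, k = 10,
                      repeats = 3, ntree = 500) {
  X <- baseline_features(table)
  if (nrow(X) < 20) stopf("need at least 20 patients")
  imp <- NULL
  fit_predict <- function(Xtr, ytr, Xte, s) {
    fit <- with_seed(s, randomForest::randomForest(
      x = Xtr, y = factor(ytr), ntree = ntree))
    list(pred = as.character(stats::predict(fit, Xte)),
         extra = fit$importance[, "MeanDecreaseGini"])
  }
  cv <- cv_harness(X, labels, fit_predict, k, repeats, seed)
  imp <- Reduce(`+`, cv$extras) / length(cv$extras)
  imp <- sort(imp, decreasing = TRUE)
  list(predictions = cv$pooled,
       metrics = classification_metrics(confusion_counts(labels, cv$pooled)),
       importances = imp,
       top10 = data.frame(feature = names(imp), importance = unname(imp),
                          row.names = NULL)[seq_len(min(10, length(imp))), ],
       folds = cv$votes)
}

# Feature matrix for the tree/forest baselines: biomarkers plus age, plus a
# numeric gender indicator when both genders are present.
baseline_features <- function(table) {
  if (inherits(table, "cohort_table")) {
    X <- as.data.frame(marker_values(table))
    X$age <- table$age
    if (length(unique(table$gender)) > 1)
      X$gender <- as.integer(table$gender == "M")
    X
  } else {
    as.data.frame(table)
  }
}

#' LIME-style local explanation of one prediction
#'
#' Explains a single patient's predicted class probability with a local
#' surrogate: features are discretized into quartile bins learned from the
#' background data; perturbed samples are drawn by resampling bins
#' (uniformly) and sampling values from the background within the chosen
#' bin; samples are weighted by an exponential kernel on the fraction of
#' bins matching the instance; and a ridge-regularized weighted linear model
#' on the bin-match indicators approximates `predict_fn` locally. The
#' fitted weights are the feature contributions; each is reported with the
#' instance's bin range.
#'
#' @param predict_fn function mapping a feature data.frame to P(sick).
#' @param instance single-row data.frame (or named vector) to explain.
#' @param background data.frame of reference observations (same columns).
#' @param n_samples number of perturbed samples.
#' @param seed RNG seed.
#' @param n_features report the top-weighted features (default all).
#' @param kernel_width width of the exponential proximity kernel on binary
#'   bin-mismatch distance.
#' @param ridge ridge penalty of the surrogate fit.
#' @return data.frame of class `explanation_bins` with columns `feature`,
#'   `lower`, `upper` (the instance's bin, `-Inf`/`Inf` at the extremes),
#'   `mean_weight`, `toward` (`"sick"` for positive weights).
#' @export
local_explain <- function(predict_fn, instance, background, n_samples = 500,
                          seed = 1, n_features = Inf, kernel_width = 0.75,
                          ridge = 1e-3) {
  background <- as.data.frame(background)
  if (nrow(background) == 0) stopf("background must be non-empty")
  instance <- if (is.data.frame(instance)) instance[1, , drop = FALSE]
  else as.data.frame(as.list(instance))
  feats <- names(background)
  # quartile bins per feature; constant features are excluded with a warning
  bins <- list()
  for (f in feats) {
    qs <- unique(stats::quantile(background[[f]], c(0.25, 0.5, 0.75),
                                 na.rm = TRUE, names = FALSE))
    if (length(qs) < 1 || length(unique(background[[f]])) < 2) {
      warnf("constant feature '%s' excluded from explanation", f)
      next
    }
    bins[[f]] <- qs
  }
  feats <- names(bins)
  if (!length(feats)) stopf("no non-constant features to explain")
  bin_of <- function(x, cuts) findInterval(x, cuts, left.open = TRUE) + 1L

  with_seed(seed, {
    inst_bin <- vapply(feats, function(f)
      bin_of(instance[[f]], bins[[f]]), 1L)
    # perturbed dataset: random bin per feature, value resampled from the
    # background members of that bin (fallback: uniform within bin edges)
    Xp <- as.data.frame(instance)[rep(1, n_samples), , drop = FALSE]
    Z <- matrix(0L, n_samples, length(feats),
                dimnames = list(NULL, feats))
    for (f in feats) {
      nb <- length(bins[[f]]) + 1L
      bv <- bin_of(background[[f]], bins[[f]])
      pick <- sample.int(nb, n_samples, replace = TRUE)
      val <- numeric(n_samples)
      for (b in seq_len(nb)) {
        sel <- pick == b
        if (!any(sel)) next
        pool <- background[[f]][bv == b & !is.na(background[[f]])]
        if (!length(pool)) pool <- background[[f]][!is.na(background[[f]])]
        val[sel] <- sample(pool, sum(sel), replace = TRUE)
      }
      Xp[[f]] <- val
      Z[, f] <- as.integer(pick == inst_bin[[f]])
    }
    y <- predict_fn(Xp)
    dist <- 1 - rowMeans(Z)  # fraction of mismatched bins
    w <- exp(-dist^2 / kernel_width^2)
    # ridge-regularized weighted least squares; the intercept is unpenalized
    Zc <- cbind(1, Z)
    A <- crossprod(Zc * sqrt(w)) + ridge * diag(c(0, rep(1, ncol(Z))))
    beta <- solve(A, crossprod(Zc, w * y))[-1, 1]
    edges <- vapply(feats, function(f) {
      cuts <- c(-Inf, bins[[f]], Inf)
      c(cuts[inst_bin[[f]]], cuts[inst_bin[[f]] + 1L])
    }, numeric(2))
    out <- data.frame(feature = feats,
                      lower = edges[1, ], upper = edges[2, ],
                      mean_weight = unname(beta),
                      toward = ifelse(beta >= 0, "sick", "healthy"),
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(-abs(out$mean_weight)), ]
    out <- utils::head(out, n_features)
    class(out) <- c("explanation_bins", "data.frame")
    out
  })
}
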