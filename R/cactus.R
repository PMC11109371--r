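# CACTUS core: class-conditional flip probabilities, rank statistic, and
# cost-function (naive-Bayes-style likelihood) classification.
#
# For each biomarker and class c the model stores P(f|c), the conditional
# probability of flip state f given the class. A patient's per-class cost is
# the product of the class-conditional probabilities of their observed flips
# (accumulated in log space); the class with the greater cost wins. The rule
# contains no class-prior term, which is what makes it robust to the heavy
# sick/healthy imbalance of haematuria cohorts.

FLIP_STATES <- c("U", "D")

#' Fit a flip model (class-conditional probabilities and ranks)
#'
#' Estimates, for every biomarker and class, the smoothed conditional
#' probability \eqn{P(f|c) = (n_{f,c} + \alpha) / (n_c + 2\alpha)} of each
#' flip state, with missing flips excluded from the counts, and derives the
#' rank statistic (see [flip_rank()]).
#'
#' @param flips a `flip_matrix` from [abstract_flips()] (or any character
#'   matrix with entries in `{"U","D",NA}`).
#' @param labels class label per patient; any number of classes `>= 2` is
#'   supported (the study uses `{"sick","healthy"}`).
#' @param alpha non-negative smoothing pseudocount (default 0.5, Jeffreys).
#'   With `alpha = 0` a zero count makes a conditional probability exactly 0
#'   and the fit aborts with an error directing you to `alpha > 0`.
#' @return a `flip_model`: list with `classes`, `alpha`, `n_per_class`,
#'   `prob` (named list per state of marker x class probability matrices),
#'   `ranks` (marker x state matrix) and, when `flips` carries them, the
#'   `cutoffs` used.
#' @export
fit_flip_model <- function(flips, labels, alpha = 0.5) {
  if (alpha < 0) stopf("alpha must be >= 0")
  stopifnot(length(labels) == nrow(flips))
  classes <- if (all(unique(labels) %in% c("sick", "healthy")))
    intersect(c("sick", "healthy"), unique(labels))
  else sort(unique(labels))
  if (length(classes) < 2)
    stopf("both classes must be present to fit a model; got only: %s",
          paste(classes, collapse = ", "))
  markers <- colnames(flips)

  count_state <- function(state, cls) {
    colSums(flips[labels == cls, , drop = FALSE] == state, na.rm = TRUE)
  }
  prob <- list()
  for (state in FLIP_STATES) prob[[state]] <-
    matrix(NA_real_, length(markers), length(classes),
           dimnames = list(markers, classes))
  for (cls in classes) {
    nU <- count_state("U", cls)
    nD <- count_state("D", cls)
    n_obs <- nU + nD  # non-missing flips in this class, per marker
    if (any(n_obs == 0))
      stopf("class '%s' has no observed flips for biomarker(s): %s", cls,
            paste(markers[n_obs == 0], collapse = ", "))
    if (alpha == 0 && any(nU == 0 | nD == 0))
      stopf("zero flip count with alpha = 0 for biomarker(s) %s; use alpha > 0",
            paste(markers[nU == 0 | nD == 0], collapse = ", "))
    prob$U[, cls] <- (nU + alpha) / (n_obs + 2 * alpha)
    prob$D[, cls] <- (nD + alpha) / (n_obs + 2 * alpha)
  }

  model <- structure(
    list(classes = classes, alpha = alpha,
         n_per_class = stats::setNames(as.integer(table(labels)[classes]),
                                       classes),
         prob = prob, cutoffs = attr(flips, "cutoffs")),
    class = "flip_model")
  model$ranks <- compute_ranks(model)
  model
}

# Rank matrix (markers x states): mean absolute pairwise difference of
# P(f|c) over the C(N,2) class pairs.
compute_ranks <- function(model) {
  classes <- model$classes
  pairs <- utils::combn(length(classes), 2)
  ranks <- sapply(FLIP_STATES, function(state) {
    p <- model$prob[[state]]
    acc <- numeric(nrow(p))
    for (k in seq_len(ncol(pairs)))
      acc <- acc + abs(p[, pairs[1, k]] - p[, pairs[2, k]])
    acc / ncol(pairs)
  })
  matrix(ranks, ncol = length(FLIP_STATES),
         dimnames = list(rownames(model$prob$U), FLIP_STATES))
}

#' Rank of a biomarker's flip state
#'
#' The rank \eqn{R_{xf} = \sum_{i<j} |P(f|c_i) - P(f|c_j)| / {N \choose 2}}
#' measures how much a flip's conditional probability varies across the N
#' classes: an explainability/importance score. For two classes it is simply
#' `|P(f|sick) - P(f|healthy)|`, and R(U) = R(D) by the complement rule.
#'
#' @param model a fitted `flip_model`.
#' @param biomarker marker name.
#' @param flip flip state, `"U"` or `"D"`.
#' @return the rank, a number in `[0, 1]`.
#' @export
flip_rank <- function(model, biomarker, flip = "U") {
  flip <- match.arg(flip, FLIP_STATES)
  if (!biomarker %in% rownames(model$ranks))
    stopf("unknown biomarker '%s'", biomarker)
  model$ranks[biomarker, flip]
}

#' Per-class cost scores for one patient
#'
#' The cost of class s is the product over the patient's observed flips of
#' the flip's class-conditional probability ("node significance"); markers
#' with missing flips contribute a factor of 1 (exponent 0). Costs are
#' accumulated in log space so 80-marker products cannot underflow. The class
#' with the greater cost is the prediction; exact ties go to `tie` (default
#' `"sick"`: in a screening setting sensitivity is favoured).
#'
#' @param patient_flips named character vector (one row of a `flip_matrix`).
#' @param model a fitted `flip_model`.
#' @param tie class predicted on exact ties.
#' @return list of class `cost_scores`: `log_cost` (named per class),
#'   `predicted`, `n_markers_used`.
#' @export
cost_scores <- function(patient_flips, model, tie = "sick") {
  row <- matrix(patient_flips, nrow = 1,
                dimnames = list(NULL, names(patient_flips)))
  scores <- cost_score_matrix(row, model)
  if (scores$n_used[1] == 0) stopf("all flips missing for this patient")
  structure(list(log_cost = scores$log_cost[1, ],
                 predicted = decide(scores$log_cost, model$classes, tie)[1],
                 n_markers_used = scores$n_used[1]),
            class = "cost_scores")
}

#' @export
print.cost_scores <- function(x, ...) {
  cat(sprintf("cost_scores: predicted '%s' from %d markers\n", x$predicted,
              x$n_markers_used))
  print(round(x$log_cost, 4))
  invisible(x)
}

# Vectorized log-cost computation: patients x classes matrix.
cost_score_matrix <- function(flips, model) {
  markers <- rownames(model$prob$U)
  missing_m <- setdiff(colnames(flips), markers)
  if (length(missing_m))
    stopf("biomarker-set mismatch: %s not in model",
          paste(missing_m, collapse = ", "))
  flips <- flips[, markers[markers %in% colnames(flips)], drop = FALSE]
  if (!setequal(colnames(flips), markers))
    stopf("biomarker-set mismatch: model markers %s absent from flips",
          paste(setdiff(markers, colnames(flips)), collapse = ", "))
  isU <- !is.na(flips) & flips == "U"
  isD <- !is.na(flips) & flips == "D"
  log_cost <- sapply(model$classes, function(cls)
    isU %*% log(model$prob$U[colnames(flips), cls]) +
    isD %*% log(model$prob$D[colnames(flips), cls]))
  log_cost <- matrix(log_cost, nrow = nrow(flips),
                     dimnames = list(rownames(flips), model$classes))
  list(log_cost = log_cost, n_used = rowSums(isU | isD))
}

decide <- function(log_cost, classes, tie = "sick") {
  if (!tie %in% classes) tie <- classes[1]
  best <- max.col(log_cost, ties.method = "first")
  pred <- classes[best]
  # exact tie between the top two scores -> tie class
  top <- apply(log_cost, 1, function(r) sum(r == max(r)))
  pred[top > 1] <- tie
  pred
}

#' Classify every patient of a flip matrix
#'
#' Row-wise [cost_scores()]: output order matches patient order.
#'
#' @param flips a `flip_matrix` whose biomarker set matches the model's.
#' @param model a fitted `flip_model`.
#' @param tie class predicted on exact ties (default `"sick"`).
#' @return character vector of predicted classes, with the log-cost matrix in
#'   the `"log_cost"` attribute.
#' @export
classify <- function(flips, model, tie = "sick") {
  scores <- cost_score_matrix(flips, model)
  if (any(scores$n_used == 0))
    stopf("patient(s) with all flips missing: %s",
          paste(rownames(flips)[scores$n_used == 0], collapse = ", "))
  structure(decide(scores$log_cost, model$classes, tie),
            log_cost = scores$log_cost)
}

#' Top-ranked biomarkers of a fitted model
#'
#' @param model a fitted `flip_model`.
#' @param k number of biomarkers to report (clamped to the marker count).
#' @return data.frame sorted by descending rank (ties broken by biomarker
#'   name) with columns `biomarker`, `flip`, `rank`, and one `p_<class>`
#'   column per class giving P(U|class).
#' @export
top_ranked <- function(model, k = 10) {
  stopifnot(k >= 1)
  ranks <- model$ranks[, "U"]
  ord <- order(-ranks, rownames(model$ranks))
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(biomarker = rownames(model$ranks)[ord], flip = "U",
                    rank = unname(ranks[ord]), stringsAsFactors = FALSE)
  for (cls in model$classes)
    out[[paste0("p_", cls)]] <- unname(model$prob$U[ord, cls])
  out
}

#' @export
print.flip_model <- function(x, ...) {
  cat(sprintf("flip_model: %d biomarkers, classes %s (n = %s), alpha = %g\n",
              nrow(x$prob$U), paste(x$classes, collapse = "/"),
              paste(x$n_per_class, collapse = "/"), x$alpha))
  cat("top ranks:\n")
  print(utils::head(top_ranked(x, 5)), digits = 3)
  invisible(x)
}

#' Export / import a flip model as JSON
#'
#' Serializes classes, alpha, class sizes, per-marker thresholds and
#' conditional probabilities and ranks, so classifications are auditable and
#' reproducible outside R.
#'
#' @param model a fitted `flip_model`.
#' @param path file path to write to / read from.
#' @return `write_flip_model` returns `path` invisibly; `read_flip_model`
#'   returns the reconstructed `flip_model`.
#' @export
write_flip_model <- function(model, path) {
  payload <- list(
    classes = model$classes, alpha = model$alpha,
    n_per_class = as.list(model$n_per_class),
    biomarkers = rownames(model$prob$U),
    prob = lapply(model$prob, function(p)
      stats::setNames(as.data.frame(p), colnames(p))),
    ranks = as.data.frame(model$ranks),
    cutoffs = if (!is.null(model$cutoffs))
      cutoff_table(model$cutoffs) else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_flip_model
#' @export
read_flip_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  prob <- lapply(p$prob, function(df) {
    m <- as.matrix(df)
    rownames(m) <- p$biomarkers
    m
  })
  cutoffs <- NULL
  if (!is.null(p$cutoffs)) {
    cutoffs <- lapply(seq_len(nrow(p$cutoffs)), function(i)
      new_cutoff(p$cutoffs$biomarker[i], p$cutoffs$threshold[i],
                 ifelse(p$cutoffs$direction[i] == "U_sick", 1, -1) *
                   p$cutoffs$youden_j[i]))
    names(cutoffs) <- p$cutoffs$biomarker
  }
  model <- structure(
    list(classes = p$classes, alpha = p$alpha,
         n_per_class = stats::setNames(unlist(p$n_per_class), p$classes),
         prob = prob, cutoffs = cutoffs),
    class = "flip_model")
  model$ranks <- as.matrix(p$ranks)
  rownames(model$ranks) <- p$biomarkers
  model
}
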