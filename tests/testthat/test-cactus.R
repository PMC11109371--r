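# Flip matrices for model tests are built directly as character matrices;
# fit_flip_model accepts any patients x markers matrix over {"U","D",NA}.

flips_from_counts <- function(nU_sick, n_sick, nU_healthy, n_healthy,
                              marker = "m1") {
  m <- matrix(c(rep(c("U", "D"), c(nU_sick, n_sick - nU_sick)),
                rep(c("U", "D"), c(nU_healthy, n_healthy - nU_healthy))),
              ncol = 1, dimnames = list(NULL, marker))
  list(flips = m, labels = rep(c("sick", "healthy"), c(n_sick, n_healthy)))
}

test_that("conditional probabilities are smoothed relative frequencies", {
  d <- flips_from_counts(8, 10, 3, 10)
  m0 <- fit_flip_model(d$flips, d$labels, alpha = 0)
  expect_equal(m0$prob$U["m1", "sick"], 0.8)
  expect_equal(m0$prob$U["m1", "healthy"], 0.3)

  d0 <- flips_from_counts(0, 10, 5, 10)
  mj <- fit_flip_model(d0$flips, d0$labels, alpha = 0.5)
  expect_equal(mj$prob$U["m1", "sick"], 0.5 / 11)   # (0 + 0.5)/(10 + 1)
  expect_error(fit_flip_model(d0$flips, d0$labels, alpha = 0), "alpha")
  expect_error(fit_flip_model(d$flips, rep("sick", 20)), "both classes")

  # normalization holds exactly for every marker and class
  set.seed(3)
  fl <- matrix(sample(c("U", "D", NA), 200, TRUE, c(.45, .45, .1)), 20,
               dimnames = list(NULL, paste0("b", 1:10)))
  fit <- fit_flip_model(fl, rep(c("sick", "healthy"), 10))
  expect_equal(fit$prob$U + fit$prob$D,
               matrix(1, 10, 2, dimnames = dimnames(fit$prob$U)))
})

test_that("ranks are mean absolute pairwise differences across classes", {
  d <- flips_from_counts(8, 10, 3, 10)
  m <- fit_flip_model(d$flips, d$labels, alpha = 0)
  expect_equal(flip_rank(m, "m1", "U"), 0.5)        # |0.8 - 0.3|
  expect_error(flip_rank(m, "nope"), "unknown")

  # uninformative marker: equal probabilities, rank 0
  d2 <- flips_from_counts(4, 10, 4, 10)
  m2 <- fit_flip_model(d2$flips, d2$labels, alpha = 0)
  expect_equal(flip_rank(m2, "m1", "U"), 0)

  # three classes with P(U|c) = 0.9, 0.5, 0.1: checked against a brute-force
  # enumeration of the C(3,2) pairs
  fl3 <- matrix(c(rep(c("U", "D"), c(9, 1)), rep(c("U", "D"), c(5, 5)),
                  rep(c("U", "D"), c(1, 9))), ncol = 1,
                dimnames = list(NULL, "m1"))
  lab3 <- rep(c("a", "b", "c"), each = 10)
  m3 <- fit_flip_model(fl3, lab3, alpha = 0)
  p <- m3$prob$U["m1", c("a", "b", "c")]
  pairs <- combn(3, 2)
  oracle <- sum(abs(p[pairs[1, ]] - p[pairs[2, ]])) / ncol(pairs)
  expect_equal(flip_rank(m3, "m1", "U"), oracle)
  expect_equal(flip_rank(m3, "m1", "U"), (0.4 + 0.8 + 0.4) / 3)
})

test_that("rank symmetry R(U) = R(D) holds on every fitted model", {
  set.seed(14)
  for (i in 1:10) {
    fl <- matrix(sample(c("U", "D", NA), 300, TRUE, c(.4, .4, .2)), 30,
                 dimnames = list(NULL, paste0("b", 1:10)))
    fit <- fit_flip_model(fl, sample(rep(c("sick", "healthy"), 15)))
    expect_equal(fit$ranks[, "U"], fit$ranks[, "D"])
  }
})

test_that("cost scores are the log-space class-conditional products", {
  # two markers, patient (U, U): C_sick = 0.8*0.7, C_healthy = 0.3*0.4
  model <- fit_flip_model(
    matrix(c(rep(c("U", "D"), c(8, 2)), rep(c("U", "D"), c(3, 7)),
             rep(c("U", "D"), c(7, 3)), rep(c("U", "D"), c(4, 6))),
           ncol = 2, dimnames = list(NULL, c("m1", "m2"))),
    rep(c("sick", "healthy"), each = 10), alpha = 0)
  sc <- cost_scores(c(m1 = "U", m2 = "U"), model)
  expect_equal(exp(sc$log_cost[["sick"]]), 0.8 * 0.7)
  expect_equal(exp(sc$log_cost[["healthy"]]), 0.3 * 0.4)
  expect_equal(sc$predicted, "sick")
  expect_equal(sc$n_markers_used, 2)

  # missing flips contribute exponent zero (factor 1)
  sc1 <- cost_scores(c(m1 = "U", m2 = NA), model)
  expect_equal(exp(sc1$log_cost[["sick"]]), 0.8)
  expect_equal(sc1$n_markers_used, 1)
  expect_error(cost_scores(c(m1 = NA, m2 = NA), model), "missing")

  # exact tie goes to sick (screening favours sensitivity)
  tie_model <- fit_flip_model(
    matrix(rep(c("U", "D"), c(10, 10)), ncol = 1,
           dimnames = list(NULL, "m1")),
    rep(c("sick", "healthy"), 10), alpha = 0)
  expect_equal(cost_scores(c(m1 = "U"), tie_model)$predicted, "sick")
})

test_that("log-space scores equal the direct product within 1e-12", {
  set.seed(8)
  fl <- matrix(sample(c("U", "D"), 40 * 6, TRUE), 40,
               dimnames = list(NULL, paste0("b", 1:6)))
  model <- fit_flip_model(fl, sample(rep(c("sick", "healthy"), 20)))
  for (i in sample(40, 5)) {
    row <- fl[i, ]
    sc <- cost_scores(row, model)
    oracle <- brute_force_cost(row, model)
    expect_equal(exp(sc$log_cost), oracle, tolerance = 1e-12)
  }
})

test_that("classification is invariant to column order and class priors", {
  co <- log_transform(generate_cohort(sim_config(60, 30, p = 5, shift = 1),
                                      seed = 17))
  cuts <- fit_cutoffs(co)
  fl <- abstract_flips(co, cuts)
  model <- fit_flip_model(fl, co$label, alpha = 0.5)
  pred <- classify(fl, model)

  # permuting biomarker columns changes nothing (product commutativity)
  perm <- unclass(fl)[, sample(ncol(fl))]
  expect_equal(as.vector(classify(perm, model)), as.vector(pred))

  # duplicating all sick rows x3 leaves fitted probabilities and predictions
  # unchanged: the decision rule has no class-prior term
  idx <- c(seq_len(nrow(fl)), rep(which(co$label == "sick"), 2))
  model_dup <- fit_flip_model(unclass(fl)[idx, ], co$label[idx], alpha = 0)
  model_ref <- fit_flip_model(fl, co$label, alpha = 0)
  expect_equal(model_dup$prob, model_ref$prob)
  expect_equal(as.vector(classify(fl, model_dup)),
               as.vector(classify(fl, model_ref)))
})

test_that("a perfectly separating marker reproduces the labels", {
  csv <- file.path(tempdir(), "sep.csv")
  lines <- c('patient_id,gender,age,diagnosis,label,m1',
             sprintf('S%02d,M,60,bladder cancer,sick,%g', 1:10, 10 + 1:10),
             sprintf('H%02d,M,60,no cause identified,healthy,%g', 1:10, 1:10))
  writeLines(lines, csv)
  co <- log_transform(read_cohort_csv(csv, lod_sidecar = tempfile()))
  fl <- abstract_flips(co, fit_cutoffs(co))
  model <- fit_flip_model(fl, co$label)
  expect_equal(as.vector(classify(fl, model)), co$label)
  expect_error(classify(fl[, 0, drop = FALSE], model), "mismatch")
})

test_that("top_ranked orders by rank, clamps k, and recovers truth", {
  # informative markers mk01..mk05, pure-noise markers appended
  specs <- rbind(
    do.call(rbind, lapply(1:5, function(j)
      biomarker_spec(sprintf("mk%02d", j), "au", 0, 1.5, log_sd = 0.5))),
    do.call(rbind, lapply(6:10, function(j)
      biomarker_spec(sprintf("mk%02d", j), "au", 0, 0, log_sd = 0.5))))
  cfg <- generator_config(4000, 0, 2000, 0, biomarkers = specs)
  co <- log_transform(generate_cohort(cfg, seed = 23))
  fl <- abstract_flips(co, fit_cutoffs(co))
  model <- fit_flip_model(fl, co$label)
  top <- top_ranked(model, 5)
  expect_setequal(top$biomarker, sprintf("mk%02d", 1:5))
  expect_true(all(diff(top$rank) <= 0))
  expect_equal(nrow(top_ranked(model, 100)), 10)    # clamped to marker count
  expect_named(top, c("biomarker", "flip", "rank", "p_sick", "p_healthy"))
})

test_that("models survive a JSON round trip", {
  co <- log_transform(generate_cohort(sim_config(30, 30, p = 4), seed = 19))
  fl <- abstract_flips(co, fit_cutoffs(co))
  model <- fit_flip_model(fl, co$label)
  path <- tempfile(fileext = ".json")
  write_flip_model(model, path)
  back <- read_flip_model(path)
  expect_equal(back$prob, model$prob)
  expect_equal(back$ranks, model$ranks)
  expect_equal(back$alpha, model$alpha)
  expect_equal(as.vector(classify(fl, back)), as.vector(classify(fl, model)))
  reflips <- abstract_flips(co, back$cutoffs)
  expect_identical(as.vector(unclass(reflips)), as.vector(unclass(fl)))
})
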