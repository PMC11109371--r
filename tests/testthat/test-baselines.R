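test_that("silhouette scan matches the textbook definition on 6 points", {
  # two tight triplets on a line: hand-computable silhouette at k = 2
  x <- matrix(c(0, 0.5, 1, 10, 10.5, 11), ncol = 1)
  scan <- silhouette_scan(x, k_min = 1, k_max = 4, seed = 2, scale = FALSE)
  expect_equal(scan$best_k, 2)
  expect_true(is.na(scan$scores$mean_silhouette[scan$scores$k == 1]))

  # oracle: mean over points of (b - a) / max(a, b) with explicit distances
  pts <- as.vector(x)
  cl <- rep(1:2, each = 3)
  sil <- vapply(seq_along(pts), function(i) {
    same <- setdiff(which(cl == cl[i]), i)
    a <- mean(abs(pts[i] - pts[same]))
    b <- mean(abs(pts[i] - pts[cl != cl[i]]))
    (b - a) / max(a, b)
  }, 0)
  got <- scan$scores$mean_silhouette[scan$scores$k == 2]
  expect_equal(got, mean(sil), tolerance = 1e-10)
})

test_that("silhouette scan selects the generative number of blobs", {
  set.seed(1)
  blob <- function(n, mx, my) cbind(rnorm(n, mx, 0.5), rnorm(n, my, 0.5))
  two <- rbind(blob(40, 0, 0), blob(40, 8, 8))
  three <- rbind(blob(30, 0, 0), blob(30, 8, 8), blob(30, 8, -8))
  expect_equal(silhouette_scan(two, 1, 6, seed = 4)$best_k, 2)
  expect_equal(silhouette_scan(three, 1, 6, seed = 4)$best_k, 3)
  # determinism under a fixed seed
  s1 <- silhouette_scan(two, 2, 5, seed = 9)
  s2 <- silhouette_scan(two, 2, 5, seed = 9)
  expect_identical(s1, s2)
  expect_error(silhouette_scan(two[1:2, , drop = FALSE], 2, 3), "3 rows")
})

test_that("single-marker logistic regression selects form and scores", {
  # marker identical across classes: uninformative, balanced accuracy 0.5
  r <- single_marker_logit(rep(1:5, 20), rep(c("sick", "healthy"), 50))
  expect_equal(r$balanced_accuracy, 0.5)

  # extreme imbalance with a weak marker: all-sick prediction, 0.5
  set.seed(44)
  vals <- c(rnorm(444, 0.1), rnorm(41, 0))
  labs <- rep(c("sick", "healthy"), c(444, 41))
  r2 <- single_marker_logit(vals, labs)
  expect_equal(r2$balanced_accuracy, 0.5)

  # U-shaped relationship: the natural-cubic-spline form must win
  set.seed(45)
  x <- rnorm(400)
  y <- ifelse(abs(x) > 1, "sick", "healthy")
  r3 <- single_marker_logit(x, y)
  expect_equal(r3$chosen_form, "spline")
  expect_gt(r3$balanced_accuracy, 0.7)

  expect_error(single_marker_logit(1:4, rep("sick", 4)), "both classes")
})

test_that("perfect separation is flagged but still scored", {
  x <- c(1:20, 41:60)
  y <- rep(c("healthy", "sick"), each = 20)
  r <- single_marker_logit(x, y)
  expect_true(r$separation)
  expect_equal(r$balanced_accuracy, 1)
})

test_that("stratified folds are reproducible and balanced", {
  labels <- rep(c("sick", "healthy"), c(444, 41))
  f1 <- cv_folds(labels, k = 10, repeats = 3, seed = 12)
  f2 <- cv_folds(labels, k = 10, repeats = 3, seed = 12)
  expect_identical(f1, f2)
  for (r in 1:3) {
    sizes <- table(f1[, r])
    expect_lte(diff(range(sizes)), 2)    # n not divisible by k
    # every fold keeps at least 3 healthy patients (41 over 10 folds)
    healthy_per_fold <- table(f1[labels == "healthy", r])
    expect_lte(diff(range(healthy_per_fold)), 1)
  }
})

test_that("tree and forest recover separable structure under CV", {
  cfg <- sim_config(n_sick = 60, n_healthy = 60, p = 4, shift = 4,
                    log_sd = 0.5)
  co <- impute_median(log_transform(generate_cohort(cfg, seed = 3)))
  tr <- tree_cv(co, seed = 5)
  expect_gte(tr$metrics$balanced_accuracy, 0.95)
  fo <- forest_cv(co, seed = 5, ntree = 150)
  expect_gte(fo$metrics$balanced_accuracy, 0.95)
  expect_named(fo$top10, c("feature", "importance"))
  expect_equal(length(tr$predictions), nrow(co))
})

test_that("shuffled labels give chance-level pooled accuracy", {
  cfg <- sim_config(n_sick = 60, n_healthy = 60, p = 4, shift = 1,
                    log_sd = 0.5)
  co <- impute_median(log_transform(generate_cohort(cfg, seed = 7)))
  set.seed(70)
  bas <- replicate(10, {
    co$label <- sample(co$label)
    tree_cv(co, seed = sample.int(1e6, 1))$metrics$balanced_accuracy
  })
  expect_true(all(abs(bas - 0.5) <= 0.12))
  expect_lte(abs(mean(bas) - 0.5), 0.05)
})

test_that("the local explainer recovers a single-feature rule", {
  set.seed(21)
  background <- data.frame(f1 = rnorm(300), f2 = rnorm(300), f3 = rnorm(300))
  med <- median(background$f1)
  predict_fn <- function(d) as.numeric(d$f1 > med)
  wins <- vapply(1:20, function(s) {
    ex <- local_explain(predict_fn, background[7, ], background,
                        n_samples = 300, seed = s)
    ex$feature[which.max(abs(ex$mean_weight))] == "f1"
  }, TRUE)
  expect_gte(mean(wins), 0.95)

  # constant prediction function: all feature weights vanish
  ex0 <- local_explain(function(d) rep(0.4, nrow(d)), background[1, ],
                       background, n_samples = 200, seed = 1)
  expect_true(all(abs(ex0$mean_weight) < 1e-6))

  # determinism: identical seed, identical bins and weights
  e1 <- local_explain(predict_fn, background[3, ], background, seed = 9)
  e2 <- local_explain(predict_fn, background[3, ], background, seed = 9)
  expect_identical(e1, e2)

  # constant features are excluded with a warning
  bg2 <- background
  bg2$f3 <- 1
  expect_warning(local_explain(predict_fn, bg2[1, ], bg2, seed = 2,
                               n_samples = 100), "constant")
})
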