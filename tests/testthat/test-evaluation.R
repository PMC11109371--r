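test_that("metrics follow their defining identities", {
  m <- classification_metrics(confusion(tp = 40, fp = 5, tn = 45, fn = 10),
                              chi2 = FALSE)
  expect_equal(m$sensitivity, 40 / 50)
  expect_equal(m$specificity, 45 / 50)
  expect_equal(m$accuracy, 85 / 100)
  expect_equal(m$balanced_accuracy, (0.8 + 0.9) / 2)

  # symmetry: sensitivity = specificity = s gives balanced accuracy s
  s <- classification_metrics(confusion(30, 10, 30, 10), chi2 = FALSE)
  expect_equal(s$balanced_accuracy, s$sensitivity)

  # accuracy identity on random confusions:
  # accuracy = (sens * n_sick + spec * n_healthy) / n
  set.seed(2)
  for (i in 1:20) {
    cf <- confusion(sample(1:50, 1), sample(1:50, 1), sample(1:50, 1),
                    sample(1:50, 1))
    mm <- classification_metrics(cf, chi2 = FALSE)
    n_sick <- cf$tp + cf$fn
    n_healthy <- cf$tn + cf$fp
    expect_equal(mm$accuracy,
                 (mm$sensitivity * n_sick + mm$specificity * n_healthy) /
                   cf$n)
  }
  expect_error(classification_metrics(confusion(0, 3, 4, 0), chi2 = FALSE),
               "positive")
})

test_that("reporting rounds to 3 decimals half away from zero", {
  expect_equal(round_half_up(0.7505), 0.751)
  expect_equal(round_half_up(-0.7505), -0.751)
  expect_equal(round_half_up(0.7185), 0.719)
  expect_equal(round_half_up(2.5, 0), 3)
  tab <- metrics_table(list(
    a = classification_metrics(confusion(777, 171, 829, 223), chi2 = FALSE)))
  expect_equal(tab$sensitivity, 0.777)
  expect_equal(tab$balanced_accuracy, 0.803)
})

test_that("chi-squared vs chance behaves across regimes", {
  # perfectly correct predictions on a balanced n = 100: X2 = n, p ~ 1e-23
  expect_lt(chi2_vs_chance(confusion(50, 0, 50, 0)), 1e-15)

  # all patients predicted sick: zero marginal, warning, p = 1
  expect_warning(p <- chi2_vs_chance(confusion(90, 10, 0, 0)), "degenerate")
  expect_equal(p, 1)

  # calibration under the permutation null: random predictions on shuffled
  # labels give p > 0.05 in at least 90% of shuffles
  set.seed(33)
  truth <- rep(c("sick", "healthy"), c(523, 152))
  hits <- replicate(50, {
    pred <- sample(truth)
    chi2_vs_chance(confusion_counts(truth, pred)) > 0.05
  })
  expect_gte(mean(hits), 0.9)

  # matches the uncorrected Pearson test from stats:: on a plain table
  cf <- confusion(40, 20, 30, 10)
  ref <- stats::chisq.test(matrix(c(40, 10, 20, 30), 2), correct = FALSE)
  expect_equal(chi2_vs_chance(cf), unname(ref$p.value))
})

test_that("McNemar discordance logic and both p-value paths work", {
  truth <- rep("sick", 10)
  expect_equal(mcnemar_test(truth, truth, truth)$p.value, 1.0)

  # b = c = 5: perfect symmetry, exact p = 1
  pa <- rep(c("sick", "healthy"), 5)
  pb <- rev(pa)
  r <- mcnemar_test(pa, pb, truth)
  expect_equal(r$b, 5)
  expect_equal(r$c, 5)
  expect_equal(r$p.value, 1.0)
  expect_match(r$method, "exact")

  # large-sample path: b = 15, c = 45 uses the corrected chi-squared
  truth2 <- rep("sick", 60)
  pa2 <- rep(c("sick", "healthy"), c(15, 45))
  pb2 <- rep(c("healthy", "sick"), c(15, 45))
  r2 <- mcnemar_test(pa2, pb2, truth2)
  expect_match(r2$method, "chi-squared")
  expect_equal(r2$p.value,
               pchisq((abs(15 - 45) - 1)^2 / 60, 1, lower.tail = FALSE))
  # and agrees with the stats:: implementation of the same statistic
  ref <- stats::mcnemar.test(matrix(c(0, 45, 15, 0), 2), correct = TRUE)
  expect_equal(r2$p.value, unname(ref$p.value))
})

test_that("pairwise McNemar matrix is symmetric with an NA diagonal", {
  set.seed(6)
  truth <- sample(c("sick", "healthy"), 80, TRUE)
  preds <- list(a = sample(truth), b = sample(truth), c = truth)
  m <- mcnemar_matrix(preds, truth)
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  expect_equal(m["a", "b"],
               mcnemar_test(preds$a, preds$b, truth)$p.value)
})

test_that("the boundary table reports raw-scale cut-offs and '-' gaps", {
  # a flip model whose microalbumin cut-off is 2.597 on the ln scale
  csv <- file.path(tempdir(), "bt.csv")
  writeLines(c(
    'patient_id,gender,age,diagnosis,label,microalbumin,other',
    sprintf('S%d,M,60,bladder cancer,sick,%g,%g', 1:6,
            exp(2.597) * c(1.1, 1.2, 1.3, 1.35, 1.4, 1.5), 1:6),
    sprintf('H%d,M,60,no cause identified,healthy,%g,%g', 1:6,
            exp(2.597) * c(0.5, 0.6, 0.7, 0.8, 0.9, 0.999), 1:6)
  ), csv)
  co <- log_transform(read_cohort_csv(csv, lod_sidecar = tempfile()))
  cuts <- fit_cutoffs(co)
  cuts$microalbumin$threshold <- 2.597    # pin the reported boundary
  fl <- abstract_flips(co, cuts)
  model <- fit_flip_model(fl, co$label)

  tab <- boundary_table(list(cactus.male = model), log_scale = TRUE)
  row <- tab[tab$biomarker == "microalbumin", ]
  expect_equal(as.numeric(row$cactus.male), 13.43, tolerance = 1e-3)

  # markers a model did not select print as "-": degenerate marker dropped
  expect_equal(boundary_table(list())$biomarker, character(0))
})
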