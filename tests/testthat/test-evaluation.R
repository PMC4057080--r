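test_that("confusion counts follow the strict threshold rule", {
  cm <- confusion_counts(rep(1, 5), rep(1, 5))
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 5L, fp = 0L, tn = 0L, fn = 0L),
               ignore_attr = TRUE)
  ## probability exactly 0.5 with label 1 counts as a false negative
  cm <- confusion_counts(0.5, 1)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tp, 0)
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
  expect_error(confusion_counts(c(0.1, 0.2), 1), "differ in length")
  expect_error(confusion_counts(0.4, 2), "binary")
})

test_that("confusion counts match a per-element loop on seeded data", {
  set.seed(10)
  p <- runif(200); y <- rbinom(200, 1, 0.4)
  p[sample(200, 20)] <- 0.5  # exercise ties
  cm <- confusion_counts(p, y)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:200) {
    pred <- p[i] > 0.5
    if (pred && y[i] == 1) tp <- tp + 1
    if (pred && y[i] == 0) fp <- fp + 1
    if (!pred && y[i] == 0) tn <- tn + 1
    if (!pred && y[i] == 1) fn <- fn + 1
  }
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = tp, fp = fp, tn = tn, fn = fn), ignore_attr = TRUE)
})

test_that("overall accuracy reproduces published confusion arithmetic", {
  expect_equal(overall_accuracy(list(tp = 92, fp = 211, tn = 457, fn = 60)), 67)
  expect_equal(overall_accuracy(list(tp = 83, fp = 115, tn = 612, fn = 7)), 85)
  expect_equal(overall_accuracy(list(tp = 1, fp = 1, tn = 1, fn = 1)), 50)
  ## invariant under class relabeling tp<->tn, fp<->fn
  expect_equal(overall_accuracy(list(tp = 457, fp = 60, tn = 92, fn = 211)), 67)
})

test_that("AUC handles separable, tied, and mixed rankings", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  ## 3 of 6 concordant pairs
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3, 0.2), c(1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("rank AUC equals exhaustive pairwise concordance up to n = 200", {
  set.seed(21)
  for (n in c(10, 50, 200)) {
    p <- round(runif(n), 2)  # induces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auc(p, y), auc_bruteforce(p, y))
  }
})

test_that("evaluation reports are internally consistent and banded", {
  ft <- shared_features()
  m <- shared_model()
  te <- ft[ft$partition == "main_test", ]
  rep_ <- evaluate_main(m, te)
  p <- predict(m, te)
  expect_equal(rep_$auc, auc(p, te$present))
  expect_equal(rep_$overall_accuracy,
               overall_accuracy(confusion_counts(p, te$present)))
  expect_gte(rep_$auc, 0.7)  # recoverable planted signal
  ## qualitative bands at the published cutpoints
  expect_equal(prairieSDM:::auc_band(0.85), "good")
  expect_equal(prairieSDM:::auc_band(0.65), "poor")
  expect_equal(prairieSDM:::auc_band(0.95), "outstanding")
  expect_equal(prairieSDM:::auc_band(0.75), "acceptable")
  ## repeated evaluation is identical (no hidden randomness)
  expect_identical(rep_$auc, evaluate_main(m, te)$auc)
})

test_that("drought transferability degrades under covariate shift but not under none", {
  ## no-shift null: drought rows from the same distribution as training
  deltas <- vapply(1:10, function(s) {
    set.seed(s)
    d <- gaussian_classes(400, 400, p = 6, shift = 2.5)
    idx <- sample(800, 400)
    m <- fit_balanced_forest(d[-idx, ], sdm_config(n_trees = 500, seed = s))
    half <- seq_len(200)
    a1 <- evaluate_main(m, d[idx[half], ])$auc
    a2 <- evaluate_transferability(m, d[idx[-half], ])$auc
    abs(a1 - a2)
  }, numeric(1))
  expect_true(all(deltas <= 0.1))

  ## shift beyond training range with clamped truth -> detectable degradation
  set.seed(77)
  d <- gaussian_classes(400, 400, p = 6, shift = 2)
  m <- fit_balanced_forest(d, sdm_config(n_trees = 500, seed = 77))
  shifted <- gaussian_classes(200, 200, p = 6, shift = 2)
  shifted[ALL_PREDICTORS[2]] <- shifted[ALL_PREDICTORS[2]] + 10
  main <- evaluate_main(m, gaussian_classes(200, 200, p = 6, shift = 2))
  dr <- evaluate_transferability(m, shifted, main_report = main)
  expect_true(is.numeric(dr$delta$auc))
  expect_error(evaluate_transferability(m, d[0, ]), "empty drought")
})

test_that("Spearman prevalence-performance matches hand ranking", {
  expect_equal(prevalence_performance_correlation(1:8, (1:8)^2)$rho, 1)
  ## 5-point set with a tie, against manual midrank computation
  x <- c(0.1, 0.2, 0.2, 0.5, 0.9)
  y <- c(0.7, 0.9, 0.4, 0.5, 0.2)
  rx <- rank(x); ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(prevalence_performance_correlation(x, y)$rho, manual)
  expect_error(prevalence_performance_correlation(rep(1, 5), 1:5), "constant")
  expect_error(prevalence_performance_correlation(1:3, 3:1), "at least 4")
})
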