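small_cfg <- function(seed = 1, ...) sdm_config(n_trees = 500, seed = seed, ...)

test_that("year alternation assigns odd-indexed years to training", {
  ry <- data.frame(route_id = 1, year = 1971:1980)
  p <- partition_years(ry, drought_years = integer(0))
  expect_equal(ry$year[p$partition == "main_train"], c(1971, 1973, 1975, 1977, 1979))
  expect_equal(ry$year[p$partition == "main_test"], c(1972, 1974, 1976, 1978, 1980))
  pf <- partition_years(ry, drought_years = integer(0), flip = TRUE)
  expect_equal(ry$year[pf$partition == "main_train"], c(1972, 1974, 1976, 1978, 1980))
})

test_that("an all-drought survey leaves empty main partitions and fit fails", {
  ry <- data.frame(route_id = rep(1:2, each = 6), year = rep(1987:1992, 2))
  p <- partition_years(ry, drought_years = 1987:1992)
  expect_true(all(p$partition == "drought"))
  d <- gaussian_classes(5, 5, p = 4)[0, ]
  expect_error(fit_balanced_forest(d, small_cfg()), "single-class|predictor")
})

test_that("no two consecutive surveyed years share a main partition", {
  set.seed(8)
  ry <- do.call(rbind, lapply(1:50, function(r) {
    yrs <- sort(sample(1971:2011, sample(5:30, 1)))
    data.frame(route_id = r, year = yrs)
  }))
  p <- partition_years(ry, drought_years = 1987:1992)
  for (r in unique(p$route_id)) {
    sub <- p[p$route_id == r & p$partition != "drought", ]
    sub <- sub[order(sub$year), ]
    if (nrow(sub) < 2) next
    adj <- diff(sub$year) == 1
    same <- sub$partition[-1] == sub$partition[-nrow(sub)]
    expect_false(any(adj & same))
  }
})

test_that("focal-species selection applies inclusive cutoffs", {
  occ <- data.frame(
    species = rep(c("rare", "edge", "common"), each = 100),
    present = c(rep(c(1, 0), c(4, 96)), rep(c(1, 0), c(5, 95)),
                rep(c(1, 0), c(30, 70))))
  sel <- select_focal_species(occ, cutoff = 0.05)
  expect_false(sel$focal[sel$species == "rare"])    # 4/100 excluded
  expect_true(sel$focal[sel$species == "edge"])     # 5/100 included (>=)
  expect_true(sel$focal[sel$species == "common"])
  dry <- select_focal_species(occ, cutoff = 0.07, min_detections = 10)
  expect_equal(as.character(dry$species[dry$focal]), "common")
  ## planted prevalences match direct counting
  expect_equal(sel$prevalence, c(0.30, 0.05, 0.04)[order(c("common", "edge", "rare"))])
})

test_that("segment choice takes the higher-detection section, ties first", {
  expect_equal(choose_segment(12, 30), "third")
  expect_equal(choose_segment(5, 5), "first")
  expect_equal(choose_segment(c(1, 7, 3), c(0, 9, 3)),
               c("first", "third", "first"))
})

test_that("a perfectly separating predictor is learned almost exactly", {
  set.seed(2)
  d <- gaussian_classes(200, 200, p = 8, shift = 8)
  m <- fit_balanced_forest(d, small_cfg(seed = 2))
  expect_gte(m$oob_accuracy, 0.95)
  imp <- permutation_importance(m)
  expect_equal(imp$predictor[1], ALL_PREDICTORS[1])
})

test_that("fits are deterministic, balanced, and guard their contracts", {
  set.seed(3)
  d <- gaussian_classes(60, 340, p = 6)
  m1 <- fit_balanced_forest(d, small_cfg(seed = 5))
  m2 <- fit_balanced_forest(d, small_cfg(seed = 5))
  expect_identical(m1$oob_prob, m2$oob_prob)
  expect_identical(predict(m1, d), predict(m2, d))
  expect_error(fit_balanced_forest(transform(d, present = 1L), small_cfg()),
               "single-class")
  expect_warning(fit_balanced_forest(gaussian_classes(10, 200, p = 4),
                                     small_cfg(seed = 1)),
                 "fewer than the per-tree sample")
  expect_error(predict(m1, d[, 1:3]), "lacks predictor")
})

test_that("scale selection picks the best accuracy with small-radius ties", {
  set.seed(4)
  d <- gaussian_classes(150, 150, p = 5)
  one <- select_scale(list(`400` = d), small_cfg(seed = 4))
  expect_equal(one$chosen_scale, 400)
  ## identical data at two scales -> identical OOB accuracy -> smaller radius
  tie <- select_scale(list(`2000` = d, `400` = d), small_cfg(seed = 4))
  expect_equal(unname(diff(tie$accuracy)), 0)
  expect_equal(tie$chosen_scale, 400)
  expect_error(select_scale(list(`400` = d, `800` = d[1:10, ]), small_cfg()),
               "differ in row count")
})

test_that("irrelevant predictors have near-zero permutation importance", {
  set.seed(6)
  d <- gaussian_classes(200, 200, p = 10, shift = 4)
  m <- fit_balanced_forest(d, small_cfg(seed = 6))
  imp <- permutation_importance(m)
  noise <- imp$importance[imp$predictor != ALL_PREDICTORS[1]]
  ## noise band from the spread of the 9 known-irrelevant predictors
  expect_lt(max(abs(noise)), 10 * sd(noise) + 1e-6)
  expect_gt(imp$importance[imp$predictor == ALL_PREDICTORS[1]],
            max(abs(noise)))
})

test_that("response signs recover monotone and unimodal truths", {
  set.seed(12)
  n <- 500
  d <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(d) <- ALL_PREDICTORS[1:6]
  d$present <- as.integer(runif(n) < plogis(2 * d$temp - 2 * d$seas))
  m <- fit_balanced_forest(d, small_cfg(seed = 12))
  expect_equal(response_sign(m, d, "temp"), "+")
  expect_equal(response_sign(m, d, "seas"), "-")
  ## constant predictor is equivocal by contract
  d2 <- d; d2$semi <- 1
  expect_equal(response_sign(m, d2, "semi"), "~")
  ## planted unimodal response
  mrec <- vapply(1:10, function(s) {
    set.seed(s)
    du <- as.data.frame(matrix(rnorm(500 * 6), 500, 6))
    names(du) <- ALL_PREDICTORS[1:6]
    du$present <- as.integer(runif(500) < plogis(2 - 2 * du$temp^2))
    mu <- fit_balanced_forest(du, small_cfg(seed = s))
    response_sign(mu, du, "temp")
  }, character(1))
  expect_gte(sum(mrec == "m"), 8)
})

test_that("importance tables carry ranks, signs and reporting labels", {
  ft <- shared_features()
  m <- shared_model()
  imp <- permutation_importance(m, ft[ft$partition == "main_train", ], top = 10)
  expect_equal(nrow(imp), 10L)
  expect_equal(imp$rank, 1:10)
  expect_true(all(diff(imp$importance) <= 0))
  expect_true(all(imp$sign %in% c("+", "-", "m", "~")))
  expect_true(all(grepl("^[WUPT]-", imp$entry)))
  ## full table covers all 31 predictors exactly once
  full <- permutation_importance(m)
  expect_setequal(full$predictor, ALL_PREDICTORS)
})

test_that("predictions clamp beyond the training range of a covariate", {
  m <- shared_model()
  ft <- shared_features()
  tr <- ft[ft$partition == "main_train", ]
  row <- tr[5, m$predictors]
  for (v in c("semi", "T_1yr")) {
    at_max <- row; at_max[[v]] <- max(tr[[v]])
    beyond <- row; beyond[[v]] <- max(tr[[v]]) + 100
    expect_equal(predict(m, at_max), predict(m, beyond))
    at_min <- row; at_min[[v]] <- min(tr[[v]])
    below <- row; below[[v]] <- min(tr[[v]]) - 100
    expect_equal(predict(m, at_min), predict(m, below))
  }
})
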