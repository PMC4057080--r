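## Planted-truth validation benchmarks. Each run generates synthetic data
## whose true structure is known analytically, pushes it through the
## pipeline, and reports how well the pipeline recovers the truth. These
## back both the test suite and the acceptance script.

#' End-to-end range-contraction recovery run
#'
#' Plants a climate-limited virtual species (strong negative response to
#' annual temperature, positive to semipermanent wetland cover, intercept
#' 0 so training prevalence is near 0.5 and the balanced-forest vote
#' threshold coincides with the truth threshold), simulates surveys, fits
#' the balanced forest on the main training partition, projects baseline
#' (1981--2000) and future (2040--2049) suitability over a prediction
#' grid, and compares the pipeline's percent range change with the
#' analytic change computed from the species' true occurrence probability
#' on the same covariate stacks.
#'
#' @param seed integer seed for this replicate.
#' @param grid_dim prediction grid cells per side.
#' @return list: `model_change`, `truth_change` (raw signed percents),
#'   `gap` (model - truth), `prevalence`.
#' @export
contraction_recovery_run <- function(seed, grid_dim = 20) {
  sp <- virtual_species("planted", c(T_1yr = -3, semi = 1), intercept = 0,
                        response_scale = 2000)
  ds <- simulate_dataset(species = list(planted = sp), seed = seed)
  sv <- ds$survey
  truth <- sv$species$planted
  ft <- sv$covariates[["2000"]]
  ft$present <- sv$occurrences$present
  part <- partition_years(ft[c("route_id", "year")], drought_years = 1987:1992)
  tr <- ft[part$partition == "main_train", ]
  model <- fit_balanced_forest(tr, sdm_config(seed = seed),
                               species = "planted", scale_radius = 2000)
  pts <- attr(ds$climate, "points")
  stb <- build_grid_stack(ds$landscape, ds$covariates, pts, 2000,
                          1981:2000, "baseline", grid_dim)
  stf <- build_grid_stack(ds$landscape, ds$covariates_future, pts, 2000,
                          2040:2049, "future", grid_dim)
  ch <- percent_change(classify_suitability(predict_period_mean(model, stb)),
                       classify_suitability(predict_period_mean(model, stf),
                                            "future"))
  truth_map <- function(st) {
    p <- true_occurrence_probability(truth, st$features)
    as.vector(tapply(p, st$features$cell_id, mean))
  }
  tb <- truth_map(stb); tf <- truth_map(stf)
  truth_change <- 100 * (sum(tf > 0.5) - sum(tb > 0.5)) / sum(tb > 0.5)
  list(model_change = ch$percent_change_raw,
       truth_change = truth_change,
       gap = ch$percent_change_raw - truth_change,
       prevalence = mean(tr$present))
}

#' Planted-driver importance recovery run
#'
#' Plants a species driven by semipermanent wetland and grassland
#' composition (the two dominant coefficients), fits the balanced forest,
#' and asks whether both planted drivers occupy the top three importance
#' ranks. Drivers aliased by aggregate covariates (e.g. a weak annual
#' temperature signal shadowed by its less noisy multi-year proxies)
#' share permutation credit, so the benchmark plants unaliased drivers.
#'
#' @param seed integer seed.
#' @param coefficients planted coefficients.
#' @return list: `top3` (predictor names), `recovered` (both drivers in
#'   the top 3), `order_ok` (planted magnitude order preserved among the
#'   planted covariates), `importance` (full table).
#' @export
driver_recovery_run <- function(seed,
                                coefficients = c(semi = 2, grass = 1.5)) {
  sp <- virtual_species("planted", coefficients, 0, 2000)
  ds <- simulate_dataset(species = list(planted = sp), seed = seed,
                         future = FALSE)
  ft <- ds$survey$covariates[["2000"]]
  ft$present <- ds$survey$occurrences$present
  part <- partition_years(ft[c("route_id", "year")], drought_years = 1987:1992)
  m <- fit_balanced_forest(ft[part$partition == "main_train", ],
                           sdm_config(seed = seed))
  imp <- permutation_importance(m)
  planted <- names(coefficients)[order(-abs(coefficients))]
  list(top3 = imp$predictor[1:3],
       recovered = all(planted %in% imp$predictor[1:3]),
       order_ok = !is.unsorted(match(planted, imp$predictor)),
       importance = imp)
}

#' Response-scale recovery run
#'
#' Plants a species whose composition response acts at 2000 m, builds the
#' feature table at all six candidate scales, runs scale selection, and
#' reports the chosen radius.
#'
#' @param seed integer seed.
#' @return chosen scale radius (m).
#' @export
scale_recovery_run <- function(seed) {
  sp <- virtual_species("planted", c(semi = 2, grass = 1.5, crop = -1),
                        0, 2000)
  ds <- simulate_dataset(species = list(planted = sp), seed = seed,
                         future = FALSE)
  sv <- ds$survey
  comp <- composition_table(ds$landscape, segment_geometries(sv$routes))
  dsets <- lapply(CANONICAL_SCALES, function(r)
    build_feature_table(sv$occurrences, comp[comp$scale_radius == r, ],
                        ds$covariates, sv$segment_points))
  names(dsets) <- CANONICAL_SCALES
  dsets <- lapply(dsets, function(d) {
    part <- partition_years(d[c("route_id", "year")], 1987:1992)
    d[part$partition == "main_train", ]
  })
  select_scale(dsets, sdm_config(seed = seed))$chosen_scale
}

#' Permutation-null AUC run
#'
#' Shuffles a fixed 400-row, 31-predictor noise fixture's balanced
#' response independently of the predictors and reports the out-of-bag
#' AUC of the balanced forest, which should sit near 0.5.
#'
#' @param seed integer seed for the shuffle and forest.
#' @return out-of-bag AUC.
#' @export
null_auc_run <- function(seed) {
  set.seed(1)
  d <- as.data.frame(matrix(stats::rnorm(400 * 31), 400, 31))
  names(d) <- ALL_PREDICTORS
  set.seed(seed)
  d$present <- sample(rep(0:1, each = 200))
  m <- fit_balanced_forest(d, sdm_config(seed = seed))
  auc(m$oob_prob, d$present)
}

#' Prevalence-invariance run
#'
#' Two training sets share class-conditional covariate distributions
#' (one informative predictor shifted by 1.5 SD) but differ in prevalence
#' (0.1 vs 0.5, n = 2000 each). Balanced per-tree sampling should make
#' the two forests' probability surfaces nearly coincide on a common
#' evaluation grid.
#'
#' @param seed integer seed.
#' @param n training rows per dataset.
#' @return mean absolute probability difference over the common grid.
#' @export
prevalence_invariance_run <- function(seed, n = 2000) {
  set.seed(seed)
  gen <- function(n1, n0) {
    x1 <- matrix(stats::rnorm(n1 * 31), n1, 31); x1[, 1] <- x1[, 1] + 1.5
    x0 <- matrix(stats::rnorm(n0 * 31), n0, 31)
    d <- as.data.frame(rbind(x1, x0))
    names(d) <- ALL_PREDICTORS
    d$present <- c(rep(1L, n1), rep(0L, n0))
    d
  }
  d_low <- gen(round(0.1 * n), round(0.9 * n))
  d_bal <- gen(n / 2, n / 2)
  grid <- as.data.frame(matrix(stats::rnorm(200 * 31), 200, 31))
  names(grid) <- ALL_PREDICTORS
  m_low <- fit_balanced_forest(d_low, sdm_config(seed = seed))
  m_bal <- fit_balanced_forest(d_bal, sdm_config(seed = seed))
  mean(abs(predict(m_low, grid) - predict(m_bal, grid)))
}
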