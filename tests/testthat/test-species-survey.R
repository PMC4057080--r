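test_that("the truth function is an exact logistic oracle", {
  ## no coefficients, intercept 0 -> 0.5
  s0 <- virtual_species("null", c(), intercept = 0)
  expect_equal(true_occurrence_probability(s0, data.frame(x = 1)), 0.5)
  ## single coefficient +2 at standardized value 1 -> 1/(1 + exp(-2))
  s1 <- virtual_species("one", c(semi = 2), intercept = 0)
  s1$standardization <- list(center = c(semi = 0), scale = c(semi = 1))
  expect_equal(true_occurrence_probability(s1, c(semi = 1)),
               1 / (1 + exp(-2)))
  expect_equal(true_occurrence_probability(s1, c(semi = 1)), 0.8808,
               tolerance = 1e-4)
  ## monotone in a positively weighted covariate
  p <- true_occurrence_probability(s1, data.frame(semi = seq(-3, 3, 0.5)))
  expect_true(all(diff(p) > 0))
})

test_that("missing covariates and calibration are enforced by name", {
  s <- virtual_species("x", c(semi = 1, T_1yr = -1))
  expect_error(virtual_species("bad", c(nope = 1)), "unknown covariate")
  expect_error(virtual_species("bad", c(semi = 1), response_scale = 300),
               "canonical radii")
  expect_error(true_occurrence_probability(s, data.frame(semi = 1, T_1yr = 0)),
               "not calibrated")
  s <- calibrate_species(s, data.frame(semi = rnorm(50), T_1yr = rnorm(50)))
  expect_error(true_occurrence_probability(s, data.frame(semi = 1)), "T_1yr")
})

test_that("calibration stores generation-time constants", {
  set.seed(1)
  ref <- data.frame(semi = rnorm(100, 0.2, 0.05))
  s <- calibrate_species(virtual_species("x", c(semi = 2)), ref)
  expect_equal(s$standardization$center[["semi"]], mean(ref$semi))
  expect_equal(s$standardization$scale[["semi"]], sd(ref$semi))
  ## constant covariate falls back to unit scale
  s2 <- calibrate_species(virtual_species("x", c(semi = 2)),
                          data.frame(semi = rep(0.3, 10)))
  expect_equal(s2$standardization$scale[["semi"]], 1)
})

test_that("saturated intercepts give all-present / all-absent surveys", {
  l <- tiny_landscape(seed = 2, extent_cells = 128)
  cp <- climate_scenario_params(n_points = 4, n_years = 4, spin_up_years = 10,
                                start_year = 2001, drought_years = integer(0))
  cl <- generate_climate_series(cp, "historic")
  dn <- survey_design(n_routes = 3, surveyed_years = 2001:2004)
  hi <- virtual_species("hi", c(), intercept = 20)
  lo <- virtual_species("lo", c(), intercept = -20)
  sv <- simulate_surveys(l, cl, list(hi = hi, lo = lo), dn, seed = 5)
  occ <- sv$occurrences
  expect_true(all(occ$present[occ$species == "hi"] == 1L))
  expect_true(all(occ$present[occ$species == "lo"] == 0L))
  expect_equal(nrow(occ), 2 * 3 * 2 * 4)  # species x routes x segments x years
})

test_that("fixed-probability surveys match the binomial oracle", {
  l <- tiny_landscape(seed = 3, extent_cells = 128)
  cp <- climate_scenario_params(n_points = 4, n_years = 25, spin_up_years = 10,
                                start_year = 1987, drought_years = integer(0))
  cl <- generate_climate_series(cp, "historic")
  dn <- survey_design(n_routes = 40, surveyed_years = 1987:2011)
  p <- 0.3
  sp <- virtual_species("flat", c(), intercept = qlogis(p))
  sv <- simulate_surveys(l, cl, sp, dn, seed = 11)
  n <- nrow(sv$occurrences)
  expect_gte(n, 2000)
  expect_lt(abs(mean(sv$occurrences$present) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("segment prevalence tracks the mean true probability", {
  ds <- shared_dataset()
  occ <- ds$survey$occurrences
  tp <- ds$survey$true_prob
  n <- nrow(occ)
  expect_lt(abs(mean(occ$present) - mean(tp$true_prob)),
            3 * sqrt(0.25 / n) + 0.01)
})

test_that("surveys are deterministic given seed and fail on stray routes", {
  l <- tiny_landscape(seed = 2, extent_cells = 128)
  cp <- climate_scenario_params(n_points = 4, n_years = 3, spin_up_years = 10,
                                start_year = 2001, drought_years = integer(0))
  cl <- generate_climate_series(cp, "historic")
  dn <- survey_design(n_routes = 2, surveyed_years = 2001:2003)
  sp <- virtual_species("s", c(grass = 1))
  a <- simulate_surveys(l, cl, sp, dn, seed = 9)
  b <- simulate_surveys(l, cl, sp, dn, seed = 9)
  expect_identical(a$occurrences, b$occurrences)
  bad <- generate_routes(dn, l, seed = 1)
  bad$x[1] <- -50
  expect_error(simulate_surveys(l, cl, sp, dn, seed = 9, routes = bad),
               "outside the raster")
})

test_that("route geometry respects the fixed BBS segment layout", {
  expect_error(survey_design(segments = "second"))
  dn <- survey_design(n_routes = 4)
  expect_equal(dn$stops_per_segment, 10L)
  expect_equal(dn$stop_spacing, 800)
  r <- generate_routes(dn, tiny_landscape(seed = 1, extent_cells = 128),
                       seed = 3)
  expect_equal(nrow(r), 4 * 2 * 10)
  d <- r[r$segment_id == r$segment_id[1], ]
  gaps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  expect_equal(gaps, rep(800, 9), tolerance = 1e-9)
})
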