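test_that("noise-free limit reproduces the normals exactly", {
  cp <- climate_scenario_params(n_points = 4, n_years = 3, spin_up_years = 0,
                                annual_temp_anomaly_sd = 0,
                                annual_precip_anomaly_sd = 0,
                                spatial_temp_gradient = 0,
                                drought_years = integer(0))
  s <- generate_climate_series(cp, "historic")
  for (m in 1:12) {
    expect_equal(unique(s$tmean[s$month == m]), cp$monthly_temp_normals[m])
    expect_equal(unique(s$prcp[s$month == m]), cp$monthly_precip_normals[m])
  }
})

test_that("future months exceed their paired historic draws by the offset", {
  cp <- climate_scenario_params(n_points = 3, n_years = 5, spin_up_years = 2,
                                drought_years = 1972:1973,
                                future_temp_offset = 3.0,
                                future_precip_multiplier = 1.05)
  h <- generate_climate_series(cp, "historic")
  f <- generate_climate_series(cp, "future")
  key <- function(d) paste(d$point_id, d$year, d$month)
  f$year <- f$year - cp$future_year_shift
  i <- match(key(h), key(f))
  expect_false(anyNA(i))
  expect_equal(f$tmean[i] - h$tmean, rep(3.0, nrow(h)))
  ## precipitation pairing holds exactly outside the drought block
  nd <- !((h$year + (h$month >= 6)) %in% cp$drought_years)
  expect_equal(f$prcp[i][nd] / h$prcp[nd], rep(1.05, sum(nd)), tolerance = 1e-12)
})

test_that("drought precipitation ratio matches a resampling oracle", {
  cp <- climate_scenario_params(n_points = 50, n_years = 40, spin_up_years = 0,
                                start_year = 1971,
                                drought_years = 1981:1990,
                                drought_precip_multiplier = 0.6,
                                seed = 5)
  s <- generate_climate_series(cp, "historic")
  by <- s$year + (s$month >= 6)
  annual <- tapply(s$prcp, list(s$point_id, by), sum)
  expect_gte(length(annual), 2000)
  yearly <- colMeans(annual)  # anomalies are regional, so cluster by year
  is_dr <- as.integer(colnames(annual)) %in% 1981:1990
  ratio <- mean(yearly[is_dr]) / mean(yearly[!is_dr])
  ## year-level bootstrap SE of the ratio (independent resampling)
  set.seed(99)
  boots <- replicate(1000, {
    mean(sample(yearly[is_dr], replace = TRUE)) /
      mean(sample(yearly[!is_dr], replace = TRUE))
  })
  expect_lt(abs(ratio - 0.6), 3 * stats::sd(boots))
})

test_that("generation is deterministic and validates parameters", {
  cp <- climate_scenario_params(n_points = 2, n_years = 3, spin_up_years = 0,
                                drought_years = integer(0))
  expect_identical(generate_climate_series(cp, "historic"),
                   generate_climate_series(cp, "historic"))
  expect_error(climate_scenario_params(drought_precip_multiplier = 0), "> 0")
  expect_error(climate_scenario_params(n_years = 3, start_year = 2000,
                                       spin_up_years = 0,
                                       drought_years = 1987:1992),
               "outside the simulated")
})

test_that("constant series gives constant means and zero multi-year SDs", {
  s <- stepwise_series(2001:2012, tmeans = rep(10, 12), prcps = rep(40, 12))
  cv <- derive_climate_covariates(s)
  full <- cv[cv$complete_10yr, ]
  expect_true(nrow(full) >= 1)
  for (v in c("T_spr", "T_wint", "T_fall", "T_sum", "T_1yr", "T_5yr", "T_10yr"))
    expect_equal(unique(full[[v]]), 10)
  expect_equal(unique(full$T_5yr_sd), 0)
  expect_equal(unique(full$T_10yr_sd), 0)
  ## constant 40 mm/month: seasonal 120, yearly 480, 5-year 480, sd 0
  expect_equal(unique(full$P_spr), 120)
  expect_equal(unique(full$P_1yr), 480)
  expect_equal(unique(full$P_5yr), 480)
  expect_equal(unique(full$P_5yr_sd), 0)
})

test_that("ten-year mean and sample SD match the arithmetic oracle", {
  s <- stepwise_series(2001:2010, tmeans = 4:13)
  cv <- derive_climate_covariates(s, bird_years = 2010)
  expect_equal(cv$T_1yr, 13)
  expect_equal(cv$T_10yr, 8.5)
  expect_equal(cv$T_10yr_sd, sd(4:13))
  expect_equal(cv$T_10yr_sd, 3.02765, tolerance = 1e-5)
  expect_equal(cv$T_5yr, mean(9:13))
})

test_that("covariates are invariant to row order of the series", {
  s <- stepwise_series(2001:2012, tmeans = sin(1:12) * 5 + 5,
                       prcps = 30 + (1:12))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(derive_climate_covariates(s), derive_climate_covariates(shuffled))
})

test_that("seasonal windows straddle calendar years as bird-years require", {
  ## bird-year 2001: summer = Jun-Aug 2000, spring = Mar-May 2001
  s <- stepwise_series(2001, tmeans = 0)
  s$tmean[s$year == 2000 & s$month %in% 6:8] <- 20
  s$tmean[s$year == 2001 & s$month %in% 3:5] <- 8
  cv <- derive_climate_covariates(s)
  expect_equal(cv$T_sum, 20)
  expect_equal(cv$T_spr, 8)
  expect_equal(cv$T_1yr, (20 * 3 + 8 * 3) / 12)
})

test_that("a missing interior month fails naming point, year and month", {
  s <- stepwise_series(2001:2003, tmeans = c(1, 2, 3))
  s <- s[!(s$year == 2001 & s$month == 7), ]
  expect_error(derive_climate_covariates(s), "point 1, year 2001, month 7")
})

test_that("windows reaching before the series start are flagged, not errors", {
  s <- stepwise_series(2001:2006, tmeans = 1:6)
  cv <- derive_climate_covariates(s)
  expect_true(all(!cv$complete_10yr))
  expect_equal(cv$complete_5yr, cv$bird_year >= 2005)
  expect_true(all(is.na(cv$T_10yr)))
  expect_error(derive_climate_covariates(s, bird_years = 1999), "incomplete")
})
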