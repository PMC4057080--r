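#' Parameters for a synthetic regional climate scenario
#'
#' Monthly temperature and precipitation series on a small grid of climate
#' points, organized by bird-year (the 12 months June--May preceding a June
#' survey). Interannual variability enters as one regional anomaly per
#' bird-year: additive for temperature, multiplicative (mean-one lognormal)
#' for precipitation. A multi-year drought block scales precipitation down.
#' The future period replays the same anomaly draws with an additive
#' temperature offset and a multiplicative precipitation factor.
#'
#' Defaults emulate the northern prairies: monthly normals averaging 5.9
#' degC and totalling 548 mm per year, a 1987--1992 drought, and future
#' offsets of +2.9 degC and +3.9% precipitation (a statistically-downscaled
#' GCM-like scenario; a WRF-like one would use +3.8 degC and +3.1%). The
#' north--south gradient is expressed per km of the scaled-down virtual
#' domain so that the domain spans roughly 7.7 degC, emulating the mean
#' annual temperature span of the full prairie-pothole region from its
#' cool northwestern to its warm southeastern end.
#'
#' @param n_points number of climate grid points (laid out on a near-square
#'   grid over the domain).
#' @param n_years number of simulated bird-years.
#' @param start_year first bird-year (its months run from June of
#'   `start_year - 1`).
#' @param spin_up_years extra leading bird-years generated so 10-year
#'   climate windows are complete from `start_year` onwards.
#' @param monthly_temp_normals 12 monthly mean temperatures, degC (Jan-Dec).
#' @param monthly_precip_normals 12 monthly precipitation totals, mm (Jan-Dec).
#' @param spatial_temp_gradient degC per km, applied to the latitude offset
#'   from the domain centre (negative = cooler northward).
#' @param annual_temp_anomaly_sd SD of the per-bird-year temperature anomaly, degC.
#' @param annual_precip_anomaly_sd SD (log scale) of the per-bird-year
#'   multiplicative precipitation anomaly, as a fraction.
#' @param drought_years bird-years forming the drought block.
#' @param drought_precip_multiplier precipitation multiplier in drought years (> 0).
#' @param future_temp_offset additive degC offset for the future period.
#' @param future_precip_multiplier precipitation multiplier for the future period (> 0).
#' @param future_year_shift years added to bird-year labels in the future
#'   period (the draws are paired with the historic ones).
#' @param extent_km domain edge length in km (for point layout).
#' @param seed integer seed for the climate substream.
#' @return an object of class `climate_scenario_params`.
#' @export
climate_scenario_params <- function(n_points = 25,
                                    n_years = 41,
                                    start_year = 1971,
                                    spin_up_years = 10,
                                    monthly_temp_normals = c(-12, -9, -2, 6, 13, 19,
                                                             22, 21, 15, 8, -2, -9),
                                    monthly_precip_normals = c(16, 14, 26, 42, 72, 96,
                                                               82, 64, 50, 40, 28, 18),
                                    spatial_temp_gradient = -0.3,
                                    annual_temp_anomaly_sd = 0.8,
                                    annual_precip_anomaly_sd = 0.15,
                                    drought_years = 1987:1992,
                                    drought_precip_multiplier = 0.75,
                                    future_temp_offset = 2.9,
                                    future_precip_multiplier = 1.039,
                                    future_year_shift = 59,
                                    extent_km = 25.6,
                                    seed = 1L) {
  stopifnot(n_points >= 1, n_years >= 1, spin_up_years >= 0,
            length(monthly_temp_normals) == 12L,
            length(monthly_precip_normals) == 12L,
            all(monthly_precip_normals >= 0),
            annual_temp_anomaly_sd >= 0, annual_precip_anomaly_sd >= 0)
  if (drought_precip_multiplier <= 0 || future_precip_multiplier <= 0)
    stop_("precipitation multipliers must be > 0")
  years <- start_year + seq_len(n_years) - 1L
  if (length(drought_years) && !all(drought_years %in% years))
    stop_("drought_years %s outside the simulated bird-years %d..%d",
          toString(setdiff(drought_years, years)), min(years), max(years))
  structure(list(n_points = as.integer(n_points),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 spin_up_years = as.integer(spin_up_years),
                 monthly_temp_normals = monthly_temp_normals,
                 monthly_precip_normals = monthly_precip_normals,
                 spatial_temp_gradient = spatial_temp_gradient,
                 annual_temp_anomaly_sd = annual_temp_anomaly_sd,
                 annual_precip_anomaly_sd = annual_precip_anomaly_sd,
                 drought_years = as.integer(drought_years),
                 drought_precip_multiplier = drought_precip_multiplier,
                 future_temp_offset = future_temp_offset,
                 future_precip_multiplier = future_precip_multiplier,
                 future_year_shift = as.integer(future_year_shift),
                 extent_km = extent_km,
                 seed = as.integer(seed)),
            class = "climate_scenario_params")
}

#' Climate grid point layout
#'
#' @param params a [climate_scenario_params()] object.
#' @return data.frame with `point_id`, `lon_km`, `lat_km` (domain coordinates).
#' @export
climate_points <- function(params) {
  n <- params$n_points
  side <- ceiling(sqrt(n))
  coord <- (seq_len(side) - 0.5) / side * params$extent_km
  grid <- expand.grid(lon_km = coord, lat_km = coord)
  grid <- grid[seq_len(n), , drop = FALSE]
  data.frame(point_id = seq_len(n), lon_km = grid$lon_km, lat_km = grid$lat_km)
}

#' Generate a monthly climate series
#'
#' For each point and bird-year, monthly temperature = monthly normal +
#' latitudinal gradient + the year's regional anomaly; monthly
#' precipitation = monthly normal x the year's mean-one lognormal anomaly,
#' x the drought multiplier in drought bird-years. The `"future"` period
#' replays the identical anomaly draws (so each future month is exactly
#' `future_temp_offset` warmer than its paired historic month), applies the
#' future precipitation multiplier, omits the historic drought block, and
#' relabels bird-years by `future_year_shift`. Negative precipitation
#' cannot arise from the lognormal anomaly but is clamped to zero (with a
#' message) as a formal guarantee. Deterministic given `params$seed`.
#'
#' @param params a [climate_scenario_params()] object.
#' @param period `"historic"` or `"future"`.
#' @return an object of class `pp_climate`: data.frame with columns
#'   `point_id`, `lat_km`, `lon_km`, `year`, `month`, `tmean`, `prcp`, plus
#'   attributes `points`, `period`, `bird_years` and `params`. Calendar
#'   `year`/`month` cover June of the first bird-year minus one through May
#'   of the last bird-year.
#' @export
generate_climate_series <- function(params, period = c("historic", "future")) {
  stopifnot(inherits(params, "climate_scenario_params"))
  period <- match.arg(period)
  pts <- climate_points(params)
  years <- (params$start_year - params$spin_up_years) +
    seq_len(params$n_years + params$spin_up_years) - 1L

  set.seed(params$seed)
  t_anom <- stats::rnorm(length(years), 0, params$annual_temp_anomaly_sd)
  sdl <- params$annual_precip_anomaly_sd
  p_anom <- exp(stats::rnorm(length(years), -sdl^2 / 2, sdl))

  p_mult <- p_anom
  if (period == "historic") {
    p_mult <- p_mult * ifelse(years %in% params$drought_years,
                              params$drought_precip_multiplier, 1)
  } else {
    p_mult <- p_mult * params$future_precip_multiplier
  }
  t_off <- if (period == "future") params$future_temp_offset else 0
  year_shift <- if (period == "future") params$future_year_shift else 0L

  ## bird-year y = months Jun (y-1) .. May y
  months <- c(6:12, 1:5)
  cal_shift <- c(rep(-1L, 7), rep(0L, 5))
  ny <- length(years)
  np <- nrow(pts)

  by <- rep(rep(years, each = 12L), times = np)
  mo <- rep(rep(months, times = ny), times = np)
  cy <- rep(rep(years, each = 12L) + rep(cal_shift, times = ny), times = np)
  pid <- rep(pts$point_id, each = 12L * ny)
  lat <- rep(pts$lat_km, each = 12L * ny)
  lon <- rep(pts$lon_km, each = 12L * ny)
  yi <- match(by, years)

  grad <- params$spatial_temp_gradient * (lat - mean(pts$lat_km))
  tmean <- params$monthly_temp_normals[mo] + grad + t_anom[yi] + t_off
  prcp <- params$monthly_precip_normals[mo] * p_mult[yi]
  if (any(prcp < 0)) {
    message(sprintf("clamped %d negative precipitation values to 0",
                    sum(prcp < 0)))
    prcp[prcp < 0] <- 0
  }

  out <- data.frame(point_id = pid, lat_km = lat, lon_km = lon,
                    year = cy + year_shift, month = mo,
                    tmean = tmean, prcp = prcp)
  structure(out,
            points = pts,
            period = period,
            bird_years = years + year_shift,
            first_complete_bird_year = params$start_year + year_shift,
            params = params,
            class = c("pp_climate", "data.frame"))
}
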