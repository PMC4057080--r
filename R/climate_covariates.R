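#' Derive bird-year climate covariates from a monthly series
#'
#' Computes the 18 temperature and precipitation covariates per climate
#' point and bird-year. A bird-year `y` spans June of `y - 1` through May
#' of `y`, aligning climate aggregation with June bird surveys. Seasons are
#' summer (Jun--Aug of `y - 1`), fall (Sep--Nov of `y - 1`), winter (Dec
#' `y - 1` -- Feb `y`) and spring (Mar--May of `y`). Seasonal temperature
#' is the mean of the three monthly means, seasonal precipitation the sum
#' of the three monthly totals. `T_1yr`/`P_1yr` aggregate the full 12
#' months. `*_5yr`/`*_10yr` are means of the 5/10 annual (bird-year)
#' values ending at `y`, and `*_5yr_sd`/`*_10yr_sd` their sample (n-1)
#' standard deviations.
#'
#' Windows that extend before the start of the series are flagged
#' incomplete (`complete_1yr`/`complete_5yr`/`complete_10yr` FALSE, values
#' `NA`) rather than an error; a month missing *inside* the span the series
#' covers is an error naming the point, year and month.
#'
#' @param series monthly climate: a [generate_climate_series()] result or
#'   any data.frame with columns `point_id`, `year`, `month`, `tmean`,
#'   `prcp` (months 1--12, `prcp >= 0`).
#' @param bird_years optional integer vector restricting the output; every
#'   requested bird-year must then have a complete 1-year window.
#' @return data.frame with `point_id`, `bird_year`, the 18 covariate
#'   columns ([TEMP_VARS], [PRECIP_VARS]) and three completeness flags.
#' @export
derive_climate_covariates <- function(series, bird_years = NULL) {
  req <- c("point_id", "year", "month", "tmean", "prcp")
  miss <- setdiff(req, names(series))
  if (length(miss)) stop_("series lacks column(s): %s", toString(miss))
  if (any(series$prcp < 0)) stop_("negative precipitation in series")

  s <- as.data.frame(series)[req]
  s$bird_year <- s$year + as.integer(s$month >= 6L)
  ## month index within the bird-year block: Jun=1 .. May=12
  s$mix <- ifelse(s$month >= 6L, s$month - 5L, s$month + 7L)
  ## global calendar span covered by the series (for the missing-month rule)
  cal <- s$year * 12L + s$month
  span <- range(cal)

  out <- do.call(rbind, lapply(split(s, s$point_id), function(sp) {
    pid <- sp$point_id[1]
    tab <- table(sp$bird_year)
    if (any(tab > 12L))
      stop_("duplicated months for point %s, bird-year %s",
            pid, toString(names(tab)[tab > 12L]))
    yrs <- sort(as.integer(names(tab)))
    ## complete bird-years have all 12 months; an incomplete one whose
    ## window lies inside the covered span means a month is missing
    for (y in yrs[tab[as.character(yrs)] < 12L]) {
      want_cal <- (y - 1L) * 12L + c(6:12) ; want_cal <- c(want_cal, y * 12L + 1:5)
      have <- sp$year[sp$bird_year == y] * 12L + sp$month[sp$bird_year == y]
      missing <- setdiff(want_cal, have)
      inside <- missing[missing >= span[1] & missing <= span[2]]
      if (length(inside)) {
        yy <- (inside[1] - 1L) %/% 12L
        mm <- inside[1] - yy * 12L
        stop_("missing month in climate series: point %s, year %d, month %d",
              pid, yy, mm)
      }
    }
    full <- yrs[tab[as.character(yrs)] == 12L]
    if (!length(full)) return(NULL)
    ## 12 x n_years matrices of monthly values, bird-year month order
    spf <- sp[sp$bird_year %in% full, ]
    o <- order(spf$bird_year, spf$mix)
    tm <- matrix(spf$tmean[o], nrow = 12L)
    pr <- matrix(spf$prcp[o], nrow = 12L)
    seas_rows <- list(sum = 1:3, fall = 4:6, wint = 7:9, spr = 10:12)
    res <- data.frame(point_id = pid, bird_year = full)
    for (ssn in names(seas_rows)) {
      res[[paste0("T_", ssn)]] <- colMeans(tm[seas_rows[[ssn]], , drop = FALSE])
      res[[paste0("P_", ssn)]] <- colSums(pr[seas_rows[[ssn]], , drop = FALSE])
    }
    res$T_1yr <- colMeans(tm)
    res$P_1yr <- colSums(pr)
    ## multi-year aggregates over consecutive complete bird-years
    roll <- function(v, w, f) {
      vapply(seq_along(full), function(i) {
        prev <- full[i] - (w - 1L)
        idx <- match(prev:full[i], full)
        if (anyNA(idx)) NA_real_ else f(v[idx])
      }, numeric(1))
    }
    sdv <- function(x) stats::sd(x)
    res$T_5yr <- roll(res$T_1yr, 5L, mean); res$P_5yr <- roll(res$P_1yr, 5L, mean)
    res$T_10yr <- roll(res$T_1yr, 10L, mean); res$P_10yr <- roll(res$P_1yr, 10L, mean)
    res$T_5yr_sd <- roll(res$T_1yr, 5L, sdv); res$P_5yr_sd <- roll(res$P_1yr, 5L, sdv)
    res$T_10yr_sd <- roll(res$T_1yr, 10L, sdv); res$P_10yr_sd <- roll(res$P_1yr, 10L, sdv)
    res$complete_1yr <- TRUE
    res$complete_5yr <- !is.na(res$T_5yr)
    res$complete_10yr <- !is.na(res$T_10yr)
    res
  }))
  rownames(out) <- NULL
  out <- out[c("point_id", "bird_year", TEMP_VARS, PRECIP_VARS,
               "complete_1yr", "complete_5yr", "complete_10yr")]

  if (!is.null(bird_years)) {
    have <- split(out$bird_year, out$point_id)
    for (pid in names(have)) {
      absent <- setdiff(bird_years, have[[pid]])
      if (length(absent))
        stop_("bird-year %s incomplete for point %s (series starts too late)",
              toString(absent), pid)
    }
    out <- out[out$bird_year %in% bird_years, ]
    rownames(out) <- NULL
  }
  out
}
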