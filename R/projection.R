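#' Build a grid covariate stack for projection
#'
#' Lays a regular prediction grid over the landscape, computes static
#' land-cover composition in a point buffer of the chosen scale around
#' each grid cell centre, and attaches the climate covariates of the
#' nearest climate point for every bird-year of the period. Land cover is
#' static across years.
#'
#' @param landscape a `pp_landscape`.
#' @param climate_covariates [derive_climate_covariates()] output for the
#'   period's series.
#' @param points climate point layout ([climate_points()] or the `points`
#'   attribute of a series).
#' @param scale_radius composition radius (m), the species' chosen scale.
#' @param period_years contiguous bird-years of the period.
#' @param period label, e.g. `"baseline"` or `"future"`.
#' @param grid_dim grid cells per side (default 20 x 20).
#' @return object of class `pp_stack`: `cells` (cell_id, x, y),
#'   `features` (one row per cell x year), `period`, `period_years`,
#'   `grid_dim`, `scale_radius`.
#' @export
build_grid_stack <- function(landscape, climate_covariates, points,
                             scale_radius, period_years,
                             period = "baseline", grid_dim = c(20, 20)) {
  if (length(grid_dim) == 1L) grid_dim <- rep(grid_dim, 2L)
  period_years <- sort(unique(as.integer(period_years)))
  if (length(period_years) > 1 && any(diff(period_years) != 1L))
    stop_("period years must be contiguous; got %s", toString(period_years))
  gx <- (seq_len(grid_dim[1]) - 0.5) / grid_dim[1] * landscape$extent_m
  gy <- (seq_len(grid_dim[2]) - 0.5) / grid_dim[2] * landscape$extent_m
  cells <- expand.grid(x = gx, y = gy)
  cells <- data.frame(cell_id = seq_len(nrow(cells)), cells)

  geoms <- lapply(seq_len(nrow(cells)),
                  function(i) matrix(c(cells$x[i], cells$y[i]), nrow = 1L))
  names(geoms) <- as.character(cells$cell_id)
  comp <- composition_table(landscape, geoms, radii = scale_radius)
  cpt <- nearest_climate_point(geoms, points)

  cc <- climate_covariates[climate_covariates$bird_year %in% period_years, ]
  if ("complete_10yr" %in% names(cc) && any(!cc$complete_10yr))
    stop_("incomplete climate windows inside the period: bird-year(s) %s",
          toString(unique(cc$bird_year[!cc$complete_10yr])))
  have <- unique(cc$bird_year)
  if (!setequal(have, period_years))
    stop_("climate covariates missing for bird-year(s): %s",
          toString(setdiff(period_years, have)))

  feats <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cid <- cells$cell_id[i]
    cv <- cc[cc$point_id == cpt$point_id[cpt$unit_id == as.character(cid)], ]
    cv <- cv[order(cv$bird_year), ]
    cbind(data.frame(cell_id = cid, year = cv$bird_year),
          comp[rep(which(comp$unit_id == as.character(cid)), nrow(cv)),
               LAND_VARS, drop = FALSE],
          cv[, CLIMATE_VARS, drop = FALSE],
          row.names = NULL)
  }))

  structure(list(cells = cells, features = feats, period = period,
                 period_years = period_years, grid_dim = grid_dim,
                 scale_radius = scale_radius,
                 extent_m = landscape$extent_m),
            class = "pp_stack")
}

#' Period-mean predicted occurrence probability per grid cell
#'
#' Predicts every (cell, year) row of the stack and averages across the
#' period's years, cell by cell: the "probability of occurrence over the
#' time period" is the mean of annual predicted probabilities.
#'
#' @param model a `pp_sdm` (or any object with a `predict` method
#'   returning probabilities, e.g. a truth function wrapper).
#' @param stack a `pp_stack`.
#' @return data.frame `cell_id`, `x`, `y`, `mean_prob`.
#' @export
predict_period_mean <- function(model, stack) {
  stopifnot(inherits(stack, "pp_stack"))
  if (inherits(model, "pp_sdm")) {
    miss <- setdiff(model$predictors, names(stack$features))
    if (length(miss))
      stop_("stack lacks model predictor(s): %s", toString(miss))
  }
  p <- predict(model, stack$features)
  m <- tapply(p, stack$features$cell_id, mean)
  out <- stack$cells
  out$mean_prob <- as.vector(m[as.character(out$cell_id)])
  out
}

#' Mean occurrence rate over the grid
#'
#' The mean of per-cell period-mean probabilities: the spatially averaged
#' predicted occurrence rate of the period.
#'
#' @param model,stack as in [predict_period_mean()]; alternatively pass
#'   the result of [predict_period_mean()] as `model` with `stack = NULL`.
#' @return scalar mean probability.
#' @export
mean_occurrence_rate <- function(model, stack = NULL) {
  pm <- if (is.null(stack)) model else predict_period_mean(model, stack)
  mean(pm$mean_prob)
}

SUITABILITY_EDGES <- c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875)

#' Classify period-mean probabilities into a suitability map
#'
#' A cell is suitable when its period-mean probability strictly exceeds
#' 0.5. Seven breakpoints (0.125 ... 0.875) define eight ordinal bins
#' showing the degree to which a cell is predicted suitable or
#' unsuitable; a probability exactly on an edge joins the lower bin.
#'
#' @param mean_prob data.frame from [predict_period_mean()] (or a numeric
#'   vector of probabilities).
#' @param period label stored with the map.
#' @return object of class `pp_suitability`: data.frame `cell_id`, `x`,
#'   `y`, `prob`, `suitable`, `bin` (1--8), with attributes `period` and
#'   `edges`.
#' @export
classify_suitability <- function(mean_prob, period = "baseline") {
  if (is.numeric(mean_prob))
    mean_prob <- data.frame(cell_id = seq_along(mean_prob),
                            x = NA_real_, y = NA_real_,
                            mean_prob = mean_prob)
  p <- mean_prob$mean_prob
  if (any(p < 0 | p > 1)) stop_("probabilities outside [0, 1]")
  bin <- vapply(p, function(v) sum(v > SUITABILITY_EDGES), integer(1)) + 1L
  out <- data.frame(cell_id = mean_prob$cell_id, x = mean_prob$x,
                    y = mean_prob$y, prob = p,
                    suitable = p > 0.5, bin = bin)
  structure(out, period = period, edges = SUITABILITY_EDGES,
            class = c("pp_suitability", "data.frame"))
}

#' Range change between two suitability maps
#'
#' Net percent change in the number of suitable cells from baseline to
#' future, rounded half away from zero for reporting, with the gross
#' lost / gained / retained cell decomposition.
#'
#' @param baseline,future `pp_suitability` maps over the same cell set.
#' @param species optional label.
#' @param scenario optional scenario label.
#' @return object of class `change_summary`: list with cell counts,
#'   `percent_change` (integer), `percent_change_raw`, `lost`, `gained`,
#'   `retained`.
#' @export
percent_change <- function(baseline, future, species = NULL, scenario = NULL) {
  if (!identical(sort(baseline$cell_id), sort(future$cell_id)))
    stop_("baseline and future maps cover different cell sets")
  fb <- baseline$suitable[order(baseline$cell_id)]
  ff <- future$suitable[order(future$cell_id)]
  nb <- sum(fb); nf <- sum(ff)
  if (nb == 0)
    stop_("baseline has no suitable cells: percent change undefined")
  raw <- 100 * (nf - nb) / nb
  structure(list(species = species, scenario = scenario,
                 baseline_suitable = nb, future_suitable = nf,
                 percent_change = round_half_away(raw),
                 percent_change_raw = raw,
                 lost = sum(fb & !ff), gained = sum(!fb & ff),
                 retained = sum(fb & ff)),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("change%s%s: %d -> %d suitable cells (%+d%%), lost %d, gained %d, retained %d\n",
              if (!is.null(x$species)) paste0(" [", x$species, "]") else "",
              if (!is.null(x$scenario)) paste0(" ", x$scenario) else "",
              x$baseline_suitable, x$future_suitable, x$percent_change,
              x$lost, x$gained, x$retained))
  invisible(x)
}
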