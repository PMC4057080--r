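#' Roadside survey design
#'
#' Fixed BBS-like geometry: a route segment is a straight polyline of 10
#' stops spaced 0.8 km apart (7.2 km end to end). Each route contributes
#' its first and/or third 10-stop segment; at desk scale the two segments
#' are placed independently and the first/third distinction is a label
#' feeding the per-species segment-choice rule.
#'
#' @param n_routes number of routes.
#' @param segments which segments exist per route, subset of
#'   `c("first", "third")`.
#' @param surveyed_years either an integer vector (every route surveyed in
#'   those years) or a list of length `n_routes` of per-route year sets.
#' @return an object of class `survey_design` with fixed
#'   `stops_per_segment = 10` and `stop_spacing = 800`.
#' @export
survey_design <- function(n_routes = 25,
                          segments = c("first", "third"),
                          surveyed_years = 1971:2011) {
  stopifnot(n_routes >= 1, all(segments %in% c("first", "third")),
            length(segments) >= 1)
  if (is.list(surveyed_years)) {
    if (length(surveyed_years) != n_routes)
      stop_("surveyed_years list must have one entry per route")
  } else {
    surveyed_years <- rep(list(as.integer(surveyed_years)), n_routes)
  }
  structure(list(n_routes = as.integer(n_routes),
                 stops_per_segment = 10L,
                 stop_spacing = 800,
                 segments = unique(segments),
                 surveyed_years = surveyed_years),
            class = "survey_design")
}

#' Place route-segment geometries on a landscape
#'
#' Each segment is a straight 10-stop polyline with uniform random origin
#' and orientation, re-drawn (up to 200 tries) until all stops fall inside
#' the raster extent. Deterministic given `seed`.
#'
#' @param design a [survey_design()].
#' @param landscape a `pp_landscape`.
#' @param seed integer seed for the route substream.
#' @return data.frame with `route_id`, `segment_id`, `segment` label,
#'   `stop`, `x`, `y` (metres).
#' @export
generate_routes <- function(design, landscape, seed = 1L) {
  stopifnot(inherits(design, "survey_design"))
  len <- (design$stops_per_segment - 1L) * design$stop_spacing
  if (len >= landscape$extent_m)
    stop_("segment length %g m does not fit in the %g m landscape extent",
          len, landscape$extent_m)
  set.seed(seed)
  rows <- list()
  for (r in seq_len(design$n_routes)) {
    for (seg in design$segments) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        x0 <- stats::runif(1, 0, landscape$extent_m)
        y0 <- stats::runif(1, 0, landscape$extent_m)
        ang <- stats::runif(1, 0, 2 * pi)
        sx <- x0 + cos(ang) * design$stop_spacing * (seq_len(design$stops_per_segment) - 1L)
        sy <- y0 + sin(ang) * design$stop_spacing * (seq_len(design$stops_per_segment) - 1L)
        if (all(sx >= 0 & sx <= landscape$extent_m &
                sy >= 0 & sy <= landscape$extent_m)) { ok <- TRUE; break }
      }
      if (!ok) stop_("could not place route %d segment %s inside the extent", r, seg)
      rows[[length(rows) + 1L]] <- data.frame(
        route_id = r, segment_id = sprintf("r%02d_%s", r, seg), segment = seg,
        stop = seq_len(design$stops_per_segment), x = sx, y = sy)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

segment_geometries <- function(routes) {
  split_ids <- unique(routes$segment_id)
  g <- lapply(split_ids, function(id) {
    sub <- routes[routes$segment_id == id, ]
    as.matrix(sub[order(sub$stop), c("x", "y")])
  })
  names(g) <- split_ids
  g
}

#' Simulate roadside-survey occurrence records
#'
#' Draws one Bernoulli presence per (species, segment, surveyed bird-year)
#' at the species' true occurrence probability, using land-cover
#' composition at the species' `response_scale` around the segment and the
#' climate covariates of the nearest climate point. Detection is perfect
#' at segment level: the observation model is a single Bernoulli draw.
#' Uncalibrated species are calibrated against the assembled segment-year
#' covariate table (the calibrated species are returned). Deterministic
#' given `seed`.
#'
#' @param landscape a `pp_landscape`.
#' @param climate a `pp_climate` (historic period) or its covariates from
#'   [derive_climate_covariates()].
#' @param species a `virtual_species` or list of them.
#' @param design a [survey_design()].
#' @param seed integer seed for the survey substream.
#' @param routes optional precomputed [generate_routes()] table; generated
#'   from `seed` when missing.
#' @return list of class `pp_survey`: `occurrences` (data.frame `species`,
#'   `route_id`, `segment_id`, `year`, `present`), `true_prob` (same rows),
#'   `covariates` (segment-year feature rows at each species scale),
#'   `routes`, `segment_points`, `species` (calibrated list).
#' @export
simulate_surveys <- function(landscape, climate, species, design, seed = 1L,
                             routes = NULL) {
  if (inherits(species, "virtual_species")) species <- list(species)
  stopifnot(length(species) >= 1)
  names(species) <- vapply(species, `[[`, "", "name")

  if (is.null(routes)) routes <- generate_routes(design, landscape, seed = seed)
  if (any(routes$x < 0 | routes$x > landscape$extent_m |
          routes$y < 0 | routes$y > landscape$extent_m)) {
    bad <- unique(routes$route_id[routes$x < 0 | routes$x > landscape$extent_m |
                                  routes$y < 0 | routes$y > landscape$extent_m])
    stop_("route(s) %s fall outside the raster extent", toString(bad))
  }
  geoms <- segment_geometries(routes)

  clim_cov <- if (is.data.frame(climate) && "tmean" %in% names(climate))
    derive_climate_covariates(climate) else climate
  pts <- attr(climate, "points")
  if (is.null(pts)) {
    pts <- unique(data.frame(point_id = climate$point_id,
                             lon_km = climate$lon_km, lat_km = climate$lat_km))
  }

  seg_pts <- nearest_climate_point(geoms, pts)

  scales <- sort(unique(vapply(species, `[[`, numeric(1), "response_scale")))
  comp <- composition_table(landscape, geoms, radii = scales)

  ## feature rows per (segment, bird-year, scale)
  seg_route <- routes$route_id[match(names(geoms), routes$segment_id)]
  occ <- list(); probs <- list()
  features_by_scale <- lapply(scales, function(sc) {
    cmp <- comp[comp$scale_radius == sc, ]
    rows <- do.call(rbind, lapply(seq_along(geoms), function(i) {
      sid <- names(geoms)[i]
      yrs <- design$surveyed_years[[seg_route[i]]]
      cv <- clim_cov[clim_cov$point_id == seg_pts$point_id[seg_pts$unit_id == sid] &
                     clim_cov$bird_year %in% yrs, ]
      if ("complete_10yr" %in% names(cv)) cv <- cv[cv$complete_10yr, ]
      if (!nrow(cv)) return(NULL)
      cbind(data.frame(route_id = seg_route[i], segment_id = sid,
                       year = cv$bird_year),
            cmp[rep(which(cmp$unit_id == sid), nrow(cv)),
                LAND_VARS, drop = FALSE],
            cv[, CLIMATE_VARS, drop = FALSE],
            row.names = NULL)
    }))
    rows
  })
  names(features_by_scale) <- as.character(scales)

  set.seed(seed + 1L)
  for (sp in names(species)) {
    feats <- features_by_scale[[as.character(species[[sp]]$response_scale)]]
    if (is.null(species[[sp]]$standardization) &&
        length(species[[sp]]$coefficients))
      species[[sp]] <- calibrate_species(species[[sp]], feats)
    p <- true_occurrence_probability(species[[sp]], feats)
    present <- as.integer(stats::runif(nrow(feats)) < p)
    occ[[sp]] <- data.frame(species = sp, feats[c("route_id", "segment_id", "year")],
                            present = present)
    probs[[sp]] <- data.frame(species = sp, feats[c("route_id", "segment_id", "year")],
                              true_prob = p)
  }

  structure(list(occurrences = do.call(rbind, c(occ, make.row.names = FALSE)),
                 true_prob = do.call(rbind, c(probs, make.row.names = FALSE)),
                 covariates = features_by_scale,
                 routes = routes, segment_points = seg_pts,
                 species = species),
            class = "pp_survey")
}
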