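#' Nearest climate grid point to a segment
#'
#' Matches each segment to the climate point minimizing Euclidean distance
#' to the segment midpoint (mean of its stop coordinates); ties break to
#' the lowest `point_id`.
#'
#' @param geometry a vertex matrix (metres), or a named list of them.
#' @param points data.frame with `point_id`, `lon_km`, `lat_km` (domain km).
#' @return for a single geometry, the `point_id`; for a list, a data.frame
#'   `unit_id`, `point_id`.
#' @export
nearest_climate_point <- function(geometry, points) {
  stopifnot(nrow(points) >= 1)
  one <- function(g) {
    if (is.numeric(g) && is.null(dim(g))) g <- matrix(g, nrow = 1L)
    mid <- colMeans(g) / 1000  # metres -> km
    d <- sqrt((points$lon_km - mid[1])^2 + (points$lat_km - mid[2])^2)
    cand <- which(d == min(d))
    points$point_id[cand[which.min(points$point_id[cand])]]
  }
  if (is.list(geometry) && !is.data.frame(geometry)) {
    data.frame(unit_id = names(geometry),
               point_id = vapply(geometry, one, numeric(1)),
               row.names = NULL)
  } else one(geometry)
}

#' Assemble the training feature table
#'
#' Joins occurrence records to their segment's land-cover composition (one
#' scale) and to the climate covariates of the segment's nearest climate
#' point for the record's bird-year, yielding one row per (segment, year)
#' with the 31 predictors and the binary response. Land cover is static:
#' the same composition row is repeated across years.
#'
#' @param occurrences data.frame `species`, `route_id`, `segment_id`,
#'   `year`, `present` (single species, or pass one species' subset).
#' @param composition [composition_table()] rows at one `scale_radius`.
#' @param climate_covariates [derive_climate_covariates()] output.
#' @param segment_points data.frame `unit_id`, `point_id` mapping segments
#'   to climate points (see [nearest_climate_point()]).
#' @return data.frame: keys (`species`, `route_id`, `segment_id`, `year`),
#'   `present`, then the 31 predictor columns.
#' @export
build_feature_table <- function(occurrences, composition, climate_covariates,
                                segment_points) {
  if (length(unique(composition$scale_radius)) != 1L)
    stop_("composition must be at a single scale; got %s",
          toString(unique(composition$scale_radius)))
  if (length(unique(occurrences$species)) > 1L)
    stop_("one species at a time; got %s",
          toString(unique(occurrences$species)))

  ci <- match(occurrences$segment_id, composition$unit_id)
  if (anyNA(ci))
    stop_("no composition row for segment(s): %s",
          toString(unique(occurrences$segment_id[is.na(ci)])))
  pi_ <- match(occurrences$segment_id, segment_points$unit_id)
  if (anyNA(pi_))
    stop_("no climate-point assignment for segment(s): %s",
          toString(unique(occurrences$segment_id[is.na(pi_)])))
  key <- paste(segment_points$point_id[pi_], occurrences$year)
  ki <- match(key, paste(climate_covariates$point_id,
                         climate_covariates$bird_year))
  if (anyNA(ki))
    stop_("no climate covariates for (point, bird-year): %s",
          toString(unique(key[is.na(ki)])))
  cc <- climate_covariates[ki, , drop = FALSE]
  if ("complete_10yr" %in% names(cc) && any(!cc$complete_10yr)) {
    bad <- unique(paste0(occurrences$segment_id, ":", occurrences$year)[!cc$complete_10yr])
    stop_("incomplete 10-year climate window for record(s): %s", toString(bad))
  }

  out <- cbind(occurrences[c("species", "route_id", "segment_id", "year", "present")],
               composition[ci, LAND_VARS, drop = FALSE],
               cc[, CLIMATE_VARS, drop = FALSE])
  rownames(out) <- NULL
  out
}
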