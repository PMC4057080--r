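## Land-cover composition in Euclidean buffers around survey geometries.
## The zonal rule is "cell centre inside the buffer": deterministic, cheap,
## and standard for coarse categorical rasters.

## minimum distance from points (px, py) to a polyline given as a matrix of
## vertices; a single-row matrix degenerates to point distance
dist_to_polyline <- function(px, py, verts) {
  stopifnot(is.matrix(verts), ncol(verts) == 2L)
  if (nrow(verts) == 1L)
    return(sqrt((px - verts[1, 1])^2 + (py - verts[1, 2])^2))
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(verts) - 1L)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- verts[i + 1L, 1]; by <- verts[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Land-cover composition around a geometry
#'
#' Proportions of the 13 land-cover classes among raster cells whose
#' centres fall within a Euclidean buffer of the geometry (a point or the
#' polyline through a segment's stops). Aggregates `pal` (temporary +
#' seasonal + semipermanent) and `total` (all wetland) are computed from
#' the parts, so the nine wetland proportions plus the four upland
#' proportions minus the two aggregates sum to one.
#'
#' @param landscape a `pp_landscape` from [generate_landscape()] (or a
#'   compatible list with `raster` and `cell_size`).
#' @param geometry numeric matrix of x/y vertices in metres (one row for a
#'   point buffer), or a length-2 vector for a point.
#' @param radius buffer radius in metres; radii outside [CANONICAL_SCALES]
#'   are allowed with a warning.
#' @param unit_id optional identifier copied into the output row.
#' @return one-row data.frame: `unit_id`, `scale_radius`, `n_cells`, and
#'   proportions `temp, seas, semi, lake, river, shrub, forest, pal, total,
#'   crop, grass, devel, tree`.
#' @export
landcover_composition <- function(landscape, geometry, radius, unit_id = NA) {
  if (is.numeric(geometry) && is.null(dim(geometry)))
    geometry <- matrix(geometry, nrow = 1L)
  stopifnot(is.matrix(geometry), ncol(geometry) == 2L, radius > 0)
  if (!radius %in% CANONICAL_SCALES)
    warn_("radius %g m is not one of the canonical scales (%s)",
          radius, toString(CANONICAL_SCALES))
  if (any(geometry[, 1] < 0 | geometry[, 1] > landscape$extent_m |
          geometry[, 2] < 0 | geometry[, 2] > landscape$extent_m))
    stop_("geometry extends outside the raster extent [0, %g] m",
          landscape$extent_m)
  cc <- landscape_cell_centers(landscape)
  d <- dist_to_polyline(cc$x, cc$y, geometry)
  inside <- d <= radius
  if (!any(inside))
    stop_("buffer of radius %g m contains no cell centres", radius)
  composition_from_codes(as.vector(landscape$raster)[inside], radius, unit_id)
}

composition_from_codes <- function(codes, radius, unit_id = NA) {
  n <- length(codes)
  counts <- tabulate(codes, nbins = max(LAND_CLASS_CODES))
  p <- counts / n
  names(p) <- names(LAND_CLASS_CODES)[order(LAND_CLASS_CODES)]
  row <- data.frame(unit_id = unit_id, scale_radius = radius, n_cells = n)
  for (v in c("temp", "seas", "semi", "lake", "river", "shrub", "forest"))
    row[[v]] <- p[[v]]
  row$pal <- p[["temp"]] + p[["seas"]] + p[["semi"]]
  row$total <- row$pal + p[["lake"]] + p[["river"]] + p[["forest"]] + p[["shrub"]]
  for (v in c("crop", "grass", "devel", "tree")) row[[v]] <- p[[v]]
  row
}

#' Composition table for many units and scales
#'
#' @param landscape a `pp_landscape`.
#' @param geometries named list of vertex matrices (names become `unit_id`).
#' @param radii buffer radii in metres.
#' @return data.frame with one row per unit x radius.
#' @export
composition_table <- function(landscape, geometries, radii = CANONICAL_SCALES) {
  stopifnot(length(geometries) >= 1, !is.null(names(geometries)))
  cc <- landscape_cell_centers(landscape)
  codes <- as.vector(landscape$raster)
  rows <- lapply(names(geometries), function(id) {
    g <- geometries[[id]]
    if (is.numeric(g) && is.null(dim(g))) g <- matrix(g, nrow = 1L)
    if (any(g[, 1] < 0 | g[, 1] > landscape$extent_m |
            g[, 2] < 0 | g[, 2] > landscape$extent_m))
      stop_("geometry '%s' extends outside the raster extent", id)
    d <- dist_to_polyline(cc$x, cc$y, g)
    do.call(rbind, lapply(radii, function(r) {
      inside <- d <= r
      if (!any(inside))
        stop_("buffer of radius %g m around '%s' contains no cell centres", r, id)
      composition_from_codes(codes[inside], r, id)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
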