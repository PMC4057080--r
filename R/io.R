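## Plain-text raster and table I/O. Rasters use the ESRI ASCII grid format
## (readable by every GIS) with a JSON sidecar carrying class codes and a
## CRS note; climate uses the long-CSV layout; occurrences a flat CSV.

write_asc <- function(mat, path, cell_size, nodata = -9999, digits = NA) {
  ## mat rows are south->north; ASCII grids store north->south
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %.15g", cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  m <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  m[is.na(m)] <- nodata
  if (!is.na(digits)) m <- signif(m, digits)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  list(mat = m[rev(seq_len(nrow(m))), , drop = FALSE],
       cell_size = h[["cellsize"]])
}

#' Write / read a landscape raster
#'
#' `<path>.asc` holds the class-code grid (ESRI ASCII grid, metres,
#' origin at the south-west corner) and `<path>.json` the code-to-class
#' mapping, cell size and a CRS note.
#'
#' @param landscape a `pp_landscape`.
#' @param path file path without extension.
#' @return `write_landscape`: the paths, invisibly. `read_landscape`: a
#'   `pp_landscape` (without the basin registry).
#' @export
write_landscape <- function(landscape, path) {
  write_asc(landscape$raster, paste0(path, ".asc"), landscape$cell_size)
  meta <- list(classes = as.list(LAND_CLASS_CODES),
               cell_size = landscape$cell_size,
               extent_m = landscape$extent_m,
               crs = "local projected coordinates, metres")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paste0(path, c(".asc", ".json")))
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  g <- read_asc(paste0(path, ".asc"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(raster = matrix(as.integer(g$mat), nrow(g$mat)),
                 cell_size = g$cell_size,
                 extent_m = nrow(g$mat) * g$cell_size,
                 basins = NULL,
                 params = NULL,
                 classes = unlist(meta$classes)),
            class = "pp_landscape")
}

#' Write / read a monthly climate series as long CSV
#'
#' Columns: `point_id`, `lat_km`, `lon_km`, `year`, `month`, `tmean`,
#' `prcp`.
#'
#' @param series a `pp_climate` (or compatible data.frame).
#' @param path CSV path.
#' @export
write_climate_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("point_id", "lat_km", "lon_km",
                                           "year", "month", "tmean", "prcp")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  s <- utils::read.csv(path)
  pts <- unique(s[c("point_id", "lon_km", "lat_km")])
  pts <- pts[order(pts$point_id), ]
  rownames(pts) <- NULL
  structure(s, points = pts, class = c("pp_climate", "data.frame"))
}

#' Write / read occurrence records
#'
#' Columns: `species`, `route_id`, `segment_id`, `year`, `present` (0/1).
#'
#' @param occurrences occurrence data.frame.
#' @param path CSV path.
#' @export
write_occurrences_csv <- function(occurrences, path) {
  utils::write.csv(occurrences[c("species", "route_id", "segment_id",
                                 "year", "present")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) utils::read.csv(path)

#' Write / read a suitability map
#'
#' Two ASCII grids — `<path>_prob.asc` (period-mean probability) and
#' `<path>_bin.asc` (ordinal bin code 1--8) — plus `<path>_meta.json`
#' (period, breakpoint edges, cell size). Bin codes round-trip exactly;
#' probabilities to the 7 significant digits written.
#'
#' @param map a `pp_suitability` over a regular grid.
#' @param path path prefix.
#' @param grid_dim grid cells per side (inferred when the map's `x`
#'   coordinates form a grid).
#' @export
write_suitability_map <- function(map, path, grid_dim = NULL) {
  if (is.null(grid_dim)) {
    grid_dim <- c(length(unique(map$x)), length(unique(map$y)))
    if (prod(grid_dim) != nrow(map))
      stop_("map is not a regular grid; pass grid_dim")
  }
  cs <- max(map$x) * 2 / (2 * grid_dim[1] - 1)  # from cell-centre layout
  pm <- matrix(map$prob[order(map$cell_id)], grid_dim[1], grid_dim[2])
  bm <- matrix(map$bin[order(map$cell_id)], grid_dim[1], grid_dim[2])
  write_asc(t(pm), paste0(path, "_prob.asc"), cs, digits = 7)
  write_asc(t(bm), paste0(path, "_bin.asc"), cs)
  jsonlite::write_json(list(period = attr(map, "period"),
                            edges = attr(map, "edges"),
                            grid_dim = grid_dim, cell_size = cs),
                       paste0(path, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, c("_prob.asc", "_bin.asc", "_meta.json")))
}

#' @rdname write_suitability_map
#' @export
read_suitability_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
  p <- read_asc(paste0(path, "_prob.asc"))
  b <- read_asc(paste0(path, "_bin.asc"))
  gd <- meta$grid_dim
  prob <- as.vector(t(p$mat)); bin <- as.integer(t(b$mat))
  cells <- expand.grid(x = (seq_len(gd[1]) - 0.5) * meta$cell_size,
                       y = (seq_len(gd[2]) - 0.5) * meta$cell_size)
  out <- data.frame(cell_id = seq_len(nrow(cells)), cells,
                    prob = prob, suitable = prob > 0.5, bin = bin)
  structure(out, period = meta$period, edges = meta$edges,
            class = c("pp_suitability", "data.frame"))
}
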