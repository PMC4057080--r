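#' Parameters for a virtual pothole landscape
#'
#' Describes a square categorical raster emulating a prairie-pothole
#' land-cover layer: wetland basins scattered as non-overlapping discs over
#' an upland matrix of patches. Defaults describe a 25.6 km x 25.6 km
#' scaled-down study region with a realistic basin density and a
#' cropland-dominated upland, standing in for the much larger real region.
#'
#' @param extent_cells width/height of the square raster in cells (>= 16).
#' @param cell_size cell edge length in metres.
#' @param basin_density wetland basins per square kilometre.
#' @param basin_radius_range numeric length-2, min/max basin radius (m).
#' @param regime_weights named probabilities over the seven wetland regimes
#'   (temp, seas, semi, lake, river, forest, shrub); must sum to 1.
#' @param upland_weights named probabilities over the four upland classes
#'   (crop, grass, devel, tree); must sum to 1.
#' @param patch_size target upland patch size in cells; patches are square
#'   blocks of side `round(sqrt(patch_size))`.
#' @param seed integer seed for the landscape substream.
#' @return an object of class `landscape_params`.
#' @export
landscape_params <- function(extent_cells = 256,
                             cell_size = 100,
                             basin_density = 2,
                             basin_radius_range = c(50, 250),
                             regime_weights = c(temp = 0.30, seas = 0.30,
                                                semi = 0.20, lake = 0.06,
                                                river = 0.04, forest = 0.05,
                                                shrub = 0.05),
                             upland_weights = c(crop = 0.55, grass = 0.35,
                                                devel = 0.05, tree = 0.05),
                             patch_size = 36,
                             seed = 1L) {
  stopifnot(extent_cells >= 16, cell_size > 0, basin_density >= 0,
            length(basin_radius_range) == 2L, patch_size >= 1)
  if (basin_radius_range[1] > basin_radius_range[2])
    stop_("basin_radius_range min (%g) exceeds max (%g)",
          basin_radius_range[1], basin_radius_range[2])
  regimes <- c("temp", "seas", "semi", "lake", "river", "forest", "shrub")
  uplands <- c("crop", "grass", "devel", "tree")
  if (!setequal(names(regime_weights), regimes))
    stop_("regime_weights must be named over: %s", toString(regimes))
  if (!setequal(names(upland_weights), uplands))
    stop_("upland_weights must be named over: %s", toString(uplands))
  if (abs(sum(regime_weights) - 1) > 1e-12)
    stop_("regime_weights sum to %.15f, not 1", sum(regime_weights))
  if (abs(sum(upland_weights) - 1) > 1e-12)
    stop_("upland_weights sum to %.15f, not 1", sum(upland_weights))
  structure(list(extent_cells = as.integer(extent_cells),
                 cell_size = cell_size,
                 basin_density = basin_density,
                 basin_radius_range = basin_radius_range,
                 regime_weights = regime_weights[regimes],
                 upland_weights = upland_weights[uplands],
                 patch_size = patch_size,
                 seed = as.integer(seed)),
            class = "landscape_params")
}

#' Generate a virtual pothole landscape
#'
#' Places `round(basin_density * area_km2)` wetland basins as
#' non-overlapping discs (rejection sampling, at most 100 retries per
#' basin), each assigned a wetland regime drawn from `regime_weights`, over
#' an upland matrix tiled with square patches whose classes are drawn from
#' `upland_weights`. Cells belong to a basin when their centre falls inside
#' the disc. Deterministic given `params$seed`.
#'
#' @param params a [landscape_params()] object.
#' @return an object of class `pp_landscape`: list with `raster` (integer
#'   matrix of [LAND_CLASS_CODES], row 1 = southern edge), `cell_size`,
#'   `extent_m`, `basins` (data.frame x, y, radius, regime) and `params`.
#' @export
generate_landscape <- function(params) {
  stopifnot(inherits(params, "landscape_params"))
  n <- params$extent_cells
  cs <- params$cell_size
  extent_m <- n * cs
  area_km2 <- (extent_m / 1000)^2
  set.seed(params$seed)

  ## upland matrix: square blocks of ~patch_size cells
  side <- max(1L, as.integer(round(sqrt(params$patch_size))))
  nb <- ceiling(n / side)
  block_class <- matrix(
    sample(LAND_CLASS_CODES[names(params$upland_weights)], nb * nb,
           replace = TRUE, prob = params$upland_weights),
    nb, nb)
  idx <- ceiling(seq_len(n) / side)
  raster <- block_class[idx, idx, drop = FALSE]

  ## wetland basins: non-overlapping discs
  n_basins <- as.integer(round(params$basin_density * area_km2))
  basins <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                       regime = character(0))
  if (n_basins > 0) {
    xs <- ys <- rs <- numeric(n_basins)
    placed <- 0L
    for (b in seq_len(n_basins)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        x <- stats::runif(1, 0, extent_m)
        y <- stats::runif(1, 0, extent_m)
        r <- stats::runif(1, params$basin_radius_range[1],
                          params$basin_radius_range[2])
        if (placed == 0L ||
            all(sqrt((xs[seq_len(placed)] - x)^2 +
                     (ys[seq_len(placed)] - y)^2) >= rs[seq_len(placed)] + r)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_(paste0("basin placement failed after 100 retries: ",
                     "basin_density %.3g per km2 is too high for this extent"),
              params$basin_density)
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y; rs[placed] <- r
    }
    regime <- sample(names(params$regime_weights), n_basins, replace = TRUE,
                     prob = params$regime_weights)
    basins <- data.frame(x = xs, y = ys, radius = rs, regime = regime,
                         stringsAsFactors = FALSE)
    ## rasterize: cell centres inside each disc
    centers <- (seq_len(n) - 0.5) * cs
    for (b in seq_len(n_basins)) {
      jr <- which(abs(centers - xs[b]) <= rs[b])   # columns = x
      ir <- which(abs(centers - ys[b]) <= rs[b])   # rows = y
      if (!length(jr) || !length(ir)) next
      dx2 <- (centers[jr] - xs[b])^2
      dy2 <- (centers[ir] - ys[b])^2
      inside <- outer(dy2, dx2, "+") <= rs[b]^2
      code <- LAND_CLASS_CODES[[regime[b]]]
      raster[ir, jr][inside] <- code
    }
  }

  structure(list(raster = raster, cell_size = cs, extent_m = extent_m,
                 basins = basins, params = params),
            class = "pp_landscape")
}

#' @export
print.pp_landscape <- function(x, ...) {
  tab <- table(factor(x$raster, levels = LAND_CLASS_CODES,
                      labels = names(LAND_CLASS_CODES)))
  cat(sprintf("pp_landscape: %d x %d cells of %g m (%.1f km2), %d basins\n",
              nrow(x$raster), ncol(x$raster), x$cell_size,
              (x$extent_m / 1000)^2, nrow(x$basins)))
  print(round(tab / length(x$raster), 3))
  invisible(x)
}

## cell-centre coordinates of a landscape raster, as vectors aligned with
## as.vector(raster) (column-major: x varies by column, y by row)
landscape_cell_centers <- function(landscape) {
  n_row <- nrow(landscape$raster)
  n_col <- ncol(landscape$raster)
  cs <- landscape$cell_size
  list(x = rep((seq_len(n_col) - 0.5) * cs, each = n_row),
       y = rep((seq_len(n_row) - 0.5) * cs, times = n_col))
}
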