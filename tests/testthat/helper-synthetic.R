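## Shared builders for synthetic fixtures. Expensive artifacts are
## memoized for the duration of a test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## a small landscape for geometry-level tests
tiny_landscape <- function(seed = 7, extent_cells = 64, cell_size = 100,
                           basin_density = 4, ...) {
  generate_landscape(landscape_params(extent_cells = extent_cells,
                                      cell_size = cell_size,
                                      basin_density = basin_density,
                                      seed = seed, ...))
}

## a uniform single-class landscape (grassland unless told otherwise)
uniform_landscape <- function(class = "grass", extent_cells = 64,
                              cell_size = 100) {
  lp <- landscape_params(extent_cells = extent_cells, cell_size = cell_size,
                         basin_density = 0,
                         upland_weights = c(crop = 0, grass = 0, devel = 0,
                                            tree = 0) +
                           stats::setNames(as.numeric(
                             names(LAND_CLASS_CODES[8:11]) == class),
                             names(LAND_CLASS_CODES[8:11])),
                         seed = 1)
  generate_landscape(lp)
}

## a monthly series with a prescribed constant value per bird-year,
## one climate point; bird-years `years` get temperature `tmeans[i]` in
## every month and precipitation `prcps[i]` in every month
stepwise_series <- function(years, tmeans, prcps = rep(40, length(years))) {
  do.call(rbind, lapply(seq_along(years), function(i) {
    y <- years[i]
    data.frame(point_id = 1,
               year = c(rep(y - 1L, 7), rep(y, 5)),
               month = c(6:12, 1:5),
               tmean = tmeans[i], prcp = prcps[i])
  }))
}

## default simulated study (moderately expensive; memoized)
shared_dataset <- function() {
  memo("shared_dataset", {
    sp <- virtual_species("demo", c(semi = 2, grass = 1.5), 0, 2000)
    simulate_dataset(species = list(demo = sp), seed = 42)
  })
}

## feature table + partitions for the shared dataset
shared_features <- function() {
  memo("shared_features", {
    ds <- shared_dataset()
    ft <- ds$survey$covariates[["2000"]]
    ft$present <- ds$survey$occurrences$present
    ft$partition <- partition_years(ft[c("route_id", "year")],
                                    drought_years = 1987:1992)$partition
    ft
  })
}

shared_model <- function() {
  memo("shared_model", {
    ft <- shared_features()
    fit_balanced_forest(ft[ft$partition == "main_train", ],
                        sdm_config(seed = 7), species = "demo")
  })
}

## gaussian class-conditional fixture: predictor 1 carries the signal
gaussian_classes <- function(n1, n0, p = 31, shift = 1.5) {
  x1 <- matrix(stats::rnorm(n1 * p), n1, p); x1[, 1] <- x1[, 1] + shift
  x0 <- matrix(stats::rnorm(n0 * p), n0, p)
  d <- as.data.frame(rbind(x1, x0))
  names(d) <- ALL_PREDICTORS[seq_len(p)]
  d$present <- c(rep(1L, n1), rep(0L, n0))
  d
}

## brute-force AUC: exhaustive pairwise concordance with half credit for ties
auc_bruteforce <- function(prob, labels) {
  pos <- prob[labels == 1]; neg <- prob[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
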