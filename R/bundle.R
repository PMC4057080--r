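#' Simulate a complete synthetic study
#'
#' One call wiring the generator together: landscape, historic (and
#' optionally future) climate, routes, and occurrence records for a pool
#' of virtual species. All randomness flows from `seed` through named
#' substreams, so any stage can be regenerated independently.
#'
#' @param landscape_params a [landscape_params()]; its `seed` is
#'   overridden by the landscape substream of `seed`.
#' @param climate_params a [climate_scenario_params()]; likewise.
#' @param design a [survey_design()].
#' @param species a `virtual_species` or list; defaults to
#'   [default_species_pool()].
#' @param seed top-level integer seed.
#' @param future also generate the future climate series and covariates.
#' @return list: `landscape`, `climate` (+ `climate_future`), derived
#'   `covariates` (+ `covariates_future`), `survey` (a `pp_survey`),
#'   `params`, `seed`.
#' @export
simulate_dataset <- function(landscape_params = prairieSDM::landscape_params(),
                             climate_params = climate_scenario_params(),
                             design = survey_design(),
                             species = default_species_pool(),
                             seed = 1L,
                             future = TRUE) {
  ss <- substream_seeds(seed)
  landscape_params$seed <- unname(ss["landscape"])
  climate_params$seed <- unname(ss["climate"])
  landscape <- generate_landscape(landscape_params)
  climate <- generate_climate_series(climate_params, "historic")
  covariates <- derive_climate_covariates(climate)
  routes <- generate_routes(design, landscape, seed = unname(ss["routes"]))
  survey <- simulate_surveys(landscape, climate, species, design,
                             seed = unname(ss["survey"]), routes = routes)
  out <- list(landscape = landscape, climate = climate,
              covariates = covariates, survey = survey,
              params = list(landscape = landscape_params,
                            climate = climate_params, design = design),
              seed = seed)
  if (future) {
    out$climate_future <- generate_climate_series(climate_params, "future")
    out$covariates_future <- derive_climate_covariates(out$climate_future)
  }
  out
}

#' Write a fixture bundle to disk
#'
#' Materializes a [simulate_dataset()] run as plain-text artifacts:
#' landscape grid + sidecar, historic and future climate CSVs, routes and
#' occurrences CSVs, and a manifest. `config` may be a YAML file path or
#' a list with any of `landscape`, `climate`, `design` entries holding
#' arguments for the respective constructors.
#'
#' @param config list or YAML path of generator arguments (optional).
#' @param out_dir output directory.
#' @param seed top-level seed.
#' @return named vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(config = NULL, out_dir, seed = 1L) {
  cfg <- list()
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_("reading YAML configs requires the yaml package")
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) cfg <- config
  lp <- do.call(landscape_params, cfg$landscape %||% list())
  cp <- do.call(climate_scenario_params, cfg$climate %||% list())
  dn <- do.call(survey_design, cfg$design %||% list())
  ds <- simulate_dataset(lp, cp, dn, seed = seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- c()
  p["landscape"] <- file.path(out_dir, "landscape.asc")
  write_landscape(ds$landscape, file.path(out_dir, "landscape"))
  p["climate"] <- write_climate_csv(ds$climate,
                                    file.path(out_dir, "climate_historic.csv"))
  p["climate_future"] <- write_climate_csv(ds$climate_future,
                                           file.path(out_dir, "climate_future.csv"))
  p["routes"] <- file.path(out_dir, "routes.csv")
  utils::write.csv(ds$survey$routes, p["routes"], row.names = FALSE)
  p["occurrences"] <- write_occurrences_csv(ds$survey$occurrences,
                                            file.path(out_dir, "occurrences.csv"))
  jsonlite::write_json(list(seed = seed,
                            landscape = unclass(lp)[setdiff(names(lp), "seed")],
                            climate = unclass(cp)[setdiff(names(cp), "seed")],
                            design = list(n_routes = dn$n_routes,
                                          segments = dn$segments)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  p["manifest"] <- file.path(out_dir, "manifest.json")
  invisible(p)
}
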