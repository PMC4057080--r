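#' Define a virtual species with a known logistic response
#'
#' A virtual species' true occurrence probability is
#' `plogis(intercept + sum(coefficients * z))` where `z` are covariates
#' standardized by constants fixed at calibration time and stored with the
#' species, so the truth function is a fully reproducible analytic oracle.
#'
#' @param name species label.
#' @param coefficients named numeric vector; names must be covariate names
#'   from [ALL_PREDICTORS].
#' @param intercept real intercept on the logit scale.
#' @param response_scale buffer radius (m) at which composition covariates
#'   enter the truth; must be one of [CANONICAL_SCALES].
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(name, coefficients = numeric(0), intercept = 0,
                            response_scale = 2000) {
  if (is.null(coefficients)) coefficients <- numeric(0)
  stopifnot(is.numeric(coefficients))
  if (length(coefficients) && is.null(names(coefficients)))
    stop_("coefficients must be named by covariate")
  bad <- setdiff(names(coefficients), ALL_PREDICTORS)
  if (length(bad)) stop_("unknown covariate name(s) in coefficients: %s",
                         toString(bad))
  if (!response_scale %in% CANONICAL_SCALES)
    stop_("response_scale %g not in the canonical radii (%s)",
          response_scale, toString(CANONICAL_SCALES))
  structure(list(name = name, coefficients = coefficients,
                 intercept = intercept, response_scale = response_scale,
                 standardization = NULL),
            class = "virtual_species")
}

#' Fix a virtual species' standardization constants
#'
#' Stores the mean and standard deviation of each covariate the species
#' responds to, taken from a reference covariate table (typically the
#' segment-year covariates of the survey design that will sample it).
#' Degenerate (constant) covariates get unit scale.
#'
#' @param species a [virtual_species()].
#' @param covariates data.frame containing every coefficient covariate.
#' @return the species with `$standardization` filled in.
#' @export
calibrate_species <- function(species, covariates) {
  stopifnot(inherits(species, "virtual_species"))
  keys <- names(species$coefficients)
  miss <- setdiff(keys, names(covariates))
  if (length(miss)) stop_("covariate table lacks: %s", toString(miss))
  center <- vapply(keys, function(k) mean(covariates[[k]]), numeric(1))
  scale <- vapply(keys, function(k) stats::sd(covariates[[k]]), numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  species$standardization <- list(center = center, scale = scale)
  species
}

#' True occurrence probability of a virtual species
#'
#' The analytic oracle: logistic response to stored-standardized
#' covariates. Vectorized over rows when `covariates` is a data.frame.
#'
#' @param species a calibrated [virtual_species()] (see
#'   [calibrate_species()]; species without coefficients need no calibration).
#' @param covariates named numeric vector, list, or data.frame holding at
#'   least every covariate the species responds to.
#' @return numeric probability (vector of one per row).
#' @export
true_occurrence_probability <- function(species, covariates) {
  stopifnot(inherits(species, "virtual_species"))
  keys <- names(species$coefficients)
  if (length(keys) == 0)
    return(rep(stats::plogis(species$intercept),
               if (is.data.frame(covariates)) nrow(covariates) else 1L))
  if (is.null(species$standardization))
    stop_("species '%s' is not calibrated; call calibrate_species() first",
          species$name)
  if (!is.data.frame(covariates))
    covariates <- as.data.frame(as.list(covariates))
  miss <- setdiff(keys, names(covariates))
  if (length(miss))
    stop_("missing covariate(s) for species '%s': %s", species$name,
          toString(miss))
  z <- vapply(keys, function(k) {
    (covariates[[k]] - species$standardization$center[[k]]) /
      species$standardization$scale[[k]]
  }, numeric(nrow(covariates)))
  z <- matrix(z, nrow = nrow(covariates))
  eta <- species$intercept + as.vector(z %*% species$coefficients)
  stats::plogis(eta)
}

#' Default virtual waterbird community
#'
#' Three archetypes spanning the responses summarized for the real
#' community: a wetland-obligate driven by semipermanent basins and
#' grassland, a climate-sensitive species that declines with temperature
#' and tracks multi-year precipitation, and a generalist with a weak
#' unimodal temperature response.
#'
#' @param response_scale buffer radius (m) shared by the community.
#' @return named list of `virtual_species`.
#' @export
default_species_pool <- function(response_scale = 2000) {
  list(
    wetland_obligate = virtual_species(
      "wetland_obligate",
      coefficients = c(semi = 2, grass = 1.5, crop = -0.5),
      intercept = -0.5, response_scale = response_scale),
    climate_sensitive = virtual_species(
      "climate_sensitive",
      coefficients = c(T_1yr = -1.5, P_10yr = 1, pal = 1),
      intercept = -0.5, response_scale = response_scale),
    generalist = virtual_species(
      "generalist",
      coefficients = c(total = 0.8, T_sum = -0.4),
      intercept = 0.5, response_scale = response_scale)
  )
}
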