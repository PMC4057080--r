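## Covariate vocabulary: 13 land-cover composition variables (9 wetland,
## 4 upland) and 18 climate variables (9 temperature, 9 precipitation).
## Short names follow the field's usage so importance reports read as e.g.
## "W-semi(+)" or "P-10yr(-)".

#' @rdname covariate_names
#' @export
WETLAND_VARS <- c("temp", "seas", "semi", "lake", "river", "shrub",
                  "forest", "pal", "total")

#' @rdname covariate_names
#' @export
UPLAND_VARS <- c("crop", "grass", "devel", "tree")

#' @rdname covariate_names
#' @export
LAND_VARS <- c(WETLAND_VARS, UPLAND_VARS)

.climate_suffixes <- c("spr", "wint", "fall", "sum", "1yr", "5yr", "10yr",
                       "5yr_sd", "10yr_sd")

#' @rdname covariate_names
#' @export
TEMP_VARS <- paste0("T_", .climate_suffixes)

#' @rdname covariate_names
#' @export
PRECIP_VARS <- paste0("P_", .climate_suffixes)

#' @rdname covariate_names
#' @export
CLIMATE_VARS <- c(TEMP_VARS, PRECIP_VARS)

#' Covariate vocabulary
#'
#' The 31 predictor names used throughout the pipeline: wetland composition
#' (`temp`, `seas`, `semi`, `lake`, `river`, `shrub`, `forest`, plus the
#' aggregates `pal` = temp+seas+semi and `total` = all wetland), upland
#' composition (`crop`, `grass`, `devel`, `tree`), and seasonal / annual /
#' multi-year temperature (`T_*`) and precipitation (`P_*`) aggregates.
#'
#' @name covariate_names
#' @export
ALL_PREDICTORS <- c(LAND_VARS, CLIMATE_VARS)

## Raster class codes: the 11 mapped land-cover classes (aggregates pal and
## total are derived, never rasterized).
#' Raster land-cover class codes
#'
#' Integer codes used in categorical landscape rasters: 1-7 wetland regimes
#' (temporary, seasonal, semipermanent, lake, river, forested, shrub),
#' 8-11 upland (cropland, grassland, developed, tree).
#' @export
LAND_CLASS_CODES <- stats::setNames(1:11, c("temp", "seas", "semi", "lake",
                                            "river", "forest", "shrub",
                                            "crop", "grass", "devel", "tree"))

#' Canonical composition buffer radii (metres)
#' @export
CANONICAL_SCALES <- c(200, 400, 1000, 2000, 4000, 8000)

#' Map an internal predictor name to its reporting label
#'
#' Land-cover variables gain a `W-` (wetland) or `U-` (upland) prefix;
#' climate variables swap the underscore for a dash (`T_5yr` -> `T-5yr`).
#' An optional sign code is appended in parentheses.
#'
#' @param predictor internal predictor name(s), e.g. `"semi"`, `"P_10yr"`.
#' @param sign optional sign code(s) in `c("+", "-", "m", "~")`.
#' @return character vector of labels, e.g. `"W-semi(+)"`.
#' @export
format_predictor <- function(predictor, sign = NULL) {
  bad <- setdiff(predictor, ALL_PREDICTORS)
  if (length(bad)) stop_("unknown predictor name(s): %s", toString(bad))
  lab <- ifelse(predictor %in% WETLAND_VARS, paste0("W-", predictor),
         ifelse(predictor %in% UPLAND_VARS, paste0("U-", predictor),
                sub("_", "-", predictor)))
  if (!is.null(sign)) lab <- paste0(lab, "(", sign, ")")
  lab
}

#' Parse a reporting label such as "W-semi(+)" or "T-spring(-)"
#'
#' Inverse of [format_predictor()]. Tolerates the long-form season aliases
#' that appear in published tables (`spring`, `summer`, `winter`) and the
#' typographic tilde.
#'
#' @param entry character vector of labels.
#' @return data.frame with columns `entry`, `category` (W/U/P/T),
#'   `predictor` (internal name) and `sign` (`NA` when absent).
#' @export
parse_predictor_entry <- function(entry) {
  m <- regmatches(entry, regexec("^([WUPT])-([A-Za-z0-9_]+)(\\((.+)\\))?$", entry))
  bad <- entry[vapply(m, length, 1L) == 0L]
  if (length(bad)) stop_("unparseable importance entry: %s", toString(bad))
  cat_ <- vapply(m, `[`, "", 2L)
  var <- vapply(m, `[`, "", 3L)
  sign <- vapply(m, `[`, "", 5L)
  sign[sign == ""] <- NA_character_
  sign[!is.na(sign) & sign %in% c("∼", "⁓")] <- "~"
  sign[!is.na(sign) & sign %in% c("−", "–")] <- "-"
  aliases <- c(spring = "spr", summer = "sum", winter = "wint", autumn = "fall")
  var <- ifelse(var %in% names(aliases), aliases[var], var)
  predictor <- ifelse(cat_ %in% c("P", "T"), paste0(cat_, "_", var), var)
  bad <- entry[!predictor %in% ALL_PREDICTORS]
  if (length(bad)) stop_("entry names no known predictor: %s", toString(bad))
  badsign <- entry[!is.na(sign) & !sign %in% c("+", "-", "m", "~")]
  if (length(badsign)) stop_("invalid sign code in entry: %s", toString(badsign))
  data.frame(entry = entry, category = cat_, predictor = predictor,
             sign = sign, stringsAsFactors = FALSE)
}
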