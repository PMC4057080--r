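#' Transcribed reference tables from the published 31-species assessment
#'
#' Plain-text transcriptions of the published regional waterbird SDM
#' results that this package reimplements, shipped as fixtures so the
#' table-level arithmetic (column means, category shares, prevalence /
#' performance correlation) can be recomputed exactly:
#' * `evaluation` — per-species prevalence in each partition, main-test
#'   confusion counts, overall accuracy and AUC, and dry-years accuracy
#'   and AUC (31 species);
#' * `range_change` — percent change in suitable cells under two future
#'   climate scenarios (a statistically downscaled GCM, "cgcm", and a
#'   dynamically downscaled one, "wrfc") and their average (31 species);
#' * `importance_main` — the top-ten predictors with response signs per
#'   species (31 x 10 entries);
#' * `importance_dry` — the dry-years (1987--1992) top-ten lists for the
#'   22 species passing the 0.07 prevalence cutoff (22 x 10 entries).
#'
#' @param name which table.
#' @return data.frame.
#' @export
reference_table <- function(name = c("evaluation", "range_change",
                                     "importance_main", "importance_dry")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   paste0("ppr_", switch(name,
                                         evaluation = "model_evaluation",
                                         range_change = "range_change",
                                         importance_main = "importance_main",
                                         importance_dry = "importance_dry"),
                          ".csv"),
                   package = "prairieSDM", mustWork = TRUE)
  utils::read.csv(f, check.names = FALSE)
}

#' Column mean as an integer percent
#'
#' @param values numeric vector (signed percents).
#' @return mean rounded half away from zero.
#' @export
column_mean <- function(values) {
  if (!length(values)) stop_("empty input")
  round_half_away(mean(values))
}

#' Two-scenario average for one species
#'
#' @param scenario_a,scenario_b percent change under each scenario.
#' @return mean rounded half away from zero.
#' @export
species_pair_average <- function(scenario_a, scenario_b) {
  round_half_away((scenario_a + scenario_b) / 2)
}

#' Group species by climate-change sensitivity
#'
#' Sensitivity is defined on projected habitat loss (= minus the average
#' percent change): loss >= 66 is `most`, 33 <= loss < 66 `moderate`,
#' loss < 33 (including gains) `least`.
#'
#' @param change named (or unnamed) vector of average percent changes.
#' @return data.frame `species`, `change`, `group`.
#' @export
sensitivity_groups <- function(change) {
  loss <- -change
  group <- ifelse(loss >= 66, "most", ifelse(loss >= 33, "moderate", "least"))
  data.frame(species = names(change) %||% seq_along(change),
             change = unname(change),
             group = factor(group, levels = c("most", "moderate", "least")),
             row.names = NULL)
}

#' Share of top-ten entries falling in given predictor categories
#'
#' @param entries character vector of `"W-semi(+)"`-style labels.
#' @param categories subset of `c("W", "U", "P", "T")`.
#' @return integer percent (rounded half away from zero).
#' @export
top10_category_share <- function(entries, categories) {
  parsed <- parse_predictor_entry(entries)
  round_half_away(100 * mean(parsed$category %in% categories))
}

#' Share of the available predictor pool
#'
#' @param size predictors in the category (e.g. 18 climate).
#' @param total available predictors (default 31).
#' @return integer percent.
#' @export
available_share <- function(size, total = 31) {
  stopifnot(size >= 0, size <= total)
  round_half_away(100 * size / total)
}

#' Enrichment of a category among top-ten predictors
#'
#' How much more (or less) likely a predictor category is to appear in
#' the top-ten lists than in the available pool.
#'
#' @param top10_share integer percent among top-ten entries.
#' @param avail_share integer percent of the available pool.
#' @return ratio, reported to 1 decimal.
#' @export
enrichment_ratio <- function(top10_share, avail_share) {
  if (avail_share == 0) stop_("available share is zero: ratio undefined")
  round_half_away(top10_share / avail_share, digits = 1)
}

#' Render a report bundle from pipeline artifacts
#'
#' Writes the per-species evaluation table, range-change table,
#' importance lists, sensitivity groups and a run manifest (seed, config,
#' md5 hash of the canonical config JSON) to a directory.
#'
#' @param artifacts list with any of: `evaluation` (data.frame),
#'   `change` (data.frame with `species` and scenario columns),
#'   `importance_main`, `importance_dry` (data.frames `species`, `rank`,
#'   `entry`), `sensitivity` (from [sensitivity_groups()]), `config`
#'   (an [sdm_config()]), `seed`.
#' @param out_dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
render_report <- function(artifacts, out_dir) {
  required <- c("evaluation", "change", "importance_main", "config", "seed")
  miss <- setdiff(required, names(artifacts))
  if (length(miss)) stop_("missing pipeline artifact(s): %s", toString(miss))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[file]] <<- p
  }
  wr(artifacts$evaluation, "evaluation.csv")
  wr(artifacts$change, "change.csv")
  wr(artifacts$importance_main, "importance_main.csv")
  if (!is.null(artifacts$importance_dry))
    wr(artifacts$importance_dry, "importance_dry.csv")
  if (is.null(artifacts$sensitivity) && "average" %in% names(artifacts$change))
    artifacts$sensitivity <- sensitivity_groups(
      stats::setNames(artifacts$change$average, artifacts$change$species))
  if (!is.null(artifacts$sensitivity)) wr(artifacts$sensitivity, "sensitivity.csv")

  cfg_json <- jsonlite::toJSON(unclass(artifacts$config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(seed = artifacts$seed,
                   config = unclass(artifacts$config),
                   config_hash = unname(tools::md5sum(tmp)),
                   package_version = as.character(utils::packageVersion("prairieSDM")),
                   files = names(paths))
  unlink(tmp)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["manifest.json"]] <- mp
  invisible(unlist(paths))
}
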