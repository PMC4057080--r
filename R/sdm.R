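#' SDM configuration
#'
#' The balanced bagged-classification-tree configuration: 3000 trees, each
#' grown on a bootstrap of 25 presence and 25 absence records (with
#' replacement), 5 candidate predictors per split, six candidate
#' land-cover scales, a 0.05 section-level prevalence cutoff for focal
#' species (0.07 with >= 10 detections for the dry-years models), and a
#' 0.5 probability threshold for concluding presence.
#'
#' @param n_trees trees per forest.
#' @param per_class_sample per-tree, per-class bootstrap size.
#' @param candidate_vars_per_split predictors evaluated at each split.
#' @param scales candidate composition radii (m).
#' @param prevalence_cutoff minimum prevalence for focal species.
#' @param dry_prevalence_cutoff prevalence cutoff for dry-years models.
#' @param dry_min_detections minimum detections for dry-years models.
#' @param threshold probability threshold for concluding presence (strict `>`).
#' @param seed integer seed for forest construction.
#' @return an object of class `sdm_config`.
#' @export
sdm_config <- function(n_trees = 3000,
                       per_class_sample = 25,
                       candidate_vars_per_split = 5,
                       scales = CANONICAL_SCALES,
                       prevalence_cutoff = 0.05,
                       dry_prevalence_cutoff = 0.07,
                       dry_min_detections = 10,
                       threshold = 0.5,
                       seed = 1L) {
  stopifnot(n_trees >= 1, per_class_sample >= 1,
            candidate_vars_per_split >= 1, length(scales) >= 1)
  if (threshold <= 0 || threshold >= 1) stop_("threshold must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees),
                 per_class_sample = as.integer(per_class_sample),
                 candidate_vars_per_split = as.integer(candidate_vars_per_split),
                 scales = scales,
                 prevalence_cutoff = prevalence_cutoff,
                 dry_prevalence_cutoff = dry_prevalence_cutoff,
                 dry_min_detections = dry_min_detections,
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "sdm_config")
}

#' Partition surveyed years into training, test and drought sets
#'
#' Drought bird-years form their own partition. The remaining surveyed
#' years of each route alternate between `main_train` and `main_test`,
#' starting with the route's earliest surveyed year in `main_train`
#' (`flip = TRUE` starts in `main_test`), so no two consecutively surveyed
#' non-drought years of a route share a main partition and temporal
#' autocorrelation between training and test rows is reduced.
#'
#' @param route_years data.frame with `route_id` and `year` (one row per
#'   surveyed segment-year; duplicated years per route are allowed and get
#'   the same label).
#' @param drought_years integer vector of drought bird-years.
#' @param flip start the alternation in `main_test` instead.
#' @return the input with a `partition` factor column
#'   (`main_train`/`main_test`/`drought`).
#' @export
partition_years <- function(route_years, drought_years = integer(0),
                            flip = FALSE) {
  stopifnot(all(c("route_id", "year") %in% names(route_years)))
  part <- rep(NA_character_, nrow(route_years))
  part[route_years$year %in% drought_years] <- "drought"
  for (r in unique(route_years$route_id)) {
    i <- which(route_years$route_id == r & is.na(part))
    yrs <- sort(unique(route_years$year[i]))
    lab <- rep(c("main_train", "main_test"), length.out = length(yrs))
    if (flip) lab <- rev(c("main_train", "main_test"))[match(lab, c("main_train", "main_test"))]
    part[i] <- lab[match(route_years$year[i], yrs)]
  }
  route_years$partition <- factor(part,
                                  levels = c("main_train", "main_test", "drought"))
  route_years
}

#' Select focal species by prevalence
#'
#' @param occurrences data.frame with `species` and `present`.
#' @param cutoff minimum section-level occurrence rate (inclusive).
#' @param min_detections minimum number of detections (inclusive).
#' @return data.frame `species`, `prevalence`, `detections`, `focal`.
#' @export
select_focal_species <- function(occurrences, cutoff = 0.05,
                                 min_detections = 0) {
  if (!nrow(occurrences)) stop_("empty occurrence table")
  agg <- stats::aggregate(present ~ species, data = occurrences,
                          FUN = function(x) c(mean(x), sum(x)))
  out <- data.frame(species = agg$species,
                    prevalence = agg$present[, 1],
                    detections = agg$present[, 2])
  out$focal <- out$prevalence >= cutoff & out$detections >= min_detections
  out
}

#' Choose the first or third route segment for a species
#'
#' The segment with more detections wins; ties go to the first.
#'
#' @param detections_first,detections_third detection counts.
#' @return `"first"` or `"third"`.
#' @export
choose_segment <- function(detections_first, detections_third) {
  stopifnot(is.numeric(detections_first), is.numeric(detections_third))
  ifelse(detections_third > detections_first, "third", "first")
}

#' Fit a balanced bagged-classification-tree SDM
#'
#' An ensemble of `n_trees` classification trees, each grown on a
#' per-class bootstrap of `per_class_sample` presences and
#' `per_class_sample` absences drawn with replacement, evaluating
#' `candidate_vars_per_split` predictors per split. The probability
#' prediction is the fraction of trees voting presence. Out-of-bag
#' accuracy (at the config threshold, strict `>`) is recorded.
#' Deterministic given `config$seed`.
#'
#' @param data feature table from [build_feature_table()] (or any
#'   data.frame with a binary `present` column and predictor columns).
#' @param config an [sdm_config()].
#' @param predictors predictor column names; defaults to the 31 canonical
#'   predictors present in `data`.
#' @param species optional species label stored in the fit.
#' @param scale_radius optional chosen scale stored in the fit.
#' @return object of class `pp_sdm`: the forest, OOB probabilities and
#'   accuracy, training summary and config snapshot.
#' @export
fit_balanced_forest <- function(data, config = sdm_config(),
                                predictors = NULL, species = NULL,
                                scale_radius = NULL) {
  stopifnot(inherits(config, "sdm_config"), "present" %in% names(data))
  if (is.null(predictors))
    predictors <- intersect(ALL_PREDICTORS, names(data))
  if (!length(predictors)) stop_("no predictor columns found")
  y <- factor(data$present, levels = c(0L, 1L))
  if (length(unique(data$present)) < 2L)
    stop_("single-class response: cannot fit a presence-absence model")
  n1 <- sum(data$present == 1L); n0 <- sum(data$present == 0L)
  x <- data[predictors]
  if (min(n0, n1) < config$per_class_sample) {
    warn_("a class has %d records, fewer than the per-tree sample of %d; sampling with replacement still draws %d",
          min(n0, n1), config$per_class_sample, config$per_class_sample)
    ## replicate the scarce class so each per-tree stratum can still supply
    ## per_class_sample draws; with-replacement draws from the replicated
    ## rows are distributionally identical to draws from the originals
    idx <- seq_len(nrow(data))
    for (cls in c(0L, 1L)) {
      n_cls <- sum(data$present == cls)
      if (n_cls > 0 && n_cls < config$per_class_sample) {
        extra <- rep(which(data$present == cls),
                     ceiling(config$per_class_sample / n_cls) - 1L)
        idx <- c(idx, extra)
      }
    }
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = x, y = y,
    ntree = config$n_trees,
    mtry = min(config$candidate_vars_per_split, length(predictors)),
    replace = TRUE,
    strata = y,
    sampsize = c(config$per_class_sample, config$per_class_sample),
    importance = TRUE,
    keep.forest = TRUE)
  oob_prob <- forest$votes[seq_len(nrow(data)), "1"]
  oob_pred <- as.integer(oob_prob > config$threshold)
  structure(list(forest = forest,
                 predictors = predictors,
                 species = species,
                 scale_radius = scale_radius,
                 oob_prob = oob_prob,
                 oob_accuracy = mean(oob_pred == data$present),
                 training = list(n = nrow(data), n_present = n1,
                                 prevalence = n1 / nrow(data),
                                 range = lapply(x, range)),
                 config = config),
            class = "pp_sdm")
}

#' @export
print.pp_sdm <- function(x, ...) {
  cat(sprintf("pp_sdm%s: %d trees, %d predictors, n = %d (prevalence %.3f), OOB accuracy %.3f%s\n",
              if (!is.null(x$species)) paste0(" [", x$species, "]") else "",
              x$forest$ntree, length(x$predictors), x$training$n,
              x$training$prevalence, x$oob_accuracy,
              if (!is.null(x$scale_radius)) sprintf(", scale %g m", x$scale_radius) else ""))
  invisible(x)
}

#' Predict occurrence probability
#'
#' @param object a `pp_sdm`.
#' @param newdata data.frame with the model's predictor columns.
#' @param ... unused.
#' @return numeric vector: fraction of trees voting presence.
#' @export
predict.pp_sdm <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss)) stop_("newdata lacks predictor(s): %s", toString(miss))
  as.vector(stats::predict(object$forest,
                           newdata[object$predictors], type = "prob")[, "1"])
}

#' Fit at all candidate scales and select the best
#'
#' Fits one balanced forest per candidate scale (same configuration and
#' seed, so scales differ only in the land-cover columns) and keeps the
#' one with the highest out-of-bag overall accuracy; ties break to the
#' smallest radius. Out-of-bag accuracy is used so the test partition is
#' never consumed by model selection.
#'
#' @param datasets named list of feature tables, names = scale radii (m);
#'   all must share the same rows (same segment-years).
#' @param config an [sdm_config()].
#' @param ... passed to [fit_balanced_forest()] (e.g. `species`).
#' @return list: `chosen_scale`, `model` (a `pp_sdm`), `accuracy` (named
#'   vector over scales), `models` (all fits).
#' @export
select_scale <- function(datasets, config = sdm_config(), ...) {
  stopifnot(is.list(datasets), length(datasets) >= 1, !is.null(names(datasets)))
  scales <- as.numeric(names(datasets))
  if (anyNA(scales)) stop_("dataset names must be scale radii in metres")
  n <- unique(vapply(datasets, nrow, integer(1)))
  if (length(n) != 1L) stop_("scale variants differ in row count: %s", toString(n))
  models <- lapply(datasets, fit_balanced_forest, config = config, ...)
  acc <- vapply(models, `[[`, numeric(1), "oob_accuracy")
  names(acc) <- names(datasets)
  best <- which(acc == max(acc))
  pick <- best[which.min(scales[best])]
  model <- models[[pick]]
  model$scale_radius <- scales[pick]
  list(chosen_scale = scales[pick], model = model, accuracy = acc,
       models = models)
}

#' Permutation variable importance
#'
#' Mean decrease in out-of-bag classification accuracy across trees when
#' the predictor's values are randomly shuffled, as accumulated during
#' forest construction. Ranked non-increasing; ties keep predictor order.
#'
#' @param model a `pp_sdm`.
#' @param data optional feature table; when supplied, a response `sign`
#'   column is added via [response_sign()].
#' @param top optional integer: keep only the `top` rows.
#' @return data.frame `rank`, `predictor`, `importance`, optionally
#'   `sign` and `entry` (the `"W-semi(+)"`-style label).
#' @export
permutation_importance <- function(model, data = NULL, top = NULL) {
  stopifnot(inherits(model, "pp_sdm"))
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  out <- data.frame(predictor = rownames(imp),
                    importance = as.vector(imp[, 1]))
  out <- out[order(-out$importance), ]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  if (!is.null(data)) {
    out$sign <- vapply(out$predictor, function(p)
      response_sign(model, data, p), character(1))
    out$entry <- format_predictor(out$predictor, out$sign)
  }
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), ]
  out
}

#' Response sign of a predictor via partial dependence
#'
#' Evaluates the model's mean predicted probability over the training rows
#' at 20 quantile-spaced values of the predictor (all other predictors at
#' their observed values). The profile is classified as `"+"` (monotone
#' non-decreasing within tolerance, with a net rise), `"-"` (the mirror),
#' `"m"` (an interior maximum exceeding both endpoints by more than the
#' tolerance) or `"~"` (equivocal, including constant predictors).
#'
#' @param model a `pp_sdm`.
#' @param data feature table used for the profile (typically training data).
#' @param predictor predictor name.
#' @param n_points profile resolution.
#' @param tol tolerance in probability for monotonicity/unimodality calls.
#' @param max_rows subsample cap on profile rows (for speed).
#' @return one of `"+"`, `"-"`, `"m"`, `"~"`.
#' @export
response_sign <- function(model, data, predictor, n_points = 20, tol = 0.01,
                          max_rows = 200) {
  stopifnot(inherits(model, "pp_sdm"))
  if (!predictor %in% model$predictors)
    stop_("'%s' is not a model predictor", predictor)
  v <- data[[predictor]]
  grid <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_points),
                                 names = FALSE, type = 7))
  if (length(grid) < 2L) return("~")
  rows <- data[model$predictors]
  if (nrow(rows) > max_rows) {
    idx <- round(seq(1, nrow(rows), length.out = max_rows))
    rows <- rows[idx, , drop = FALSE]
  }
  prof <- vapply(grid, function(g) {
    rows[[predictor]] <- g
    mean(predict(model, rows))
  }, numeric(1))
  d <- diff(prof)
  net <- prof[length(prof)] - prof[1]
  if (all(d >= -tol) && net > tol) return("+")
  if (all(d <= tol) && -net > tol) return("-")
  interior <- prof[-c(1, length(prof))]
  if (length(interior) && max(interior) > max(prof[1], prof[length(prof)]) + tol)
    return("m")
  "~"
}
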