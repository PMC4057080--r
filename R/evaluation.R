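#' Confusion counts at a probability threshold
#'
#' Presence is concluded when the predicted probability strictly exceeds
#' the threshold; a probability exactly on the threshold is classed
#' absent. The strict rule matches the suitability rule used in
#' projection ("greater than 0.5").
#'
#' @param probabilities predicted occurrence probabilities.
#' @param labels observed 0/1 presence.
#' @param threshold probability threshold (default 0.5).
#' @return object of class `confusion`: list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  if (!length(probabilities)) stop_("empty input")
  if (length(probabilities) != length(labels))
    stop_("probabilities (%d) and labels (%d) differ in length",
          length(probabilities), length(labels))
  if (!all(labels %in% c(0, 1))) stop_("labels must be binary 0/1")
  pred <- probabilities > threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion")
}

#' Overall classification accuracy
#'
#' Correct predictions over total predictions, as a percentage. For
#' reporting, the percentage is rounded half away from zero to the
#' nearest integer (`round = TRUE`, the default).
#'
#' @param cm a `confusion` object or list with `tp`, `fp`, `tn`, `fn`.
#' @param round round to integer percent for reporting.
#' @return percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(cm, round = TRUE) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total < 1) stop_("empty confusion matrix")
  pct <- 100 * (cm$tp + cm$tn) / total
  if (round) round_half_away(pct) else pct
}

#' Area under the ROC curve
#'
#' The rank (Mann--Whitney) formulation: the probability that a randomly
#' chosen presence receives a higher score than a randomly chosen absence,
#' with tied scores counting one half. Equivalent to exhaustive pairwise
#' concordance.
#'
#' @param probabilities predicted scores.
#' @param labels observed 0/1 presence; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop_("probabilities and labels differ in length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_("AUC undefined: both classes must be present")
  r <- rank(probabilities)  # midranks handle ties as half-concordant
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auc_band <- function(a) {
  if (a > 0.9) "outstanding" else if (a >= 0.8) "good"
  else if (a >= 0.7) "acceptable" else "poor"
}

#' Evaluate a fitted SDM on a held-out partition
#'
#' Predicts to the supplied rows and reports confusion counts, overall
#' accuracy (integer percent), AUC with its qualitative band (>= 0.7
#' acceptable, 0.8--0.9 good, > 0.9 outstanding) and partition prevalence.
#' A single-class partition yields `NA` AUC with a warning.
#'
#' @param model a `pp_sdm`.
#' @param rows feature table of the evaluation partition.
#' @param label partition label stored in the report.
#' @return object of class `evaluation_report`.
#' @export
evaluate_main <- function(model, rows, label = "main_test") {
  if (!nrow(rows)) stop_("empty evaluation partition")
  p <- predict(model, rows)
  cm <- confusion_counts(p, rows$present, model$config$threshold)
  a <- if (length(unique(rows$present)) < 2L) {
    warn_("partition '%s' has a single class; AUC omitted", label)
    NA_real_
  } else auc(p, rows$present)
  structure(list(species = model$species, label = label,
                 n = nrow(rows), prevalence = mean(rows$present),
                 confusion = cm,
                 overall_accuracy = overall_accuracy(cm),
                 auc = a,
                 band = if (is.na(a)) NA_character_ else auc_band(a)),
            class = "evaluation_report")
}

#' Evaluate transferability to the drought partition
#'
#' The same metrics computed on drought rows with a model trained on the
#' wetter years; when the main-test report is supplied, degradation
#' deltas (accuracy and AUC) are attached.
#'
#' @param model a `pp_sdm` trained without the drought rows.
#' @param drought_rows feature table of drought segment-years.
#' @param main_report optional `evaluation_report` on the main test set.
#' @return object of class `evaluation_report` with a `delta` element
#'   when `main_report` is given.
#' @export
evaluate_transferability <- function(model, drought_rows, main_report = NULL) {
  if (is.null(drought_rows) || !nrow(drought_rows))
    stop_("empty drought partition")
  rep_ <- evaluate_main(model, drought_rows, label = "drought")
  if (!is.null(main_report)) {
    rep_$delta <- list(
      accuracy = rep_$overall_accuracy - main_report$overall_accuracy,
      auc = rep_$auc - main_report$auc)
  }
  rep_
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation [%s]%s: n = %d, prevalence %.2f\n", x$label,
              if (!is.null(x$species)) paste0(" ", x$species) else "",
              x$n, x$prevalence))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d | accuracy %d%% | AUC %s (%s)\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn,
              x$overall_accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.2f", x$auc)),
              ifelse(is.na(x$band), "-", x$band)))
  invisible(x)
}

#' Spearman correlation between prevalence and model performance
#'
#' Rank correlation (midrank ties) with a two-sided p-value, used to check
#' whether model performance is related to species prevalence.
#'
#' @param prevalence per-species prevalence.
#' @param performance per-species AUC (or any performance score).
#' @return list `rho`, `p_value`, `n`.
#' @export
prevalence_performance_correlation <- function(prevalence, performance) {
  if (length(prevalence) != length(performance))
    stop_("inputs differ in length")
  if (length(prevalence) < 4) stop_("need at least 4 species")
  if (stats::sd(prevalence) == 0 || stats::sd(performance) == 0)
    stop_("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(prevalence, performance,
                                         method = "spearman",
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(prevalence))
}
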