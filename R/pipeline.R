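# Cohort-level wrappers: feature extraction across all recordings, feature
# table assembly with group tags, and the per-group selection + modelling +
# ensemble analysis.

#' Extract the novel features for every subject-period of a cohort
#'
#' Runs the temperature chain on each recording and the sleep-feature
#' computation on each subject-period's night variables, returning one row
#' per (subject, period).
#'
#' @param cohort A `wf_cohort` from [generate_cohort()], or a list with
#'   `recordings` (list of `wf_recording`), `sleep_windows` and
#'   `night_vars` tibbles.
#' @param config A [wf_config()].
#' @param extended Emit extended temperature columns.
#' @return A feature tibble (novel features only).
#' @export
extract_cohort_features <- function(cohort, config = wf_config(),
                                    extended = FALSE) {
  temp <- purrr::map_dfr(cohort$recordings, function(rec) {
    sw <- cohort$sleep_windows[
      cohort$sleep_windows$subject_id == rec$subject_id[1] &
        cohort$sleep_windows$period_id == rec$period_id[1], ]
    extract_temp_features(rec, sw, config, extended)
  })
  sleep <- cohort$night_vars |>
    dplyr::group_by(.data$subject_id, .data$period_id) |>
    dplyr::group_modify(~ extract_sleep_features(.x)) |>
    dplyr::ungroup()
  dplyr::inner_join(
    dplyr::select(temp, -"n_valid_nights", -"n_valid_days"),
    sleep, by = c("subject_id", "period_id")
  )
}

#' Assemble the full analysis feature table with group tags
#'
#' Joins the novel features with an optional externally computed
#' (GGIR-style) activity/sleep feature table and the demographic covariates
#' from the outcome table (age; sex encoded as `sex_f`, 1 = female), and
#' records each column's feature group in the `feature_groups` attribute.
#'
#' @param novel Novel feature tibble from [extract_cohort_features()].
#' @param outcomes Outcome tibble (for age and sex).
#' @param external Optional external feature tibble keyed by subject and
#'   period; columns prefixed `pa_` are tagged "pa", the rest "sleep".
#' @return A feature tibble with attribute `feature_groups` (named
#'   character vector: column -> "demographic"/"sleep"/"pa"/"novel").
#' @export
assemble_feature_table <- function(novel, outcomes, external = NULL) {
  key <- c("subject_id", "period_id")
  out <- novel
  groups <- setNames(rep("novel", ncol(novel) - 2), setdiff(names(novel), key))
  if (!is.null(external)) {
    out <- dplyr::inner_join(out, external, by = key)
    ext_cols <- setdiff(names(external), key)
    groups <- c(groups, setNames(
      ifelse(startsWith(ext_cols, "pa_"), "pa", "sleep"), ext_cols))
  }
  base <- outcomes[outcomes$timepoint == "baseline", ]
  idx <- match(out$subject_id, base$subject_id)
  out$age <- base$age[idx]
  out$sex_f <- as.integer(base$sex[idx] == "F")
  groups <- c(groups, c(age = "demographic", sex_f = "demographic"))
  attr(out, "feature_groups") <- groups
  out
}

#' Per-group feature selection, modelling and AUC-weighted ensemble
#'
#' For each requested feature group (with age and sex appended to control
#' for demographics), ranks features with RRCT inside a leave-one-subject-
#' out loop, aggregates the per-fold rankings with the voting scheme, fits
#' fold-standardized L2 logistic regressions with 1..m_sel features, and
#' records the AUC curve. The per-group models are then combined with the
#' weighted-average ensemble, each weight being the group's maximum
#' out-of-sample AUC (at its best feature count).
#'
#' @param features Prepared feature tibble (see [prepare_features()]) with
#'   a `feature_groups` attribute.
#' @param outcomes Outcome tibble.
#' @param target `"diagnosis"` or `"severity"`.
#' @param groups Feature groups to model; `"combined"` pools all columns.
#' @param config A [wf_config()].
#' @return A list of class `wf_analysis`: per-group `voted`
#'   (`wf_voted`), `curve` (`wf_auc_curve`), plus `ensemble` (tibble of
#'   per-sample combined probabilities), `ensemble_metrics`, `weights`,
#'   `target`.
#' @export
analyze_cohort <- function(features, outcomes,
                           target = c("diagnosis", "severity"),
                           groups = c("sleep", "pa", "novel", "combined"),
                           config = wf_config()) {
  target <- match.arg(target)
  key <- c("subject_id", "period_id")
  fg <- attr(features, "feature_groups")
  if (is.null(fg)) {
    fg <- setNames(rep("novel", ncol(features) - 2),
                   setdiff(names(features), key))
  }
  fg <- fg[names(fg) %in% names(features)]
  demo <- names(fg)[fg == "demographic"]

  y <- encode_target(outcomes, features[key], target)
  subj <- features$subject_id

  groups <- intersect(groups, c(unique(fg), "combined"))
  fits <- list()
  for (g in groups) {
    cols <- if (g == "combined") names(fg) else
      union(names(fg)[fg == g], demo)   # demographics appended to each group
    cols <- intersect(cols, names(features))
    if (length(cols) == 0) next
    x <- features[, cols, drop = FALSE]
    msel <- min(config$m_sel, ncol(x))
    selmat <- loso_selection(x, y, subj, msel)
    voted <- vote_features(selmat)
    curve <- auc_curve(x, y, subj, voted$feature, config)
    fits[[g]] <- list(selection = selmat, voted = voted, curve = curve)
  }

  weights <- vapply(fits, function(f) attr(f$curve, "best_auc"), numeric(1))
  if (any(weights <= 0)) {
    abort(sprintf(
      paste("Ensemble weights must be positive, but the %s model(s) achieved",
            "best AUC 0 (degenerate at this sample size); drop the group or",
            "enlarge the cohort."),
      paste(sprintf("'%s'", names(fits)[weights <= 0]), collapse = ", ")))
  }
  probs <- vapply(fits, function(f) {
    best <- attr(f$curve, "best_k")
    attr(f$curve, "cv_results")[[best]]$prob
  }, numeric(nrow(features)))
  ens <- weighted_ensemble(probs, weights)
  structure(list(
    groups = fits,
    weights = weights,
    ensemble = tibble::tibble(subject_id = subj,
                              period_id = features$period_id,
                              y = y, prob = ens),
    ensemble_metrics = metrics_binary(ens, y),
    target = target
  ), class = "wf_analysis")
}

#' @export
print.wf_analysis <- function(x, ...) {
  cat(sprintf("<wf_analysis> target: %s\n", x$target))
  for (g in names(x$groups)) {
    cu <- x$groups[[g]]$curve
    cat(sprintf("  %-9s best AUC %.3f at k = %d\n",
                g, attr(cu, "best_auc"), attr(cu, "best_k")))
  }
  cat(sprintf("  ensemble  AUC %.3f (balanced accuracy %.3f)\n",
              x$ensemble_metrics$auc, x$ensemble_metrics$balanced_accuracy))
  invisible(x)
}

#' One row per model of an analysis, plus the ensemble
#'
#' @param x A `wf_analysis`.
#' @param ... Unused.
#' @return A tibble `model`, `best_k`, `auc`, `balanced_accuracy`.
#' @export
tidy.wf_analysis <- function(x, ...) {
  rows <- purrr::map_dfr(names(x$groups), function(g) {
    cu <- x$groups[[g]]$curve
    best <- attr(cu, "best_k")
    cv <- attr(cu, "cv_results")[[best]]
    m <- metrics_binary(cv$prob, cv$y)
    tibble::tibble(model = g, best_k = best, auc = m$auc,
                   balanced_accuracy = m$balanced_accuracy)
  })
  dplyr::bind_rows(rows, tibble::tibble(
    model = "ensemble", best_k = NA_integer_,
    auc = x$ensemble_metrics$auc,
    balanced_accuracy = x$ensemble_metrics$balanced_accuracy
  ))
}
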