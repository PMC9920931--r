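# Outcome encoding, fold-standardized L2 logistic regression under
# leave-one-subject-out cross-validation, metrics, and the AUC-weighted
# probabilistic ensemble.

#' Impute and prune a feature table before selection and modelling
#'
#' Missing cells are first filled from the same subject's other wear period
#' (within-subject imputation cannot leak information across subjects);
#' columns that still contain missing values are dropped; samples whose
#' sleep-derived features are entirely missing are removed.
#'
#' @param features Feature tibble keyed by `subject_id`, `period_id`.
#' @param sleep_cols Columns treated as sleep-derived for the all-missing
#'   sample rule; defaults to [sleep_feature_names()] intersected with the
#'   table.
#' @return The pruned tibble; dropped columns and rows are reported in the
#'   attributes `dropped_features` and `dropped_samples`.
#' @export
prepare_features <- function(features, sleep_cols = NULL) {
  key <- c("subject_id", "period_id")
  feat_cols <- setdiff(names(features), key)
  if (is.null(sleep_cols)) sleep_cols <- intersect(sleep_feature_names(), feat_cols)

  out <- features
  # within-subject imputation across the other period
  for (col in feat_cols) {
    miss <- which(is.na(out[[col]]))
    for (i in miss) {
      donor <- out[[col]][out$subject_id == out$subject_id[i] &
                            out$period_id != out$period_id[i]]
      donor <- donor[!is.na(donor)]
      if (length(donor) > 0) out[[col]][i] <- mean(donor)
    }
  }
  drop_rows <- rep(FALSE, nrow(out))
  if (length(sleep_cols) > 0) {
    drop_rows <- apply(is.na(out[, sleep_cols, drop = FALSE]), 1, all)
  }
  dropped_samples <- out[drop_rows, key]
  out <- out[!drop_rows, , drop = FALSE]
  still_na <- feat_cols[vapply(feat_cols, function(c) anyNA(out[[c]]), logical(1))]
  out <- out[, setdiff(names(out), still_na), drop = FALSE]
  attr(out, "dropped_features") <- still_na
  attr(out, "dropped_samples") <- dropped_samples
  out
}

#' Encode classification targets
#'
#' Diagnosis: TIA = 0, stroke = 1. Stroke severity group: the modified
#' Rankin Scale recorded after the wear period, dichotomized as 0 versus
#' above 0 (no disability versus any disability); the baseline mRS is never
#' used.
#'
#' @param outcomes Outcome tibble (see [read_outcomes()]).
#' @param samples Tibble with `subject_id`, `period_id` rows to encode.
#' @param target `"diagnosis"` or `"severity"`.
#' @return Integer vector of 0/1 labels aligned with `samples`.
#' @export
encode_target <- function(outcomes, samples, target = c("diagnosis", "severity")) {
  target <- match.arg(target)
  if (target == "diagnosis") {
    diag <- outcomes$diagnosis[match(samples$subject_id, outcomes$subject_id)]
    return(as.integer(diag == "stroke"))
  }
  tp <- paste0("after_", samples$period_id)
  key_out <- paste(outcomes$subject_id, outcomes$timepoint)
  mrs <- outcomes$mrs[match(paste(samples$subject_id, tp), key_out)]
  as.integer(mrs > 0)
}

# ridge logistic fit matching penalized likelihood with inverse
# regularization C: glmnet ridge with lambda = 1 / (n * C)
fit_l2_logistic <- function(x_train, y_train, C = 1) {
  n <- nrow(x_train)
  if (ncol(x_train) == 1) {
    # glmnet requires >= 2 columns; duplicate-with-zero trick keeps the
    # penalty and solution for the real column unchanged
    x_train <- cbind(x_train, 0)
  }
  # glmnet emits a small-sample advisory below 8 observations per class;
  # expected in leave-one-subject-out folds of pilot-sized cohorts
  suppressWarnings(
    glmnet::glmnet(x_train, y_train, family = "binomial", alpha = 0,
                   lambda = 1 / (n * C), standardize = FALSE,
                   thresh = 1e-10)
  )
}

predict_l2_logistic <- function(fit, x_test) {
  if (ncol(x_test) == 1) x_test <- cbind(x_test, 0)
  as.numeric(predict(fit, newx = x_test, type = "response"))
}

#' Leave-one-subject-out fit and out-of-sample prediction
#'
#' For each subject: hold out all of that subject's samples, standardize
#' every feature by the training fold's mean and standard deviation (the
#' same statistics are applied to the held-out samples, so nothing from the
#' test samples enters the fit), train an L2-penalized logistic regression
#' on the top `k` features, and predict held-out probabilities. A training
#' fold containing a single class aborts with the held-out subject named.
#'
#' @param x Complete feature data frame.
#' @param y 0/1 labels.
#' @param subject_ids Subject of each sample.
#' @param feature_list Features in descending importance.
#' @param k Number of top features to use.
#' @param config A [wf_config()] (for the penalty strength).
#' @return A tibble of class `wf_cv_result`: `subject_id`, `y`, `prob`,
#'   with each sample predicted exactly once. The attribute `fold_stats`
#'   holds each fold's standardization mean/sd (training-fold statistics
#'   only), so leakage checks can inspect them directly.
#' @export
loso_fit_predict <- function(x, y, subject_ids, feature_list,
                             k = length(feature_list),
                             config = wf_config()) {
  stopifnot(k >= 1, k <= length(feature_list))
  feats <- feature_list[seq_len(k)]
  xm <- as.matrix(as.data.frame(x)[, feats, drop = FALSE])
  subjects <- unique(subject_ids)
  if (length(subjects) < 3) abort("Leave-one-subject-out needs at least 3 subjects.")

  fold_stats <- list()
  out <- purrr::map_dfr(subjects, function(s) {
    test <- subject_ids == s
    ytr <- y[!test]
    if (length(unique(ytr)) < 2) {
      abort(sprintf("Training fold holding out subject '%s' has a single class.", s))
    }
    mu <- colMeans(xm[!test, , drop = FALSE])
    sg <- apply(xm[!test, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    fold_stats[[s]] <<- list(mean = mu, sd = sg)
    xtr <- sweep(sweep(xm[!test, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(xm[test, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- fit_l2_logistic(xtr, ytr, config$lr_inverse_reg)
    tibble::tibble(subject_id = s,
                   sample = which(test),
                   y = y[test],
                   prob = predict_l2_logistic(fit, xte))
  })
  out <- out[order(out$sample), ]
  structure(out, class = c("wf_cv_result", class(out)), k = k,
            features = feats, fold_stats = fold_stats)
}

#' Binary classification metrics
#'
#' AUC is the Mann-Whitney rank statistic (tied probabilities receive
#' average ranks, so a constant classifier scores exactly 0.5). Balanced
#' accuracy is the mean of sensitivity and specificity at the 0.5
#' threshold.
#'
#' @param prob Predicted probabilities of class 1.
#' @param y 0/1 labels (both classes must be present).
#' @param threshold Classification threshold for the confusion matrix.
#' @return List: `auc`, `balanced_accuracy`, `sensitivity`, `specificity`,
#'   `confusion` (2x2 matrix), `roc` (tibble of ROC points).
#' @export
metrics_binary <- function(prob, y, threshold = 0.5) {
  stopifnot(length(prob) == length(y))
  if (length(unique(y)) < 2) abort("Both classes must be present to compute metrics.")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(prob)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- tp / n1; spec <- tn / n0

  thr <- sort(unique(c(-Inf, prob, Inf)), decreasing = TRUE)
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(prob[y == 1] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(prob[y == 0] >= t), numeric(1))
  )
  list(auc = auc, balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(pred = c("0", "1"),
                                          truth = c("0", "1"))),
       roc = roc)
}

#' Out-of-sample AUC as features are added incrementally
#'
#' Fits the leave-one-subject-out model with the top 1, 2, ..., `m` voted
#' features and records the AUC of each, mirroring how a compact model is
#' chosen: the first model uses only the top feature.
#'
#' @inheritParams loso_fit_predict
#' @param feature_list Voted feature list (descending importance).
#' @param balanced Also record balanced accuracy per k.
#' @return A tibble of class `wf_auc_curve`: `k`, `auc` (and
#'   `balanced_accuracy`), with attributes `best_k`, `best_auc`, and
#'   `cv_results` (list of `wf_cv_result` per k).
#' @export
auc_curve <- function(x, y, subject_ids, feature_list,
                      config = wf_config(), balanced = TRUE) {
  ks <- seq_along(feature_list)
  cvs <- lapply(ks, function(k)
    loso_fit_predict(x, y, subject_ids, feature_list, k, config))
  met <- lapply(cvs, function(cv) metrics_binary(cv$prob, cv$y))
  out <- tibble::tibble(k = ks, auc = vapply(met, `[[`, numeric(1), "auc"))
  if (balanced) {
    out$balanced_accuracy <- vapply(met, `[[`, numeric(1), "balanced_accuracy")
  }
  best <- which.max(out$auc)
  structure(out, class = c("wf_auc_curve", class(out)),
            best_k = ks[best], best_auc = out$auc[best], cv_results = cvs)
}

#' AUC-weighted average of per-subset probabilities
#'
#' Combines the held-out probabilities of models fit on different feature
#' subsets into one probabilistic output per sample:
#' `p_hat_i = sum_j w_j p_ij / sum_j w_j`, where each weight is the
#' maximum out-of-sample AUC its subset's model achieved. The output is a
#' convex combination, so it always lies between the per-subset minimum and
#' maximum for every sample.
#'
#' @param prob_matrix Matrix or data frame, one column per subset model,
#'   one row per sample (all subsets must cover the same samples; missing
#'   entries are an error).
#' @param weights Positive weights, one per column.
#' @return Numeric vector of combined probabilities.
#' @export
weighted_ensemble <- function(prob_matrix, weights) {
  pm <- as.matrix(prob_matrix)
  if (anyNA(pm)) abort("Every subset must provide a probability for every sample.")
  stopifnot(length(weights) == ncol(pm), all(weights > 0))
  as.numeric(pm %*% weights / sum(weights))
}
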