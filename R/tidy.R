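# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an AUC-versus-feature-count curve
#'
#' @param x A `wf_auc_curve`.
#' @param ... Unused.
#' @return A tibble `k`, `auc` (and `balanced_accuracy` when recorded).
#' @export
tidy.wf_auc_curve <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of an AUC curve: the chosen model
#'
#' @param x A `wf_auc_curve`.
#' @param ... Unused.
#' @return A tibble with `best_k` (feature count maximizing AUC) and
#'   `best_auc`.
#' @export
glance.wf_auc_curve <- function(x, ...) {
  tibble::tibble(best_k = attr(x, "best_k"), best_auc = attr(x, "best_auc"))
}

#' Tidy a leave-one-subject-out prediction set
#'
#' @param x A `wf_cv_result`.
#' @param ... Unused.
#' @return A tibble `subject_id`, `y`, `prob`.
#' @export
tidy.wf_cv_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)[c("subject_id", "y", "prob")])
}

#' One-row performance summary of held-out predictions
#'
#' @param x A `wf_cv_result`.
#' @param ... Unused.
#' @return A tibble `k`, `auc`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
glance.wf_cv_result <- function(x, ...) {
  m <- metrics_binary(x$prob, x$y)
  tibble::tibble(k = attr(x, "k"), auc = m$auc,
                 balanced_accuracy = m$balanced_accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity)
}

#' Tidy a voted feature subset
#'
#' @param x A `wf_voted`.
#' @param ... Unused.
#' @return A tibble `rank`, `feature`, `stability`.
#' @export
tidy.wf_voted <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Tidy a correlation report
#'
#' @param x A `wf_corr_report`.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @export
tidy.wf_corr_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Plot AUC against the number of selected features
#'
#' @param object A `wf_auc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_auc_curve <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dat[dat$k == attr(object, "best_k"), ],
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = dat$k) +
    ggplot2::labs(x = "Number of selected features (descending importance)",
                  y = "Leave-one-subject-out AUC") +
    ggplot2::theme_minimal()
}

#' Heatmap of the significant feature-outcome correlations
#'
#' Only cells that are individually significant are coloured; features and
#' outcomes with no significant-and-strong cell are dropped from the axes.
#'
#' @param object A `wf_corr_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_corr_report <- function(object, ...) {
  dat <- tidy(filter_corr_report(object))
  if (nrow(dat) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "No significant correlations") +
             ggplot2::theme_void())
  }
  dat$rho_shown <- ifelse(dat$significant, dat$rho, NA_real_)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$outcome, y = .data$feature,
                                    fill = .data$rho_shown)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey95", limits = c(-1, 1),
                                  name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = sprintf(
                    "Coloured cells: p < %.2f (per cell, uncorrected); %d tests run",
                    attr(object, "alpha"), attr(object, "n_tests"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curve of held-out predictions
#'
#' @param cv A `wf_cv_result`.
#' @return A ggplot.
#' @export
plot_roc <- function(cv) {
  m <- metrics_binary(cv$prob, cv$y)
  ggplot2::ggplot(m$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", m$auc)) +
    ggplot2::theme_minimal()
}
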