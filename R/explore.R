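# Exploratory association analysis: questionnaire deltas and the Spearman
# correlation screen between features and outcomes.

#' Derive per-period questionnaire outcome variables
#'
#' For each questionnaire and wear period, three series are derived: the
#' value recorded after the period ("after"), the change from the previous
#' assessment ("change": period 1 relative to baseline, period 2 relative
#' to period 1), and the difference from baseline ("diff_base"). PHQ-2 is
#' recorded only at baseline and after the first period, so it is passed
#' through unmodified at those two timepoints and never derived for period
#' 2. Missing operands propagate to missing derived values.
#'
#' @param outcomes Outcome tibble (see [read_outcomes()]).
#' @return A tibble with one row per (subject, period) and columns
#'   `<questionnaire>_after`, `<questionnaire>_change`,
#'   `<questionnaire>_diff_base`, plus `phq2_baseline` and `phq2_after`
#'   attached to period 1 rows.
#' @export
derive_outcomes <- function(outcomes) {
  qs <- c("mrs", "gad7", "fq_ag", "fq_soc", "fq_sp")
  wide <- outcomes |>
    tidyr::pivot_longer(dplyr::all_of(c(qs, "phq2")),
                        names_to = "questionnaire", values_to = "value") |>
    tidyr::pivot_wider(id_cols = c("subject_id", "questionnaire"),
                       names_from = "timepoint", values_from = "value")
  if (!"after_p2" %in% names(wide)) wide$after_p2 <- NA_real_

  periods <- c("p1", "p2")
  rows <- purrr::map_dfr(periods, function(p) {
    after_col <- paste0("after_", p)
    prev_col <- if (p == "p1") "baseline" else "after_p1"
    base <- wide[wide$questionnaire != "phq2", ]
    out <- tibble::tibble(
      subject_id = base$subject_id[base$questionnaire == "mrs"],
      period_id = p
    )
    for (q in qs) {
      b <- base[base$questionnaire == q, ]
      b <- b[match(out$subject_id, b$subject_id), ]
      out[[paste0(q, "_after")]] <- b[[after_col]]
      out[[paste0(q, "_change")]] <- b[[after_col]] - b[[prev_col]]
      out[[paste0(q, "_diff_base")]] <- b[[after_col]] - b$baseline
    }
    phq <- wide[wide$questionnaire == "phq2", ]
    phq <- phq[match(out$subject_id, phq$subject_id), ]
    if (p == "p1") {
      out$phq2_baseline <- phq$baseline
      out$phq2_after <- phq$after_p1
    } else {
      out$phq2_baseline <- NA_real_
      out$phq2_after <- NA_real_
    }
    out
  })
  rows
}

# Spearman rho and two-sided p via the t approximation (appropriate at the
# cohort sizes this screen targets; an exact permutation p is available for
# tiny n)
spearman_cell <- function(x, y, exact = FALSE, n_perm = 10000) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 5) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(x, y, method = "spearman")
  if (exact) {
    obs <- abs(rho)
    perm <- vapply(seq_len(n_perm), function(i) {
      abs(cor(x, sample(y), method = "spearman"))
    }, numeric(1))
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman correlation screen of features against derived outcomes
#'
#' Computes pairwise-complete Spearman correlations and two-sided p-values
#' for every (feature, outcome) pair, flagging cells as "strong" when
#' `|rho| > strong_threshold` (default 0.3) and "significant" when
#' `p < alpha` (default 0.05). No multiple-testing correction is applied --
#' the screen is exploratory -- but the total number of tests is recorded
#' so readers can correct themselves.
#'
#' @param features Feature tibble keyed by `subject_id`, `period_id`.
#' @param derived Derived outcome tibble from [derive_outcomes()].
#' @param feature_cols Feature columns to screen; default all non-key
#'   numeric columns.
#' @param strong_threshold Absolute-correlation threshold for the strong
#'   flag.
#' @param alpha Significance level.
#' @param exact Use an exact permutation p-value instead of the t
#'   approximation.
#' @return A tibble of class `wf_corr_report`: `feature`, `outcome`, `rho`,
#'   `p`, `n`, `strong`, `significant`; attribute `n_tests`.
#' @export
spearman_screen <- function(features, derived, feature_cols = NULL,
                            strong_threshold = 0.3, alpha = 0.05,
                            exact = FALSE) {
  key <- c("subject_id", "period_id")
  dat <- dplyr::inner_join(features, derived, by = key)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), key)
    feature_cols <- feature_cols[vapply(features[feature_cols], is.numeric, logical(1))]
  }
  outcome_cols <- setdiff(names(derived), key)

  grid <- tidyr::expand_grid(feature = feature_cols, outcome = outcome_cols)
  cells <- purrr::map2_dfr(grid$feature, grid$outcome, function(f, o) {
    cell <- spearman_cell(dat[[f]], dat[[o]], exact = exact)
    tibble::tibble(feature = f, outcome = o, rho = cell[["rho"]],
                   p = cell[["p"]], n = as.integer(cell[["n"]]))
  })
  cells$strong <- !is.na(cells$rho) & abs(cells$rho) > strong_threshold
  cells$significant <- !is.na(cells$p) & cells$p < alpha
  structure(cells, class = c("wf_corr_report", class(cells)),
            n_tests = sum(!is.na(cells$p)),
            strong_threshold = strong_threshold, alpha = alpha)
}

#' Filter a correlation report to its significant rows and columns
#'
#' Keeps the features and outcomes that participate in at least one cell
#' that is both significant and strong, the usual view for a correlation
#' heatmap.
#'
#' @param report A `wf_corr_report`.
#' @return The filtered report (same class).
#' @export
filter_corr_report <- function(report) {
  hits <- report$significant & report$strong
  keep_f <- unique(report$feature[hits])
  keep_o <- unique(report$outcome[hits])
  out <- report[report$feature %in% keep_f & report$outcome %in% keep_o, ]
  attributes(out)$n_tests <- attr(report, "n_tests")
  out
}
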