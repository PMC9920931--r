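# Relevance-redundancy-complementarity trade-off (RRCT) feature ranking.
#
# Greedy forward ranking: at each step the candidate maximizing
#   relevance(candidate, y) - mean redundancy(candidate, selected)
#                           + mean complementarity(candidate, selected, y)
# is appended. All three terms are built from Spearman correlations mapped
# through the standard normal quantile transform t(rho) =
# qnorm((1 + |rho|) / 2), which stretches strong correlations apart;
# complementarity uses first-order partial correlations of candidate and
# target given each already-selected feature. The scoring is isolated in
# `rrct_score_terms()` so the trade-off arithmetic can be swapped without
# touching the ranking loop.

qtrans <- function(rho) {
  rho <- abs(rho)
  rho[is.na(rho)] <- 0
  qnorm((1 + pmin(rho, 1 - 1e-12)) / 2)
}

# first-order partial Spearman correlation of x_j and y given x_s,
# from the pairwise correlations
partial_rho <- function(r_jy, r_js, r_sy) {
  den <- sqrt(pmax((1 - r_js^2) * (1 - r_sy^2), 1e-12))
  (r_jy - r_js * r_sy) / den
}

rrct_score_terms <- function(R, r_y, j, selected) {
  rel <- qtrans(r_y[j])
  if (length(selected) == 0) return(c(rel = rel, red = 0, comp = 0))
  red <- mean(qtrans(R[j, selected]))
  pc <- partial_rho(r_y[j], R[j, selected], r_y[selected])
  comp <- mean(qtrans(pc) - rel)
  c(rel = rel, red = red, comp = comp)
}

#' Rank features by relevance, redundancy and complementarity
#'
#' Greedy correlation-based ranking that rewards association with the
#' target, penalizes redundancy with already-selected features, and rewards
#' candidates whose partial correlation with the target given the selected
#' set exceeds their marginal one. Constant features receive zero relevance
#' and never block the run. Ties break toward the earlier column.
#'
#' @param x Data frame or matrix of numeric features (no missing values).
#' @param y Target vector (binary or ordinal).
#' @param m_sel Number of features to rank; default all.
#' @return Character vector of feature names in descending selection order.
#' @export
rrct_rank <- function(x, y, m_sel = ncol(x)) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (anyNA(x)) abort("Features must be complete before ranking (impute or drop first).")
  m_sel <- min(m_sel, ncol(x))
  xm <- as.matrix(x)
  suppressWarnings({
    R <- cor(xm, method = "spearman")
    r_y <- as.numeric(cor(xm, as.numeric(y), method = "spearman"))
  })
  R[is.na(R)] <- 0
  r_y[is.na(r_y)] <- 0

  p <- ncol(xm)
  selected <- integer(0)
  remaining <- seq_len(p)
  for (step in seq_len(m_sel)) {
    scores <- vapply(remaining, function(j) {
      tr <- rrct_score_terms(R, r_y, j, selected)
      tr[["rel"]] - tr[["red"]] + tr[["comp"]]
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: first index on ties
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  colnames(xm)[selected]
}

#' Per-fold feature selection under leave-one-subject-out
#'
#' Runs [rrct_rank()] once per subject with all of that subject's samples
#' held out, yielding the selection matrix the voting scheme aggregates:
#' one row per fold, columns `rank_1 .. rank_m`.
#'
#' @param x Complete feature data frame (samples in rows).
#' @param y Target vector.
#' @param subject_ids Subject of each sample; folds are subjects.
#' @param m_sel Features per row.
#' @return A tibble of class `wf_selection_matrix` with a `held_out`
#'   column and an attribute `feature_order` (the canonical column order
#'   used for tie-breaking in voting).
#' @export
loso_selection <- function(x, y, subject_ids, m_sel = 10) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 3) abort("Leave-one-subject-out needs at least 3 subjects.")
  rows <- purrr::map_dfr(subjects, function(s) {
    keep <- subject_ids != s
    if (!any(keep)) abort(sprintf("Subject '%s' owns every sample.", s))
    ranked <- rrct_rank(x[keep, , drop = FALSE], y[keep], m_sel)
    out <- tibble::as_tibble(as.list(setNames(ranked, paste0("rank_", seq_along(ranked)))))
    dplyr::bind_cols(tibble::tibble(held_out = s), out)
  })
  structure(rows, class = c("wf_selection_matrix", class(rows)),
            feature_order = colnames(x))
}

#' Aggregate per-fold rankings with the voting scheme
#'
#' For each position `i = 1..m_sel`, features are scored by how often they
#' occur anywhere in the first `i` rank columns across all folds; the
#' highest-scoring feature not yet in the final list is appended. Ties
#' break toward the feature with the lower index in the canonical column
#' order. The result is invariant to the row order of the matrix. Each
#' selected feature also gets a stability score: the percentage of folds
#' whose ranking contains it.
#'
#' @param matrix A `wf_selection_matrix` from [loso_selection()] (or any
#'   data frame of `rank_*` character columns).
#' @param m_sel Length of the final list; default the number of rank
#'   columns.
#' @param feature_order Canonical feature order for tie-breaking; defaults
#'   to the attribute stored by [loso_selection()].
#' @return A tibble of class `wf_voted`: `rank`, `feature`, `stability`
#'   (percent of folds).
#' @export
vote_features <- function(matrix, m_sel = NULL,
                          feature_order = attr(matrix, "feature_order")) {
  rank_cols <- grep("^rank_", names(matrix), value = TRUE)
  rank_cols <- rank_cols[order(as.integer(sub("rank_", "", rank_cols)))]
  if (is.null(m_sel)) m_sel <- length(rank_cols)
  m_sel <- min(m_sel, length(rank_cols))
  mat <- as.matrix(as.data.frame(matrix)[, rank_cols, drop = FALSE])
  feats <- unique(as.vector(mat))
  if (is.null(feature_order)) feature_order <- feats
  pos <- function(f) {
    p <- match(f, feature_order)
    ifelse(is.na(p), length(feature_order) + match(f, feats), p)
  }

  chosen <- character(0)
  for (i in seq_len(m_sel)) {
    counts <- table(factor(as.vector(mat[, seq_len(i), drop = FALSE]),
                           levels = feats))
    avail <- setdiff(feats, chosen)
    if (length(avail) == 0) break
    cnt <- counts[avail]
    top <- avail[cnt == max(cnt)]
    chosen <- c(chosen, top[order(pos(top))][1])
  }
  stability <- vapply(chosen, function(f) {
    100 * mean(apply(mat, 1, function(r) f %in% r))
  }, numeric(1))
  structure(
    tibble::tibble(rank = seq_along(chosen), feature = chosen,
                   stability = unname(stability)),
    class = c("wf_voted", class(tibble::tibble()))
  )
}
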