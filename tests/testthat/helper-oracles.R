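# Independent oracle implementations used to cross-check the package.
# These are deliberately literal transcriptions of the definitions and do
# not share code with the implementation under test.

# Approximate entropy by explicit double loop over template vectors:
# Chebyshev distance, self-matches included, natural log.
apen_oracle <- function(x, m, r) {
  K <- length(x)
  phi_m <- function(mm) {
    n <- K - mm + 1L
    logC <- numeric(n)
    for (i in seq_len(n)) {
      ui <- x[i:(i + mm - 1L)]
      cnt <- 0L
      for (j in seq_len(n)) {
        uj <- x[j:(j + mm - 1L)]
        if (max(abs(ui - uj)) <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / n)
    }
    mean(logC)
  }
  phi_m(m) - phi_m(m + 1L)
}

# AUC as the Mann-Whitney U statistic computed from all pairs
auc_oracle <- function(prob, y) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Voting scheme by literal transcription of the stated rule
vote_oracle <- function(mat, feature_order) {
  m_sel <- ncol(mat)
  chosen <- character(0)
  for (i in seq_len(m_sel)) {
    vals <- as.vector(mat[, seq_len(i), drop = FALSE])
    counts <- sapply(unique(as.vector(mat)), function(f) sum(vals == f))
    avail <- setdiff(names(counts), chosen)
    if (length(avail) == 0) break
    cnt <- counts[avail]
    winners <- avail[cnt == max(cnt)]
    chosen <- c(chosen, winners[order(match(winners, feature_order))][1])
  }
  chosen
}

# Spearman rho as rank-transform followed by the textbook Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Pearson correlation by the textbook formula
pearson_oracle <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}
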