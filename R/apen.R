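#' Approximate entropy of a numeric series
#'
#' Regularity statistic ApEn(m, r, K) for a time series `x` of length K:
#' embed the series in vectors of length `m`, count for each template the
#' fraction of vectors within Chebyshev distance `r` (the template itself
#' counts as a match, so the count is never zero and the logarithm is always
#' defined), average the natural logs of those fractions to get `phi_m`, and
#' return `phi_m - phi_(m+1)`. Low values indicate a predictable series,
#' higher values an irregular one.
#'
#' With `r_mode = "relative"` the tolerance is `r_coeff * sd(x)` (sample
#' standard deviation); a constant series then has zero tolerance-relative
#' structure and ApEn is defined as 0.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Embedding dimension (window length of the template vectors).
#' @param r Tolerance. Interpreted according to `r_mode`.
#' @param r_mode Either `"relative"` (tolerance is the product of `r` and
#'   `sd(x)`, the conventional parameterization, default 0.2) or
#'   `"absolute"`.
#'
#' @return A single non-negative number.
#' @export
#' @examples
#' set.seed(1)
#' apen(sin(seq(0, 6 * pi, length.out = 100)))   # regular: small
#' apen(runif(100))                              # irregular: larger
apen <- function(x, m = 2, r = 0.2, r_mode = c("relative", "absolute")) {
  r_mode <- match.arg(r_mode)
  x <- as.numeric(x)
  if (anyNA(x)) abort("`x` must not contain missing values.")
  K <- length(x)
  if (K < m + 2) {
    abort(sprintf("ApEn undefined: series length %d < m + 2 = %d.", K, m + 2))
  }
  if (r_mode == "relative") {
    s <- sd(x)
    if (s == 0) return(0)
    r <- r * s
  }
  phi(x, m, r) - phi(x, m + 1, r)
}

# phi_m(r): mean over templates of log of the fraction of templates within
# Chebyshev distance r. Computed by accumulating, for each of the m lags, the
# pairwise "within r" indicator; memory O(n^2) with n = K - m + 1, which is
# ample at the quarter-hour series lengths this package works with.
phi <- function(x, m, r) {
  K <- length(x)
  n <- K - m + 1L
  within <- matrix(TRUE, n, n)
  for (l in seq_len(m)) {
    xl <- x[l:(l + n - 1L)]
    within <- within & (abs(outer(xl, xl, "-")) <= r)
  }
  mean(log(rowSums(within) / n))
}

#' Length-normalized approximate entropy
#'
#' `apen(x) / length(x)`: dividing by the number of points avoids
#' systematically higher entropies for longer sleep periods, so values are
#' comparable across nights of different duration.
#'
#' @inheritParams apen
#' @return A single non-negative number.
#' @export
apen_normalized <- function(x, m = 2, r = 0.2, r_mode = c("relative", "absolute")) {
  apen(x, m, r, r_mode) / length(x)
}
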