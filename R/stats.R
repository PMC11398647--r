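#' Paired surrogate rank-order test
#'
#' Nonparametric significance test for a paired difference: the observed
#' statistic is the mean of the pairwise differences, and the null
#' distribution is built by randomly flipping the sign of each pair's
#' difference (exchanging the two labels within a pair) and recomputing the
#' mean, repeated `n_surrogates` times.  Significance is the percentile rank
#' of the observed value in this surrogate distribution; the two-sided p uses
#' the absolute values with the +1 finite-sample correction.
#'
#' @param a,b paired numeric vectors of equal length (paired by test-run
#'   index).
#' @param n_surrogates number of sign-flip surrogates (default 5000).
#' @param seed RNG seed for the surrogate draws.
#' @return a `surrogate_test` list: `observed_diff`, `percentile_rank`
#'   (one-sided upper rank of the signed statistic), `p_raw` (two-sided),
#'   `n_surrogates`, `n_pairs`, `seed`.
#' @export
paired_surrogate_test <- function(a, b, n_surrogates = 5000, seed = 1) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  obs <- mean(d)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_surrogates * n, replace = TRUE),
                  nrow = n_surrogates)
  surr <- as.numeric(signs %*% d) / n
  p_raw <- (1 + sum(abs(surr) >= abs(obs))) / (n_surrogates + 1)
  pr <- (1 + sum(surr >= obs)) / (n_surrogates + 1)
  structure(list(observed_diff = obs, percentile_rank = pr, p_raw = p_raw,
                 n_surrogates = n_surrogates, n_pairs = n, seed = seed),
            class = "surrogate_test")
}

#' Bonferroni adjustment
#'
#' @param p_raw raw p-value(s).
#' @param m_comparisons number of comparisons in the family (spectral-radius
#'   levels times stimulus-type comparisons).
#' @return min(1, m * p), vectorized over `p_raw`.
#' @export
bonferroni_adjust <- function(p_raw, m_comparisons) {
  stopifnot(m_comparisons >= 1)
  pmin(1, m_comparisons * p_raw)
}
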