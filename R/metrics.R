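#' Consistency and prediction-error metrics
#'
#' Selective consistency is quantified by the Pearson correlation between the
#' onsets of the two 500 ms segments of a response series (inter-segment
#' correlation) and by the mean pairwise correlation across trials
#' (inter-trial consistency).  Prediction accuracy is summarized by per-time
#' RMSE across trials and an NRMSE normalized by the grand-mean RMSE of the
#' four Hebbian/non-Hebbian x RN/RefRN conditions.
#'
#' @name metrics
NULL

#' Inter-segment correlation of one response series
#'
#' Pearson correlation between the first `window` points of segment 1
#' (indices 1..window) and of segment 2 (indices 1001..1000+window for the
#' default 2000-point series); the window covers the first 100 ms of each
#' 500 ms segment at 2 kHz.  An optional offset shifts both windows past the
#' onset transient for sensitivity checks.
#'
#' @param series numeric response series (length >= segment + window).
#' @param window window length in samples (default 200).
#' @param segment segment length in samples (default 1000).
#' @param offset shift of both windows from the segment onsets (default 0).
#' @return Pearson r, or NA (with attribute `undefined = TRUE`) when either
#'   window has zero variance.
#' @export
inter_segment_correlation <- function(series, window = 200, segment = 1000,
                                      offset = 0) {
  stopifnot(length(series) >= segment + offset + window)
  w1 <- series[(offset + 1):(offset + window)]
  w2 <- series[(segment + offset + 1):(segment + offset + window)]
  if (sd(w1) == 0 || sd(w2) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  cor(w1, w2)
}

#' Inter-trial consistency of a set of response series
#'
#' Mean Pearson correlation over all unordered pairs of series, computed on a
#' fixed window at the start of segment 1 (matching the inter-segment window).
#' Pairs with zero variance are excluded and counted.
#'
#' @param series_list list of M >= 2 numeric series of equal length.
#' @param window window length (default 200).
#' @param offset window offset from the series start (default 0).
#' @return mean pairwise r; attribute `n_undefined` counts excluded pairs.
#' @export
inter_trial_consistency <- function(series_list, window = 200, offset = 0) {
  M <- length(series_list)
  stopifnot(M >= 2)
  wins <- vapply(series_list,
                 function(s) s[(offset + 1):(offset + window)],
                 numeric(window))
  ok <- apply(wins, 2, sd) > 0
  n_undef_series <- sum(!ok)
  if (sum(ok) < 2) {
    return(structure(NA_real_, undefined = TRUE,
                     n_undefined = M * (M - 1) / 2))
  }
  cm <- cor(wins[, ok, drop = FALSE])
  vals <- cm[upper.tri(cm)]
  n_excluded <- M * (M - 1) / 2 - length(vals)
  structure(mean(vals), n_undefined = n_excluded)
}

#' Per-time-point RMSE across trials
#'
#' @param outputs M x K matrix of model outputs (trials in rows).
#' @param targets M x K matrix of matching targets.
#' @return length-K series sqrt(mean over trials of squared residual).
#' @export
rmse_series <- function(outputs, targets) {
  if (!all(dim(outputs) == dim(targets))) stop("shape mismatch")
  sqrt(colMeans((targets - outputs)^2))
}

#' Normalized RMSE across the four plasticity-by-stimulus conditions
#'
#' Divides each condition's RMSE series by the grand mean RMSE over time and
#' the four conditions (Hebbian/non-Hebbian x RN/RefRN), so the normalized
#' series are comparable across spectral radii despite the growth of output
#' scale with radius.  The grand mean of the result is exactly 1.
#'
#' @param rmse_by_condition named list of 4 equal-length RMSE series.
#' @return named list of NRMSE series.
#' @export
nrmse_series <- function(rmse_by_condition) {
  stopifnot(length(rmse_by_condition) == 4)
  lens <- vapply(rmse_by_condition, length, 1L)
  stopifnot(length(unique(lens)) == 1)
  denom <- mean(unlist(rmse_by_condition))
  if (denom == 0) {
    return(structure(lapply(rmse_by_condition, function(x) x * NA_real_),
                     undefined = TRUE))
  }
  lapply(rmse_by_condition, function(x) x / denom)
}
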