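# Accumulation-pattern WIPAB metrics, computed from per-intensity bout
# duration lists: power-law exponent alpha, proportion of time in long
# bouts, and the Gini index of bout lengths.

#' Power-law exponent alpha of bout durations
#'
#' Continuous maximum-likelihood estimate of the exponent of the
#' bout-duration distribution,
#' `alpha = 1 + n / sum(log(x / xmin))` with `xmin` the shortest observed
#' bout. Higher alpha means activity accumulated in proportionally more
#' short bouts. Following the convention that the estimate is only
#' meaningful with some spread, the result is missing unless at least
#' `min_distinct` distinct durations are present.
#'
#' @param durations bout durations in minutes.
#' @param min_distinct minimum number of distinct duration values.
#' @return Alpha (dimensionless, > 1) or `NA`.
#' @export
power_law_exponent <- function(durations, min_distinct = 3) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0) return(NA_real_)
  if (length(unique(durations)) < min_distinct) return(NA_real_)
  xmin <- min(durations)
  s <- sum(log(durations / xmin))
  if (s <= 0) return(NA_real_)
  1 + length(durations) / s
}

#' Proportion of time accumulated in bouts longer than a threshold
#'
#' `100 * sum(durations > threshold) / sum(durations)` with a strictly-
#' greater comparison. The conventional thresholds are 60 min for sedentary
#' behaviour and 10 min for MVPA.
#'
#' @param durations bout durations in minutes.
#' @param threshold_min bout-length threshold in minutes.
#' @return Percentage in `[0, 100]`, or `NA` when total time is zero.
#' @export
proportion_long_bouts <- function(durations, threshold_min) {
  durations <- durations[!is.na(durations)]
  total <- sum(durations)
  if (!length(durations) || total <= 0) return(NA_real_)
  100 * sum(durations[durations > threshold_min]) / total
}

#' Gini index of bout durations
#'
#' Mean absolute difference between all pairs of bout lengths relative to
#' twice the mean, `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`, without a
#' small-sample correction. 0 means all bouts equal; values near 1 mean
#' time concentrated in a few long bouts.
#'
#' @param durations bout durations in minutes.
#' @return Gini index in `[0, 1)`; `NA` on empty input; 0 for a single bout.
#' @export
gini_index <- function(durations) {
  durations <- durations[!is.na(durations)]
  n <- length(durations)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  x <- sort(durations)
  # O(n log n) form of the pairwise-difference definition
  g <- 2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  max(0, g)
}

#' All accumulation metrics from a bout list
#'
#' @param bouts a `bout_list` from [find_bouts()].
#' @param sb_threshold_min,mvpa_threshold_min long-bout thresholds.
#' @return Tibble with `ple_alpha_sb`, `ple_alpha_mvpa`, `prop_sb_gt60`,
#'   `prop_mvpa_gt10`, `gini_sb`.
#' @export
accumulation_metrics <- function(bouts, sb_threshold_min = 60,
                                 mvpa_threshold_min = 10) {
  sb <- bout_durations(bouts, "SB")
  mvpa <- bout_durations(bouts, "MVPA")
  tibble::tibble(
    ple_alpha_sb = power_law_exponent(sb),
    ple_alpha_mvpa = power_law_exponent(mvpa),
    prop_sb_gt60 = proportion_long_bouts(sb, sb_threshold_min),
    prop_mvpa_gt10 = proportion_long_bouts(mvpa, mvpa_threshold_min),
    gini_sb = gini_index(sb))
}
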