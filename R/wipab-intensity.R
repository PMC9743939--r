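# Intensity-distribution WIPAB metrics: the intensity gradient (slope of
# log time vs log intensity across 25 milli-g bins) and the MX metrics (the
# acceleration above which the most active x minutes of the day are
# accumulated).

#' Build the daily intensity histogram
#'
#' Time per 25 milli-g intensity bin (0--25, 25--50, ..., 3975--4000,
#' >4000), in minutes per day averaged over the valid days. By default the
#' histogram covers the full 24 h including sleep; `awake_only = TRUE`
#' restricts it to non-sleep epochs (sleep-time minutes then drop out of the
#' 1440-minute budget).
#'
#' @param series an [epoch_series()].
#' @param valid_days integer day indices to include.
#' @param awake_only drop epochs labelled SLEEP in `iseries`.
#' @param iseries optional `intensity_series`, required when
#'   `awake_only = TRUE`.
#' @param bin_width bin width in milli-g.
#' @param top upper edge of the last finite bin, milli-g.
#' @return Tibble with columns `lo`, `hi`, `mid` (bin midpoint; `NA` for
#'   the open top bin) and `minutes` (per day).
#' @export
intensity_histogram <- function(series, valid_days, awake_only = FALSE,
                                iseries = NULL, bin_width = 25, top = 4000) {
  di <- day_index(series$time)
  sel <- di %in% valid_days
  if (awake_only) {
    if (is.null(iseries)) {
      stop("awake_only histogram needs the intensity series", call. = FALSE)
    }
    sel <- sel & iseries$labels != "SLEEP"
  }
  x <- series$enmo[sel]
  n_days <- length(unique(di[sel]))
  edges <- seq(0, top, by = bin_width)
  bin <- findInterval(x, edges, rightmost.closed = FALSE)  # 1..161
  bin <- pmin(bin, length(edges))                          # >top collapses
  counts <- tabulate(bin, nbins = length(edges))
  minutes <- counts * series$epoch_len / 60 / max(1, n_days)
  tibble::tibble(
    lo = edges,
    hi = c(edges[-1], Inf),
    mid = c(edges[-1] - bin_width / 2, NA_real_),
    minutes = minutes)
}

#' Intensity gradient
#'
#' The OLS slope of `ln(minutes per bin)` on `ln(bin midpoint)` across the
#' intensity histogram, describing how steeply accumulated time drops as
#' intensity increases. Empty bins and the open-ended top bin (no finite
#' midpoint) are omitted. A more negative gradient means a steeper drop;
#' shallower (less negative) gradients indicate time spread across the
#' whole intensity range.
#'
#' @param hist tibble from [intensity_histogram()].
#' @return List with `gradient`, `intercept`, `r_squared`; all `NA` (with a
#'   message) when fewer than two non-empty finite bins exist.
#' @export
intensity_gradient <- function(hist) {
  use <- hist$minutes > 0 & !is.na(hist$mid)
  if (sum(use) < 2) {
    message("intensity gradient undefined: fewer than two non-empty bins")
    return(list(gradient = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  lx <- log(hist$mid[use])
  ly <- log(hist$minutes[use])
  fit <- lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(gradient = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' MX metric
#'
#' The acceleration above which the most active `window_min` minutes of the
#' day are accumulated: per day this is the k-th largest epoch ENMO with
#' `k = window_min * 60 / epoch_len`; the metric is the mean of the daily
#' values over the valid days. `M8` uses an 8-h window (480 min) and
#' `M0.25` a 15-min window.
#'
#' @param series an [epoch_series()].
#' @param window_min window length in minutes (must be at least one epoch
#'   and below 24 h).
#' @param valid_days integer day indices to include.
#' @return Acceleration in milli-g (mean over valid days); `NA` if no valid
#'   day holds enough epochs.
#' @export
mx_metric <- function(series, window_min, valid_days) {
  el <- series$epoch_len
  if (window_min * 60 < el) stop("window shorter than one epoch", call. = FALSE)
  if (window_min >= 1440) stop("window must be below 24 h", call. = FALSE)
  k <- round(window_min * 60 / el)
  di <- day_index(series$time)
  vals <- vapply(valid_days, function(d) {
    x <- series$enmo[di == d]
    if (length(x) < k) return(NA_real_)
    sort(x, decreasing = TRUE)[k]
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}
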