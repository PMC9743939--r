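# Bout detection: maximal runs of identical intensity labels over awake
# time. Sleep interrupts runs; kept naps are analysable time and carry
# their ENMO-based labels.

#' Identify intensity bouts in a labelled series
#'
#' The default, strict mode turns every maximal run of identical non-sleep,
#' non-wear labels into one bout (a 100% criterion). A tolerance-based mode
#' is also exposed: a bout of a given intensity may absorb interruptions of
#' up to `max_gap_min` minutes as long as the fraction of in-intensity
#' epochs stays at or above `tolerance`; this mirrors the tolerant bout
#' definitions used by common accelerometry pipelines, whose exact
#' parameters vary between studies.
#'
#' @param iseries an `intensity_series` from [classify_intensity()].
#' @param mode `"strict"` (default) or `"tolerant"`.
#' @param tolerance minimum fraction of epochs at the bout's intensity
#'   (tolerant mode).
#' @param max_gap_min longest permissible single interruption, minutes
#'   (tolerant mode).
#' @return A `bout_list`: tibble with columns `intensity`, `start`
#'   (seconds), `duration_min`, plus attribute `total_time` (named minutes
#'   per intensity). Empty waking period gives zero rows.
#' @export
find_bouts <- function(iseries, mode = c("strict", "tolerant"),
                       tolerance = 0.8, max_gap_min = 1) {
  mode <- match.arg(mode)
  lab <- as.character(iseries$labels)
  awake <- !(lab %in% c("SLEEP", "NONWEAR"))
  el <- iseries$epoch_len
  segments <- true_runs(awake)
  rows <- list()
  for (s in seq_len(nrow(segments))) {
    idx <- segments$start[s]:segments$end[s]
    l <- lab[idx]
    if (mode == "strict") {
      r <- rle(l)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        intensity = r$values,
        start = iseries$time[idx[starts]],
        duration_min = r$lengths * el / 60)
    } else {
      rows[[length(rows) + 1]] <- tolerant_bouts(l, iseries$time[idx], el,
                                                 tolerance, max_gap_min)
    }
  }
  bouts <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(intensity = character(0), start = numeric(0),
                   duration_min = numeric(0))
  tot <- tapply(bouts$duration_min, bouts$intensity, sum)
  structure(bouts, total_time = tot, class = c("bout_list", class(bouts)))
}

# Greedy tolerant bouting within one awake segment: a bout keeps extending
# while every interruption is <= max_gap epochs and the in-intensity
# fraction stays >= tolerance.
tolerant_bouts <- function(l, time, el, tolerance, max_gap_min) {
  max_gap <- max(1L, round(max_gap_min * 60 / el))
  n <- length(l)
  out_int <- character(0); out_start <- numeric(0); out_len <- integer(0)
  i <- 1L
  while (i <= n) {
    target <- l[i]
    j <- i
    in_cnt <- 0L
    last_in <- i - 1L
    gap <- 0L
    best_end <- i
    while (j <= n) {
      if (l[j] == target) {
        in_cnt <- in_cnt + 1L
        gap <- 0L
        if (in_cnt / (j - i + 1L) >= tolerance) best_end <- j
        last_in <- j
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
      }
      j <- j + 1L
    }
    out_int <- c(out_int, target)
    out_start <- c(out_start, time[i])
    out_len <- c(out_len, best_end - i + 1L)
    i <- best_end + 1L
  }
  tibble::tibble(intensity = out_int, start = out_start,
                 duration_min = out_len * el / 60)
}

#' Bout durations for one intensity
#'
#' @param bouts a `bout_list`.
#' @param intensity one of `"SB"`, `"LPA"`, `"MVPA"`.
#' @return Numeric vector of durations in minutes.
#' @export
bout_durations <- function(bouts, intensity) {
  bouts$duration_min[bouts$intensity == intensity]
}
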