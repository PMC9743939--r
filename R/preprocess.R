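# Screening and labelling of epoch series: half-day trimming, valid-day
# rules, a simplified main-sleep detector, and intensity classification
# using wrist ENMO cut-points.

#' Trim incomplete half-days from an epoch series
#'
#' Because device start times differ, the first and last half-days of wear
#' are discarded: the returned series starts at the first midnight and ends
#' at the last midnight inside the recording. At most six complete days are
#' retained (the earliest six when more are present).
#'
#' @param series an [epoch_series()].
#' @param max_days maximum number of complete days to keep.
#' @return An [epoch_series()] covering whole calendar days. When no
#'   complete day remains the returned series has zero epochs and attribute
#'   `empty = TRUE` (no error is thrown).
#' @export
trim_half_days <- function(series, max_days = 6) {
  n <- length(series)
  if (n == 0) {
    attr(series, "empty") <- TRUE
    return(series)
  }
  t0 <- series$time[1]
  t1 <- series$time[n] + series$epoch_len
  first_mid <- ceiling(t0 / 86400) * 86400
  last_mid <- floor(t1 / 86400) * 86400
  n_days <- max(0, (last_mid - first_mid) / 86400)
  if (n_days < 1) {
    out <- slice_series(series, integer(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  keep_days <- min(n_days, max_days)
  end <- first_mid + keep_days * 86400
  idx <- which(series$time >= first_mid & series$time < end)
  slice_series(series, idx)
}

#' Assess wear-time validity of a trimmed series
#'
#' A calendar (midnight-to-midnight) day is valid when it holds at least
#' `min_wear_h` hours of wear. A participant is included when the file's
#' post-calibration error is at most `max_calibration_mg`, at least
#' `min_valid_days` days are valid, and at least one valid day falls on a
#' Saturday or Sunday.
#'
#' @param series a trimmed [epoch_series()].
#' @param min_wear_h minimum wear hours for a valid day.
#' @param min_valid_days minimum number of valid days.
#' @param max_calibration_mg maximum tolerated post-calibration error.
#' @return A `validity_report`: list with `n_valid_days`,
#'   `has_weekend_day`, `included`, `exclusion_reason`
#'   (`"calibration"`, `"wear_time"` or `"none"`) and `valid_days`
#'   (0-based calendar-day indices).
#' @export
assess_validity <- function(series, min_wear_h = 10, min_valid_days = 4,
                            max_calibration_mg = 10) {
  if (length(series) == 0) {
    return(structure(list(n_valid_days = 0L, has_weekend_day = FALSE,
                          included = FALSE, exclusion_reason = "wear_time",
                          valid_days = integer(0)),
                     class = "validity_report"))
  }
  di <- day_index(series$time)
  wear_h <- tapply(series$wear, di, sum) * series$epoch_len / 3600
  days <- as.integer(names(wear_h))
  valid <- days[wear_h >= min_wear_h]
  dow <- ((series$start_dow - 1 + valid) %% 7) + 1
  has_weekend <- any(dow >= 6)
  calib_ok <- series$calibration_error <= max_calibration_mg
  included <- calib_ok && length(valid) >= min_valid_days && has_weekend
  reason <- if (!calib_ok) "calibration"
            else if (!included) "wear_time"
            else "none"
  structure(list(n_valid_days = length(valid),
                 has_weekend_day = has_weekend,
                 included = included,
                 exclusion_reason = reason,
                 valid_days = valid),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report: %d valid days, weekend=%s, included=%s (%s)>\n",
              x$n_valid_days, x$has_weekend_day, x$included,
              x$exclusion_reason))
  invisible(x)
}

#' Detect the main nightly sleep window
#'
#' A simplified heuristic detector (a stand-in for full z-angle-based sleep
#' algorithms): per noon-to-noon period, the rolling `roll_min`-minute mean
#' activity is compared to an adaptive threshold (the period's 10th
#' percentile plus `margin_mg`), and the longest stretch of at least
#' `min_duration_min` consecutive sub-threshold minutes inside the
#' `search_start`--`search_end` clock window becomes the main sleep window.
#' Candidate windows *starting* between `nap_start` and `nap_end` are
#' treated as daytime naps and kept as analysable waking time.
#'
#' @param series an [epoch_series()] spanning at least one complete day.
#' @param ground_truth optional tibble with columns `onset`, `wake`
#'   (clock times); when supplied (e.g. from the generator's planted truth)
#'   it is expanded to windows directly, bypassing detection.
#' @param roll_min rolling-mean width in minutes.
#' @param margin_mg margin added to the adaptive threshold, milli-g.
#' @param max_threshold_mg absolute cap on the adaptive threshold, milli-g;
#'   prevents a uniformly active day from being read as sleep.
#' @param min_duration_min minimum sleep-window duration in minutes.
#' @param search_start,search_end clock bounds of the nightly search window.
#' @param nap_start,nap_end clock bounds inside which a window onset marks a
#'   kept nap rather than main sleep.
#' @return Tibble of sleep windows with columns `start`, `end` (seconds on
#'   the series clock) and `duration_h`. Zero rows (with a warning) when no
#'   qualifying window exists.
#' @export
detect_sleep <- function(series, ground_truth = NULL,
                         roll_min = 5, margin_mg = 5,
                         max_threshold_mg = 20,
                         min_duration_min = 30,
                         search_start = "21:00", search_end = "11:00",
                         nap_start = "10:00", nap_end = "18:00") {
  el <- series$epoch_len
  n <- length(series)
  if (n == 0) return(tibble::tibble(start = numeric(0), end = numeric(0),
                                    duration_h = numeric(0)))
  if (!is.null(ground_truth)) {
    onset <- parse_clock(ground_truth$onset[1])
    wake <- parse_clock(ground_truth$wake[1])
    sod <- secs_of_day(series$time)
    mask <- nightly_sleep_mask(sod, onset, wake)
    runs <- true_runs(mask)
    return(tibble::tibble(
      start = series$time[runs$start],
      end = series$time[runs$end] + el,
      duration_h = (runs$end - runs$start + 1) * el / 3600))
  }

  k <- max(1L, round(roll_min * 60 / el))
  roll <- as.numeric(stats::filter(series$enmo, rep(1 / k, k), sides = 2))
  roll[is.na(roll)] <- series$enmo[is.na(roll)]
  sod <- secs_of_day(series$time)
  s_start <- parse_clock(search_start)
  s_end <- parse_clock(search_end)
  in_search <- if (s_start > s_end) sod >= s_start | sod < s_end
               else sod >= s_start & sod < s_end
  np_s <- parse_clock(nap_start)
  np_e <- parse_clock(nap_end)

  # noon-to-noon period index
  period <- floor((series$time - 43200) / 86400)
  out <- list()
  for (p in unique(period)) {
    sel <- which(period == p)
    thr <- min(quantile(roll[sel], 0.10, na.rm = TRUE) + margin_mg,
               max_threshold_mg)
    low <- roll[sel] < thr & in_search[sel]
    runs <- true_runs(low)
    if (nrow(runs) == 0) next
    runs$len <- runs$end - runs$start + 1
    runs <- runs[runs$len * el >= min_duration_min * 60, , drop = FALSE]
    if (nrow(runs) == 0) next
    # drop nap-onset candidates
    onset_sod <- sod[sel[runs$start]]
    runs <- runs[!(onset_sod >= np_s & onset_sod < np_e), , drop = FALSE]
    if (nrow(runs) == 0) next
    best <- runs[which.max(runs$len), ]
    out[[length(out) + 1]] <- tibble::tibble(
      start = series$time[sel[best$start]],
      end = series$time[sel[best$end]] + el,
      duration_h = best$len * el / 3600)
  }
  if (length(out) == 0) {
    warning("no main sleep window found; returning zero windows",
            call. = FALSE)
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          duration_h = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Classify epoch intensity
#'
#' Applies wrist ENMO cut-points (44.8 and 100.6 milli-g separating
#' sedentary behaviour, light and moderate-to-vigorous activity) to every
#' epoch; epochs inside a main sleep window are labelled `SLEEP` and
#' non-wear epochs `NONWEAR`. The boundary convention is lower-bound
#' inclusive on the upper class: an epoch exactly at a cut-point takes the
#' higher intensity.
#'
#' @param series an [epoch_series()].
#' @param sleep_windows tibble from [detect_sleep()] (may have zero rows).
#' @param cut_points numeric `c(sb_lpa, lpa_mvpa)` in milli-g, strictly
#'   increasing.
#' @return An `intensity_series`: list with `labels` (factor with levels
#'   SB, LPA, MVPA, SLEEP, NONWEAR), `time`, `epoch_len`, `enmo`,
#'   `cut_points`.
#' @export
classify_intensity <- function(series, sleep_windows = NULL,
                               cut_points = c(sb_lpa = 44.8, lpa_mvpa = 100.6)) {
  if (cut_points[1] >= cut_points[2]) {
    stop_config("cut_points", "must be strictly increasing")
  }
  lab <- ifelse(series$enmo >= cut_points[2], "MVPA",
         ifelse(series$enmo >= cut_points[1], "LPA", "SB"))
  if (!is.null(sleep_windows) && nrow(sleep_windows) > 0) {
    for (i in seq_len(nrow(sleep_windows))) {
      inside <- series$time >= sleep_windows$start[i] &
                series$time < sleep_windows$end[i]
      lab[inside] <- "SLEEP"
    }
  }
  lab[!series$wear & lab != "SLEEP"] <- "NONWEAR"
  structure(list(
    labels = factor(lab, levels = c("SB", "LPA", "MVPA", "SLEEP", "NONWEAR")),
    time = series$time, epoch_len = series$epoch_len, enmo = series$enmo,
    cut_points = cut_points),
    class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  tb <- table(x$labels)
  cat("<intensity_series: ",
      paste(sprintf("%s=%d", names(tb), tb), collapse = " "), ">\n", sep = "")
  invisible(x)
}

#' Conventional physical-activity variables
#'
#' Daily hours of sedentary behaviour and MVPA (awake time only) and the
#' 24-h average acceleration (sleep included, as a volume metric), each
#' averaged over the valid days. Order of days does not matter.
#'
#' @param iseries an `intensity_series` from [classify_intensity()].
#' @param valid_days integer day indices (from [assess_validity()]).
#' @return Tibble with columns `time_sb`, `time_mvpa`, `mean_enmo`.
#' @export
conventional_variables <- function(iseries, valid_days) {
  di <- day_index(iseries$time)
  sel <- di %in% valid_days
  if (!any(sel)) {
    return(tibble::tibble(time_sb = NA_real_, time_mvpa = NA_real_,
                          mean_enmo = NA_real_))
  }
  el_h <- iseries$epoch_len / 3600
  lab <- iseries$labels[sel]
  dsel <- di[sel]
  per_day_h <- function(which_lab) {
    cnt <- tapply(lab == which_lab, dsel, sum)
    mean(cnt * el_h)
  }
  tibble::tibble(
    time_sb = per_day_h("SB"),
    time_mvpa = per_day_h("MVPA"),
    mean_enmo = mean(tapply(iseries$enmo[sel], dsel, mean)))
}
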