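# Per-participant feature extraction: runs screening, sleep masking,
# intensity classification and bout detection, then assembles the 3
# conventional + WIPAB metrics into one profile row.

#' Compute the full feature profile of one participant
#'
#' Runs the whole per-participant pipeline on an epoch series: half-day
#' trimming, valid-day screening, main-sleep detection, intensity
#' classification, bout detection, and all conventional and WIPAB metrics.
#' Day-based metrics (conventional variables, intensity histogram, MX)
#' average over valid days; bout-based metrics pool bouts over awake time
#' of valid days; DFA and the 24-h autocorrelation use the full trimmed
#' 24-h series, since their time scales span hours; sample entropy and
#' symbolic dynamics use the awake ENMO sequence; Lempel-Ziv complexity
#' uses the awake PA-state symbol sequence.
#'
#' @param series an [epoch_series()].
#' @param cut_points intensity cut-points, milli-g.
#' @param dfa_cfg a [dfa_config()] (epoch length is aligned automatically).
#' @param sampen_cfg a [sampen_config()].
#' @param symbolic_cfg a [symbolic_config()].
#' @param alphabet PA-state map for [symbolize_states()].
#' @param bout_mode `"strict"` or `"tolerant"` (see [find_bouts()]).
#' @param use_truth_sleep when `TRUE` and the series carries generator
#'   truth, planted sleep windows are used instead of the detector.
#' @param awake_only_hist restrict the intensity histogram to awake time.
#' @param max_days days retained by [trim_half_days()].
#' @return One-row tibble: `id`, `included`, `exclusion_reason`,
#'   `n_valid_days`, `sleep_duration`, then the [wipab_features()] columns
#'   (all `NA` when the participant is excluded).
#' @export
wipab_profile <- function(series,
                          cut_points = c(sb_lpa = 44.8, lpa_mvpa = 100.6),
                          dfa_cfg = dfa_config(),
                          sampen_cfg = sampen_config(),
                          symbolic_cfg = symbolic_config(),
                          alphabet = state_alphabet(),
                          bout_mode = "strict",
                          use_truth_sleep = FALSE,
                          awake_only_hist = FALSE,
                          max_days = 6) {
  trimmed <- trim_half_days(series, max_days = max_days)
  validity <- assess_validity(trimmed)
  base <- tibble::tibble(
    id = series$id,
    included = validity$included,
    exclusion_reason = validity$exclusion_reason,
    n_valid_days = validity$n_valid_days)
  na_feats <- tibble::as_tibble(
    setNames(as.list(rep(NA_real_, length(wipab_features()))),
             wipab_features()))
  if (!validity$included) {
    return(dplyr::bind_cols(base, tibble::tibble(sleep_duration = NA_real_),
                            na_feats))
  }

  truth <- attr(series, "truth")
  gt <- if (use_truth_sleep && !is.null(truth)) {
    tibble::tibble(onset = truth$sleep_onset, wake = truth$wake)
  } else NULL
  sleep <- detect_sleep(trimmed, ground_truth = gt)
  iseries <- classify_intensity(trimmed, sleep, cut_points = cut_points)
  vdays <- validity$valid_days

  conv <- conventional_variables(iseries, vdays)
  hist <- intensity_histogram(trimmed, vdays, awake_only = awake_only_hist,
                              iseries = iseries)
  ig <- intensity_gradient(hist)

  # bout metrics over awake time of valid days
  di <- day_index(iseries$time)
  ival <- iseries
  drop <- !(di %in% vdays)
  ival$labels[drop] <- "NONWEAR"  # excluded from bouting
  bouts <- find_bouts(ival, mode = bout_mode)
  acc <- accumulation_metrics(bouts)

  dfa_cfg$epoch_len <- trimmed$epoch_len
  dfa <- dfa_alpha(trimmed$enmo, dfa_cfg)
  acf24 <- autocorrelation_lag(trimmed$enmo, 86400 / trimmed$epoch_len)

  awake <- !(as.character(iseries$labels) %in% c("SLEEP", "NONWEAR"))
  awake_enmo <- trimmed$enmo[awake]
  sampen <- if (length(awake_enmo) > sampen_cfg$m + 1) {
    sample_entropy(awake_enmo, sampen_cfg)
  } else NA_real_
  s2uv <- if (length(awake_enmo) >= 3) {
    symbolic_2uv(awake_enmo, symbolic_cfg)
  } else NA_real_
  states <- symbolize_states(ival, bouts, alphabet)
  lzc <- if (length(states) >= 2) {
    lempel_ziv(states, alphabet_size = nrow(alphabet))$lzc
  } else NA_real_

  n_days <- length(trimmed) * trimmed$epoch_len / 86400
  sleep_h <- if (nrow(sleep) > 0) sum(sleep$duration_h) / n_days else 0

  dplyr::bind_cols(
    base,
    tibble::tibble(sleep_duration = sleep_h),
    conv,
    tibble::tibble(
      intensity_gradient = ig$gradient,
      m8 = mx_metric(trimmed, 480, vdays),
      m0_25 = mx_metric(trimmed, 15, vdays)),
    acc,
    tibble::tibble(
      dfa_alpha_short = dfa$alpha_short,
      dfa_alpha_long = dfa$alpha_long,
      acf_24h = acf24,
      lzc = lzc,
      sampen = sampen,
      sym_2uv = s2uv))
}

#' Feature profiles for a signal-mode cohort
#'
#' Applies [wipab_profile()] to every participant's series and joins the
#' feature columns onto the cohort record table.
#'
#' @param cohort tibble from [generate_cohort()] with a `series` column, or
#'   a list of [epoch_series()].
#' @param ... passed to [wipab_profile()].
#' @return Tibble of profiles (one row per participant) when given a list;
#'   the cohort joined with profile columns when given a cohort tibble.
#' @export
profile_cohort <- function(cohort, ...) {
  if (is.data.frame(cohort)) {
    if (is.null(cohort$series)) {
      stop("cohort has no 'series' column; was it generated in signal mode?",
           call. = FALSE)
    }
    profs <- purrr::map(cohort$series, wipab_profile, ...)
    profs <- dplyr::bind_rows(profs)
    profs$id <- cohort$id
    out <- dplyr::left_join(dplyr::select(cohort, -dplyr::any_of("series")),
                            profs, by = "id")
    attr(out, "truth") <- attr(cohort, "truth")
    out
  } else {
    dplyr::bind_rows(purrr::map(cohort, wipab_profile, ...))
  }
}
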