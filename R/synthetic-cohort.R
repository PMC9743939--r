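# Synthetic cohort with planted feature->outcome effects. Stands in for a
# request-only observational cohort so the modelling machinery (imputation,
# pooling, stratification) can be tested with known truth.

#' Specification of a synthetic cohort
#'
#' @param n number of participants.
#' @param effect_map named list of planted linear effects, one entry per
#'   feature name (see [wipab_features()]); each entry is a numeric vector
#'   with elements `quicki` and/or `hba1c`, the effect of one unit of the
#'   *scaled* exposure (scalings of [feature_scaling()]) on the outcome.
#' @param missingness named numeric vector of MCAR missingness fractions in
#'   `[0, 1)` per column (covariates or outcomes); a single unnamed value is
#'   applied to the default incomplete columns (income, education, alcohol,
#'   smoking, depression, sleep_duration, and quicki -- fasting bloods are
#'   missing for a fraction of participants in cohorts of this kind).
#' @param quicki_intercept,quicki_sd,hba1c_intercept,hba1c_sd intercept and
#'   residual sd of the outcome-generating linear models.
#' @param mode `"parametric"` draws feature values directly from
#'   population-calibrated distributions (fast; used for large replicate
#'   studies); `"signal"` generates a full epoch series per participant and
#'   leaves feature extraction to the pipeline.
#' @param seed integer seed.
#' @return A validated list with class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        effect_map = list(),
                        missingness = 0.05,
                        quicki_intercept = 0.36, quicki_sd = 0.03,
                        hba1c_intercept = 5.4, hba1c_sd = 0.45,
                        mode = c("parametric", "signal"),
                        seed = 1L) {
  assert_scalar_num(n, "n", lower = 1)
  mode <- match.arg(mode)
  bad <- setdiff(names(effect_map), wipab_features())
  if (length(bad)) {
    stop_config("effect_map", paste0("references unknown feature(s): ",
                                     paste(bad, collapse = ", ")))
  }
  if (is.null(names(missingness))) {
    if (length(missingness) != 1) {
      stop_config("missingness", "unnamed missingness must be a single rate")
    }
    missingness <- setNames(rep(missingness, 7),
                            c("income", "education", "alcohol", "smoking",
                              "depression", "sleep_duration", "quicki"))
  }
  if (any(missingness < 0 | missingness >= 1)) {
    stop_config("missingness", "rates must be in [0, 1)")
  }
  structure(
    list(n = as.integer(n), effect_map = effect_map,
         missingness = missingness,
         quicki_intercept = quicki_intercept, quicki_sd = quicki_sd,
         hba1c_intercept = hba1c_intercept, hba1c_sd = hba1c_sd,
         mode = mode, seed = as.integer(seed)),
    class = "cohort_spec")
}

# Population-calibrated marginal distributions for parametric feature draws.
# Centres and spreads follow the adult general-population profile the
# package targets (medians/IQRs of the kind reported for wrist-worn ENMO
# cohorts); sampen is the raw non-negative sample entropy.
draw_features <- function(n) {
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  tibble::tibble(
    time_sb = clip(rnorm(n, 12.1, 1.4), 6, 20),
    time_mvpa = clip(rnorm(n, 1.4, 0.6), 0, 6),
    mean_enmo = clip(rnorm(n, 25.5, 6.5), 5, 80),
    intensity_gradient = rnorm(n, -2.64, 0.19),
    m8 = clip(rnorm(n, 44.9, 12), 5, 150),
    m0_25 = rlnorm(n, log(128), 0.38),
    ple_alpha_sb = clip(rnorm(n, 2.44, 0.23), 1.2, 5),
    ple_alpha_mvpa = clip(rlnorm(n, log(5), 0.5), 1.2, 40),
    prop_sb_gt60 = clip(rnorm(n, 26.3, 10.7), 0, 100),
    prop_mvpa_gt10 = ifelse(rbinom(n, 1, 0.3) == 1, 0,
                            clip(rlnorm(n, log(10), 1), 0, 100)),
    gini_sb = clip(rnorm(n, 0.41, 0.075), 0.05, 0.95),
    dfa_alpha_short = clip(rnorm(n, 0.96, 0.09), 0.3, 1.6),
    dfa_alpha_long = clip(rnorm(n, 0.96, 0.15), 0.2, 1.8),
    acf_24h = clip(rnorm(n, 0.135, 0.05), -1, 1),
    lzc = clip(rnorm(n, 0.17, 0.04), 0.01, 1),
    sampen = rlnorm(n, log(0.6), 0.5),
    sym_2uv = clip(rnorm(n, 4.25, 1.1), 0, 100)
  )
}

draw_covariates <- function(n) {
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  tibble::tibble(
    age = clip(rnorm(n, 51.5, 11), 25, 79),
    sex = factor(ifelse(runif(n) < 0.55, "female", "male"),
                 levels = c("female", "male")),
    bmi = clip(rlnorm(n, log(25.4), 0.15), 15, 50),
    income = clip(rlnorm(n, log(3571), 0.45), 500, 30000),
    education = round(clip(rnorm(n, 14, 3), 8, 22)),
    alcohol = factor(sample(c("non", "normal", "intermediate", "excessive"),
                            n, replace = TRUE,
                            prob = c(0.045, 0.70, 0.20, 0.055)),
                     levels = c("non", "normal", "intermediate", "excessive")),
    smoking = factor(sample(c("never", "current", "former"), n, replace = TRUE,
                            prob = c(0.60, 0.12, 0.28)),
                     levels = c("never", "current", "former")),
    depression = runif(n) < 0.21,
    sleep_duration = clip(rnorm(n, 7.35, 0.9), 4, 11)
  )
}

#' Generate a synthetic cohort with planted effects
#'
#' Draws covariates and feature profiles for `n` participants and builds the
#' glycaemic outcomes as linear functions of the *scaled* features plus
#' Gaussian noise, per the cohort spec's `effect_map`. Fasting glucose is
#' drawn around 95 mg/dL and fasting insulin back-computed so that
#' [quicki()] reproduces the generated index exactly. Missing values are
#' then inserted completely at random. The planted truth (effect map,
#' outcome intercepts and noise sds) is attached as `attr(x, "truth")`.
#'
#' In `mode = "signal"` each participant additionally receives a
#' participant-perturbed epoch series (list column `series`); feature
#' columns are left to be filled by [wipab_profile()].
#'
#' @param cspec a [cohort_spec()].
#' @param sspec a [signal_spec()] used as the template in signal mode.
#' @return A tibble with one row per participant and attribute `truth`.
#' @export
generate_cohort <- function(cspec, sspec = signal_spec()) {
  if (!inherits(cspec, "cohort_spec")) stop_config("cspec", "must be a cohort_spec")
  set.seed(cspec$seed)
  n <- cspec$n
  cov <- draw_covariates(n)

  if (cspec$mode == "parametric") {
    feats <- draw_features(n)
    series <- NULL
  } else {
    sub <- derive_seeds(cspec$seed + 1L, n)
    series <- vector("list", n)
    feats <- NULL
    for (i in seq_len(n)) {
      sp <- sspec
      set.seed(sub[i])
      jit <- runif(3, 0.85, 1.15)
      sp$intensity_levels <- sspec$intensity_levels * jit
      sp$seed <- sub[i]
      series[[i]] <- generate_epoch_series(sp)
    }
    set.seed(cspec$seed + 2L)  # continue covariate/outcome stream
  }

  sc <- feature_scaling()
  lin <- function(outcome, intercept, sdev) {
    eta <- rep(intercept, n)
    if (!is.null(feats)) {
      for (f in names(cspec$effect_map)) {
        betas <- cspec$effect_map[[f]]
        beta <- if (outcome %in% names(betas)) betas[[outcome]] else NA_real_
        if (!is.na(beta)) {
          eta <- eta + beta * feats[[f]] / sc[[f]]
        }
      }
    }
    eta + rnorm(n, 0, sdev)
  }
  quicki_val <- lin("quicki", cspec$quicki_intercept, cspec$quicki_sd)
  quicki_val <- pmax(quicki_val, 0.15)
  hba1c_val <- pmax(lin("hba1c", cspec$hba1c_intercept, cspec$hba1c_sd), 3.5)

  glucose <- pmax(rnorm(n, 95, 10), 60)
  insulin <- 10^(1 / quicki_val - log10(glucose))

  rec <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("p%04d", seq_len(n))),
    cov,
    tibble::tibble(glucose = glucose, insulin = insulin,
                   quicki = quicki_val, hba1c = hba1c_val))
  if (!is.null(feats)) rec <- dplyr::bind_cols(rec, feats)
  if (!is.null(series)) rec$series <- series

  # MCAR missingness
  for (col in names(cspec$missingness)) {
    rate <- cspec$missingness[[col]]
    if (rate > 0 && col %in% names(rec)) {
      hit <- runif(n) < rate
      rec[[col]][hit] <- NA
      if (col == "quicki") rec$insulin[hit] <- NA
    }
  }

  attr(rec, "truth") <- list(
    effect_map = cspec$effect_map,
    quicki_intercept = cspec$quicki_intercept, quicki_sd = cspec$quicki_sd,
    hba1c_intercept = cspec$hba1c_intercept, hba1c_sd = cspec$hba1c_sd,
    mode = cspec$mode, seed = cspec$seed)
  rec
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv` (covariates, outcomes and any feature columns),
#' `truth.json` (planted generator parameters) and, in signal mode, one
#' `<id>.csv` epoch file per participant.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @param format `"csv"` (default) or `"parquet"` for the epoch files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort
  if (!is.null(tab$series)) {
    for (i in seq_len(nrow(tab))) {
      write_epoch_series(tab$series[[i]],
                         file.path(dir, paste0(tab$id[i], ".", format)))
    }
    tab$series <- NULL
  }
  readr::write_csv(tab, file.path(dir, "cohort.csv"), progress = FALSE)
  truth <- attr(cohort, "truth")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
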