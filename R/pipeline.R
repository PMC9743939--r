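# End-to-end orchestration: simulate -> screen -> bouts -> features ->
# associate, with a run manifest that accounts for every exclusion.

#' Default pipeline configuration
#'
#' @param n participants to simulate.
#' @param days complete days per participant.
#' @param effect_map planted effects (see [cohort_spec()]).
#' @param exposures,outcomes,models association-analysis scope.
#' @param n_imputations,n_iterations imputation controls.
#' @param seed master seed for the whole run.
#' @param use_truth_sleep use planted sleep windows instead of the detector.
#' @return Nested list accepted by [run_pipeline()]; can be serialised to
#'   YAML and read back with [read_pipeline_config()].
#' @export
pipeline_config <- function(n = 10, days = 6,
                            effect_map = list(),
                            exposures = c("time_sb", "time_mvpa", "mean_enmo"),
                            outcomes = c("quicki", "hba1c"),
                            models = 1:3,
                            n_imputations = 5, n_iterations = 5,
                            seed = 1L,
                            use_truth_sleep = FALSE) {
  list(n = n, days = days, effect_map = effect_map,
       exposures = exposures, outcomes = outcomes, models = models,
       n_imputations = n_imputations, n_iterations = n_iterations,
       seed = seed, use_truth_sleep = use_truth_sleep)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the [pipeline_config()] fields.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(user)] <- user
  cfg
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a signal-mode cohort, screens and profiles every participant,
#' fits the association models on the included participants with multiple
#' imputation and Rubin pooling, and writes three artefacts to `out_dir`:
#' `profiles.csv` (one feature row per participant, exclusions included
#' with their reason), `models.csv` (the pooled long results table) and
#' `manifest.json` (seeds, package version, configuration hash, and
#' per-stage participant accounting). Deterministic for a fixed seed.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return List with `profiles`, `models`, `manifest` (invisibly written to
#'   disk when `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cspec <- cohort_spec(config$n, effect_map = config$effect_map,
                       mode = "signal", seed = config$seed)
  sspec <- signal_spec(days = config$days, seed = config$seed)
  cohort <- generate_cohort(cspec, sspec)

  profiles <- profile_cohort(cohort, use_truth_sleep = config$use_truth_sleep)
  included <- profiles[profiles$included, ]
  excl <- table(profiles$exclusion_reason[!profiles$included])

  models <- NULL
  if (nrow(included) >= 10) {
    models <- associate_wipab(
      included,
      exposures = intersect(config$exposures, names(included)),
      outcomes = config$outcomes,
      models = config$models,
      n_imputations = config$n_imputations,
      n_iterations = config$n_iterations,
      seed = config$seed)
  } else {
    warning("fewer than 10 included participants; association models skipped",
            call. = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wipab")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_in = nrow(profiles),
    n_included = nrow(included),
    exclusions = as.list(excl))
  stopifnot(manifest$n_in == manifest$n_included + sum(unlist(excl)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(profiles, file.path(out_dir, "profiles.csv"),
                     progress = FALSE)
    if (!is.null(models)) {
      readr::write_csv(models, file.path(out_dir, "models.csv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(profiles = profiles, models = models, manifest = manifest))
}
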