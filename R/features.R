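# Canonical feature-column vocabulary shared by the profile builder, the
# cohort generator and the association models.

#' Names of the conventional and WIPAB feature columns
#'
#' Three conventional variables (daily sedentary hours, daily MVPA hours,
#' 24-h average acceleration) plus the WIPAB metrics, in the order the
#' profile table reports them.
#'
#' @return Character vector of feature column names.
#' @export
wipab_features <- function() {
  c("time_sb", "time_mvpa", "mean_enmo",
    "intensity_gradient", "m8", "m0_25",
    "ple_alpha_sb", "ple_alpha_mvpa",
    "prop_sb_gt60", "prop_mvpa_gt10", "gini_sb",
    "dfa_alpha_short", "dfa_alpha_long",
    "acf_24h", "lzc", "sampen", "sym_2uv")
}

#' Exposure rescaling applied before model fitting
#'
#' Divisors applied to each exposure before entering the association models,
#' so that coefficients land on a readable scale: average acceleration,
#' sedentary hours and the MX metrics are divided by 10; the MVPA power-law
#' exponent and sample entropy by 100; all other features are unscaled.
#'
#' @return Named numeric vector of divisors, one per feature.
#' @export
feature_scaling <- function() {
  sc <- setNames(rep(1, length(wipab_features())), wipab_features())
  sc[c("time_sb", "mean_enmo", "m8", "m0_25")] <- 10
  sc[c("ple_alpha_mvpa", "sampen")] <- 100
  sc
}
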