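# Glycaemic outcomes and association models: the QUICKI insulin-sensitivity
# index, the Spearman correlation matrix of behaviour variables, the three
# nested linear models per exposure, and Rubin pooling across imputations.

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' `1 / (log10(fasting insulin) + log10(fasting glucose))` with insulin in
#' uU/mL and glucose in mg/dL. Higher values indicate greater insulin
#' sensitivity. Non-positive inputs yield `NA`.
#'
#' @param insulin fasting insulin, uU/mL.
#' @param glucose fasting plasma glucose, mg/dL.
#' @return Numeric vector of QUICKI values.
#' @examples
#' quicki(10, 100)  # 1/3
#' @export
quicki <- function(insulin, glucose) {
  ins <- ifelse(!is.na(insulin) & insulin > 0, insulin, NA_real_)
  glu <- ifelse(!is.na(glucose) & glucose > 0, glucose, NA_real_)
  1 / (log10(ins) + log10(glu))
}

#' Spearman correlation matrix of behaviour variables
#'
#' Pairwise-complete Spearman correlations between the feature columns;
#' cells with fewer than `min_pairs` complete pairs are set to `NA`.
#'
#' @param profiles tibble holding the feature columns.
#' @param features character vector of columns to correlate.
#' @param min_pairs minimum complete pairs per cell.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(profiles, features = wipab_features(),
                            min_pairs = 3) {
  features <- intersect(features, names(profiles))
  m <- as.matrix(profiles[features])
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(m))
  rho[obs < min_pairs] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Plot a Spearman correlation matrix
#'
#' Heatmap of [spearman_matrix()] output (requires ggplot2).
#'
#' @param rho correlation matrix.
#' @return A ggplot object.
#' @export
plot_spearman <- function(rho) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- tibble::as_tibble(as.data.frame.table(rho, responseName = "rho"))
  names(df)[1:2] <- c("x", "y")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", high = "steelblue",
                                  limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho")
}

# Covariate sets of the three nested models.
model_covariates <- function(model) {
  switch(as.character(model),
    "1" = character(0),
    "2" = c("age", "sex"),
    "3" = c("age", "sex", "income", "education", "alcohol", "smoking",
            "sleep_duration", "depression", "bmi"),
    stop("model must be 1, 2 or 3", call. = FALSE))
}

#' Fit the nested association models for one exposure-outcome pair
#'
#' Ordinary (Gaussian identity-link) linear models on one completed
#' dataset: Model 1 unadjusted, Model 2 adjusted for age and sex, Model 3
#' further adjusted for income, education, alcohol consumption, smoking
#' status, total sleep duration, depression and BMI. The exposure is
#' rescaled by [feature_scaling()] before fitting; categorical covariates
#' use reference levels never-smoker, non-drinker, female.
#'
#' @param data completed (no relevant missingness) data frame.
#' @param exposure feature column name.
#' @param outcome `"quicki"` or `"hba1c"` (any numeric column).
#' @param models integer subset of 1:3.
#' @param drop_covariates covariates to omit (used by sex stratification).
#' @return Tibble with one row per model: `exposure`, `model`, `outcome`,
#'   `estimate`, `se`, `dfcom`, `n`.
#' @export
fit_models <- function(data, exposure, outcome, models = 1:3,
                       drop_covariates = character(0)) {
  if (!exposure %in% names(data)) stop("unknown exposure: ", exposure, call. = FALSE)
  if (!outcome %in% names(data)) stop("unknown outcome: ", outcome, call. = FALSE)
  sc <- feature_scaling()
  div <- if (exposure %in% names(sc)) sc[[exposure]] else 1
  x <- data[[exposure]] / div
  if (var(x, na.rm = TRUE) == 0 || all(is.na(x))) {
    stop("exposure '", exposure, "' has zero variance", call. = FALSE)
  }
  work <- data
  work$.exposure <- x
  set_ref <- function(col, ref) {
    f <- factor(col)
    if (ref %in% levels(f)) stats::relevel(f, ref) else f
  }
  if ("sex" %in% names(work)) work$sex <- set_ref(work$sex, "female")
  if ("smoking" %in% names(work)) work$smoking <- set_ref(work$smoking, "never")
  if ("alcohol" %in% names(work)) work$alcohol <- set_ref(work$alcohol, "non")
  purrr::map_dfr(models, function(mid) {
    covs <- setdiff(model_covariates(mid), drop_covariates)
    miss <- setdiff(covs, names(work))
    if (length(miss)) {
      stop("model ", mid, " needs covariates absent from the data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fml <- stats::reformulate(c(".exposure", covs), response = outcome)
    fit <- glm(fml, data = work, family = stats::gaussian())
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient design in model ", mid, "; collinear terms: ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    tibble::tibble(exposure = exposure, model = mid, outcome = outcome,
                   estimate = sm[".exposure", "Estimate"],
                   se = sm[".exposure", "Std. Error"],
                   dfcom = fit$df.residual,
                   n = length(fit$residuals))
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate `Qbar = mean(Q)`; total variance
#' `T = Ubar + (1 + 1/m) B` with `Ubar` the mean within-imputation variance
#' and `B` the between-imputation variance; interval and p-value from a t
#' distribution with Barnard-Rubin adjusted degrees of freedom.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param conf confidence level.
#' @param dfcom complete-data residual degrees of freedom (infinite by
#'   default, giving the classic large-sample df).
#' @return Tibble with `coef`, `se`, `t_var`, `b_var`, `u_var`, `df`,
#'   `lo`, `hi`, `p`, `n_imputations`.
#' @export
pool_rubin <- function(estimates, variances, conf = 0.95, dfcom = Inf) {
  m <- length(estimates)
  if (m != length(variances)) {
    stop("estimates and variances must have equal length", call. = FALSE)
  }
  if (m == 1) {
    warning("single imputation: pooled result is the single analysis",
            call. = FALSE)
    qbar <- estimates[1]; tt <- variances[1]; b <- 0; ubar <- variances[1]
    df <- if (is.finite(dfcom)) dfcom else Inf
  } else {
    qbar <- mean(estimates)
    ubar <- mean(variances)
    b <- sum((estimates - qbar)^2) / (m - 1)
    tt <- ubar + (1 + 1 / m) * b
    lambda <- (1 + 1 / m) * b / tt
    if (lambda <= 0) {
      df <- if (is.finite(dfcom)) dfcom else Inf
    } else {
      df_old <- (m - 1) / lambda^2
      df <- if (is.finite(dfcom)) {
        df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
        1 / (1 / df_old + 1 / df_obs)
      } else df_old
    }
  }
  se <- sqrt(tt)
  alpha <- 1 - conf
  crit <- if (is.finite(df)) qt(1 - alpha / 2, df) else qnorm(1 - alpha / 2)
  stat <- qbar / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  tibble::tibble(coef = qbar, se = se, t_var = tt, b_var = b, u_var = ubar,
                 df = df, lo = qbar - crit * se, hi = qbar + crit * se,
                 p = p, n_imputations = m)
}

#' Run the full association analysis
#'
#' Imputes the records (chained equations, [impute_chained()]), fits the
#' requested models for every exposure-outcome pair on each completed
#' dataset, and pools by Rubin's rules.
#'
#' @param records participant table with covariates, outcomes and feature
#'   columns.
#' @param exposures feature columns to analyse (defaults to every feature
#'   present).
#' @param outcomes outcome columns.
#' @param models integer subset of 1:3.
#' @param n_imputations,n_iterations,seed imputation controls.
#' @param imputed optional pre-computed result of [impute_chained()],
#'   bypassing imputation.
#' @return Long tibble: one row per exposure x model x outcome with pooled
#'   coefficient, 95% CI and p-value.
#' @export
associate_wipab <- function(records,
                            exposures = intersect(wipab_features(),
                                                  names(records)),
                            outcomes = c("quicki", "hba1c"),
                            models = 1:3,
                            n_imputations = 30, n_iterations = 20,
                            seed = 1L, imputed = NULL) {
  if (is.null(imputed)) {
    imputed <- impute_chained(records, n_imputations = n_imputations,
                              n_iterations = n_iterations, seed = seed,
                              outcomes = outcomes)
  }
  grid <- tidyr::expand_grid(exposure = exposures, outcome = outcomes)
  purrr::pmap_dfr(grid, function(exposure, outcome) {
    fits <- purrr::map_dfr(imputed, fit_models,
                           exposure = exposure, outcome = outcome,
                           models = models)
    fits |>
      dplyr::group_by(.data$model) |>
      dplyr::group_modify(function(d, key) {
        pool_rubin(d$estimate, d$se^2, dfcom = d$dfcom[1])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(exposure = exposure, outcome = outcome,
                    .before = 1)
  })
}

#' Sex-stratified finally adjusted model
#'
#' Fits the fully adjusted model (Model 3, sex dropped from the covariates)
#' separately within each sex stratum of each imputed dataset and pools per
#' stratum. Strata smaller than `min_n` are skipped with a warning.
#'
#' @param records participant table.
#' @param exposure,outcome single exposure and outcome.
#' @param min_n minimum stratum size.
#' @param n_imputations,n_iterations,seed imputation controls.
#' @param imputed optional pre-computed imputations.
#' @return Tibble with one pooled row per sex.
#' @export
stratify_by_sex <- function(records, exposure, outcome, min_n = 30,
                            n_imputations = 30, n_iterations = 20,
                            seed = 1L, imputed = NULL) {
  if (is.null(imputed)) {
    imputed <- impute_chained(records, n_imputations = n_imputations,
                              n_iterations = n_iterations, seed = seed,
                              outcomes = outcome)
  }
  sexes <- unique(as.character(records$sex[!is.na(records$sex)]))
  out <- list()
  for (s in sexes) {
    ns <- sum(as.character(imputed[[1]]$sex) == s)
    if (ns < min_n) {
      warning("sex stratum '", s, "' has ", ns, " < ", min_n,
              " participants; skipped", call. = FALSE)
      next
    }
    fits <- purrr::map_dfr(imputed, function(d) {
      fit_models(d[as.character(d$sex) == s, ], exposure, outcome,
                 models = 3, drop_covariates = "sex")
    })
    pooled <- pool_rubin(fits$estimate, fits$se^2, dfcom = fits$dfcom[1])
    pooled$sex <- s
    pooled$exposure <- exposure
    pooled$outcome <- outcome
    out[[s]] <- pooled
  }
  dplyr::bind_rows(out)
}
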