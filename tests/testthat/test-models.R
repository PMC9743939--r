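# QUICKI, Spearman matrix, nested models, chained-equation imputation and
# Rubin pooling.

test_that("quicki evaluates the index formula and rejects bad input", {
  expect_equal(quicki(10, 100), 1 / 3, tolerance = 1e-12)
  expect_equal(quicki(10, 90), 1 / (1 + log10(90)), tolerance = 1e-6)
  expect_equal(quicki(1, 10), 1)
  expect_true(is.na(quicki(0, 100)))
  expect_true(is.na(quicki(10, -5)))
  expect_true(is.na(quicki(NA, 100)))
})

test_that("spearman matrix is symmetric, rank-invariant and hand-checkable", {
  set.seed(91)
  df <- tibble::tibble(time_sb = rnorm(20), time_mvpa = rnorm(20))
  df$mean_enmo <- exp(df$time_sb)       # monotone transform
  rho <- spearman_matrix(df, c("time_sb", "time_mvpa", "mean_enmo"))
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), c(time_sb = 1, time_mvpa = 1, mean_enmo = 1))
  expect_equal(rho["time_sb", "mean_enmo"], 1)
  # 5-point toy vs hand-ranked Pearson-on-ranks
  x <- c(3, 1, 4, 1.5, 9); y <- c(2, 7, 1, 8, 3)
  toy <- tibble::tibble(time_sb = x, time_mvpa = y)
  expect_equal(spearman_matrix(toy, c("time_sb", "time_mvpa"))[1, 2],
               cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("model fits recover a planted effect and flag degenerate input", {
  co <- generate_cohort(cohort_spec(
    2000, effect_map = list(time_mvpa = c(quicki = 0.01)),
    missingness = 0, seed = 92))
  fit <- fit_models(co, "time_mvpa", "quicki", models = 1)
  expect_equal(fit$estimate, 0.01, tolerance = 0.25)
  expect_true(abs(fit$estimate - 0.01) < 2.5 * fit$se)
  co$flat <- 1
  expect_error(fit_models(co, "flat", "quicki"), "zero variance")
  expect_error(fit_models(co, "nope", "quicki"), "unknown exposure")
})

test_that("adding pure-noise covariates barely moves the coefficient", {
  co <- generate_cohort(cohort_spec(
    2000, effect_map = list(mean_enmo = c(quicki = 0.01)),
    missingness = 0, seed = 93))
  fits <- fit_models(co, "mean_enmo", "quicki", models = c(2, 3))
  m2 <- fits$estimate[fits$model == 2]
  m3 <- fits$estimate[fits$model == 3]
  expect_lt(abs(m2 - m3), 2 * fits$se[fits$model == 2])
})

test_that("rubin pooling reproduces the closed form and its limits", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$coef, 2)
  expect_equal(p$b_var, 2)
  expect_equal(p$t_var, 4)
  # B = 0 reproduces the single-dataset analysis
  p0 <- pool_rubin(rep(1.7, 5), rep(0.04, 5), dfcom = 100)
  expect_equal(p0$coef, 1.7)
  expect_equal(p0$t_var, 0.04)
  expect_equal(p0$df, 100)
  expect_equal(p0$lo, 1.7 - qt(0.975, 100) * 0.2, tolerance = 1e-12)
  # CI width grows with the between-imputation variance
  w <- vapply(c(0, 0.5, 1, 2), function(b) {
    est <- c(2 - sqrt(b / 2) , 2 + sqrt(b / 2))  # B = b
    pr <- pool_rubin(est, c(1, 1))
    pr$hi - pr$lo
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  expect_warning(p1 <- pool_rubin(2, 0.5), "single imputation")
  expect_equal(p1$coef, 2)
})

test_that("imputation is an identity on complete data and seed-stable", {
  co <- generate_cohort(cohort_spec(50, missingness = 0, seed = 94))
  imp <- impute_chained(co, n_imputations = 3, seed = 1)
  expect_length(imp, 3)
  expect_identical(imp[[1]], co)
  expect_identical(imp[[2]], co)
  co2 <- generate_cohort(cohort_spec(120, seed = 95))
  a <- impute_chained(co2, n_imputations = 2, n_iterations = 3, seed = 7)
  b <- impute_chained(co2, n_imputations = 2, n_iterations = 3, seed = 7)
  expect_identical(a, b)
  d <- impute_chained(co2, n_imputations = 2, n_iterations = 3, seed = 8)
  expect_false(identical(a[[1]]$income, d[[1]]$income))
})

test_that("imputed values restore the complete-data mean under MCAR", {
  set.seed(96)
  n <- 400
  df <- tibble::tibble(
    x = rnorm(n, 10, 2),
    quicki = rnorm(n, 0.36, 0.03),
    hba1c = rnorm(n, 5.4, 0.4))
  df$x <- df$x + 20 * df$quicki           # correlated so x is predictable
  full_mean <- mean(df$x)
  df$x[sample.int(n, 40)] <- NA
  imp <- impute_chained(df, n_imputations = 10, n_iterations = 5, seed = 3)
  means <- vapply(imp, function(d) mean(d$x), numeric(1))
  se <- sd(df$x, na.rm = TRUE) / sqrt(n)
  expect_lt(abs(mean(means) - full_mean), 2 * se)
})

test_that("completely missing variables are rejected", {
  df <- tibble::tibble(x = rep(NA_real_, 10), quicki = rnorm(10))
  expect_error(impute_chained(df), "100% missing")
})

test_that("imputation + pooling covers a planted effect end to end", {
  co <- generate_cohort(cohort_spec(
    500, effect_map = list(time_sb = c(quicki = -0.06)),
    missingness = c(quicki = 0.1), seed = 97))
  res <- associate_wipab(co, exposures = "time_sb", outcomes = "quicki",
                         models = 1, n_imputations = 5, n_iterations = 5,
                         seed = 4)
  expect_equal(nrow(res), 1)
  expect_true(res$lo < -0.06 && -0.06 < res$hi)
  expect_lt(res$p, 0.05)
})

test_that("sex stratification separates sex-specific effects", {
  co <- generate_cohort(cohort_spec(800, missingness = 0, seed = 98))
  beta_f <- 0.03
  set.seed(1)
  co$quicki <- 0.36 + ifelse(co$sex == "female", beta_f, 0) * co$gini_sb +
    rnorm(800, 0, 0.01)
  out <- stratify_by_sex(co, "gini_sb", "quicki", n_imputations = 2,
                         n_iterations = 2, seed = 5)
  expect_setequal(out$sex, c("female", "male"))
  f <- out[out$sex == "female", ]
  m <- out[out$sex == "male", ]
  expect_gt(f$lo, 0)                       # female CI excludes zero
  expect_lt(abs(m$coef), f$coef / 2)       # male effect near zero
  # single-sex input yields one stratum
  co_f <- co[co$sex == "female", ]
  out_f <- stratify_by_sex(co_f, "gini_sb", "quicki", n_imputations = 2,
                           n_iterations = 2, seed = 6)
  expect_equal(out_f$sex, "female")
})
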