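# Multiple imputation by chained equations with Rubin-style pooling
# downstream. Numeric variables use predictive mean matching (type-1, five
# donors) by default or Bayesian normal draws; binary variables logistic
# draws; categorical variables multinomial draws. Predictors are chosen
# quickpred-style: by absolute correlation with the target (or its
# missingness indicator), with the analysis outcomes always retained.

# Numeric coding of a data frame for correlation screening.
numeric_code <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) col
    else if (is.logical(col)) as.numeric(col)
    else as.numeric(as.factor(col))
  }))
}

# quickpred-style predictor matrix: pred[t, p] = TRUE when p predicts t.
select_predictors <- function(df, targets, threshold, outcomes) {
  num <- numeric_code(df)
  vars <- names(df)
  pred <- matrix(FALSE, length(targets), length(vars),
                 dimnames = list(targets, vars))
  for (t in targets) {
    rind <- as.numeric(is.na(df[[t]]))
    for (p in setdiff(vars, t)) {
      if (all(is.na(num[[p]])) || var(num[[p]], na.rm = TRUE) == 0) next
      c1 <- suppressWarnings(abs(cor(num[[t]], num[[p]],
                                     use = "pairwise.complete.obs")))
      c2 <- suppressWarnings(abs(cor(rind, num[[p]],
                                     use = "pairwise.complete.obs")))
      if (max(c1, c2, 0, na.rm = TRUE) >= threshold) pred[t, p] <- TRUE
    }
    pred[t, intersect(outcomes, setdiff(vars, t))] <- TRUE
  }
  pred
}

# Bayesian linear-regression parameter draw (sigma from scaled inv-chisq,
# beta from its normal posterior); X must include the intercept column.
bayes_lm_draw <- function(X, y) {
  qrX <- qr(X)
  rank <- qrX$rank
  beta_hat <- qr.coef(qrX, y)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y - X %*% beta_hat
  df <- max(length(y) - rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  xtx <- crossprod(X)
  # ridge fallback for (near-)singular designs
  v <- tryCatch(chol2inv(chol(xtx)),
                error = function(e) solve(xtx + diag(1e-6, ncol(X))))
  beta_star <- as.numeric(
    beta_hat + t(chol((v + t(v)) / 2)) %*% rnorm(ncol(X)) * sqrt(sigma2))
  list(beta_hat = as.numeric(beta_hat), beta_star = beta_star,
       sigma = sqrt(sigma2))
}

impute_numeric <- function(y, X, mis, method, donors) {
  draw <- bayes_lm_draw(X[!mis, , drop = FALSE], y[!mis])
  if (method == "norm") {
    as.numeric(X[mis, , drop = FALSE] %*% draw$beta_star) +
      rnorm(sum(mis)) * draw$sigma
  } else {
    yhat_obs <- as.numeric(X[!mis, , drop = FALSE] %*% draw$beta_hat)
    yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% draw$beta_star)
    yobs <- y[!mis]
    k <- min(donors, length(yobs))
    vapply(yhat_mis, function(v) {
      idx <- order(abs(yhat_obs - v))[seq_len(k)]
      yobs[sample(idx, 1)]
    }, numeric(1))
  }
}

impute_binary <- function(y, X, mis) {
  yb <- as.numeric(y[!mis])
  fit <- suppressWarnings(
    glm.fit(X[!mis, , drop = FALSE], yb, family = stats::binomial()))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  eta <- as.numeric(X[mis, , drop = FALSE] %*% beta)
  runif(sum(mis)) < stats::plogis(eta)
}

impute_factor <- function(y, Xdf, mis) {
  dat <- cbind(.y = droplevels(factor(y[!mis])), Xdf[!mis, , drop = FALSE])
  if (nlevels(dat$.y) < 2) {
    return(factor(rep(levels(dat$.y)[1], sum(mis)), levels = levels(y)))
  }
  cap <- utils::capture.output(
    fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE))
  pr <- predict(fit, newdata = Xdf[mis, , drop = FALSE], type = "probs")
  lev <- fit$lev
  if (is.null(dim(pr))) {
    # two classes: vector of P(level 2); single row: one row of class probs
    pr <- if (length(lev) == 2) cbind(1 - pr, pr) else matrix(pr, nrow = 1)
  }
  picks <- apply(pr, 1, function(p) sample(lev, 1, prob = p))
  factor(picks, levels = levels(y))
}

#' Multiple imputation by chained equations
#'
#' For each of `n_imputations` streams, missing entries are initialised by
#' random draws from the observed values and then updated over
#' `n_iterations` sweeps: each incomplete variable in turn is regressed on
#' its selected predictors in the current completed data and its missing
#' entries redrawn. Numeric variables use predictive mean matching with
#' `donors` donors and a Bayesian parameter draw (or Bayesian normal draws
#' with `method = "norm"`); logical variables logistic draws; factors
#' multinomial draws.
#'
#' @param data participant table; non-imputable columns (`id`, `series`,
#'   and `insulin`, which is deterministic in quicki and glucose) are
#'   carried through untouched.
#' @param n_imputations number of completed datasets (m).
#' @param n_iterations chained-equation sweeps per dataset.
#' @param seed integer seed; identical inputs and seed give identical
#'   imputations.
#' @param outcomes outcome columns always kept as predictors.
#' @param method `"pmm"` (default) or `"norm"` for numeric variables.
#' @param threshold quickpred correlation threshold.
#' @param donors predictive-mean-matching donor count.
#' @return List of `n_imputations` completed tibbles. With no missing data
#'   the list holds identical copies of the input.
#' @export
impute_chained <- function(data, n_imputations = 30, n_iterations = 20,
                           seed = 1L, outcomes = c("quicki", "hba1c"),
                           method = c("pmm", "norm"), threshold = 0.1,
                           donors = 5) {
  method <- match.arg(method)
  skip <- intersect(c("id", "series", "insulin"), names(data))
  work <- data[setdiff(names(data), skip)]
  work <- work[vapply(work, function(c)
    is.numeric(c) || is.logical(c) || is.factor(c) || is.character(c),
    logical(1))]
  work <- dplyr::mutate(work, dplyr::across(dplyr::where(is.character),
                                            as.factor))
  all_mis <- names(work)[vapply(work, function(c) all(is.na(c)), logical(1))]
  if (length(all_mis)) {
    stop("variable(s) 100% missing cannot be imputed: ",
         paste(all_mis, collapse = ", "), call. = FALSE)
  }
  targets <- names(work)[vapply(work, anyNA, logical(1))]
  if (length(targets) == 0) {
    return(replicate(n_imputations, data, simplify = FALSE))
  }
  # sweep order: least missing first
  targets <- targets[order(vapply(work[targets],
                                  function(c) sum(is.na(c)), numeric(1)))]
  pred <- select_predictors(work, targets, threshold, outcomes)
  sub <- derive_seeds(seed, n_imputations)

  lapply(seq_len(n_imputations), function(i) {
    set.seed(sub[i])
    comp <- work
    for (t in targets) {
      mis <- is.na(comp[[t]])
      obs <- comp[[t]][!mis]
      comp[[t]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    for (iter in seq_len(n_iterations)) {
      for (t in targets) {
        mis <- is.na(work[[t]])
        if (!any(mis)) next
        preds <- names(which(pred[t, ]))
        Xdf <- comp[preds]
        X <- stats::model.matrix(~ ., data = Xdf)
        y <- comp[[t]]
        y[mis] <- NA
        comp[[t]][mis] <-
          if (is.numeric(work[[t]])) {
            impute_numeric(work[[t]], X, mis, method, donors)
          } else if (is.logical(work[[t]])) {
            impute_binary(comp[[t]], X, mis)
          } else {
            as.character(impute_factor(comp[[t]], Xdf, mis))
          }
      }
    }
    out <- data
    for (t in targets) out[[t]] <- comp[[t]]
    out
  })
}
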