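# Multivariable logistic regression with chained-equation multiple
# imputation and Rubin's-rules pooling. Missingness is confined to the MSI
# and TMB covariates and is assumed missing at random; each incomplete
# binary covariate is imputed from a logistic model on all other
# covariates plus the outcome, with parameter draws from the approximate
# (normal) posterior of the fitted imputation model so that imputation
# uncertainty propagates into the pooled variance.

draw_glm_coefs <- function(fit) {
  beta <- coef(fit)
  V <- vcov(fit)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(beta)   # near-singular vcov: fall back to the MLE
  beta + drop(t(L) %*% rnorm(length(beta)))
}

impute_binary_once <- function(df, target, predictors) {
  obs <- !is.na(df[[target]])
  if (all(obs)) return(df)
  form <- as.formula(paste(target, "~",
                           paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(glm(form, data = df[obs, , drop = FALSE],
                              family = binomial()))
  beta <- draw_glm_coefs(fit)
  X <- model.matrix(form[-2], df[!obs, , drop = FALSE])
  pr <- plogis(drop(X[, names(beta), drop = FALSE] %*% beta))
  df[[target]][!obs] <- rbinom(sum(!obs), 1, pr)
  df
}

fit_logistic <- function(df, outcome, covariates) {
  form <- as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  X <- model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("collinear covariates in the logistic design: %s",
          paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  if (!fit$converged)
    warnf("logistic fit did not fully converge; estimates flagged")
  if (any(abs(coef(fit)) > 15))
    warnf("possible separation: |log-OR| > 15 for %s",
          paste(names(coef(fit))[abs(coef(fit)) > 15], collapse = ", "))
  fit
}

#' Multivariable logistic regression with multiple imputation
#'
#' Imputes incomplete binary covariates by chained logistic imputation
#' (default ordering: `msi_unstable` then `tmb_high`), fits the analysis
#' logistic model on each completed dataset, and pools by Rubin's rules
#' (point estimate = mean of estimates; total variance = within + (1+1/m)
#' between; Barnard-Rubin adjusted degrees of freedom). With no missing
#' data the result collapses to the single complete-data fit.
#'
#' @param data data frame holding the outcome and covariates as 0/1
#'   (or logical) columns; only the covariates named in `incomplete` may
#'   contain NA.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names.
#' @param m number of imputations (>= 2; default 20).
#' @param seed integer seed for the imputation stream.
#' @param burnin chained-equation burn-in cycles (default 10).
#' @param incomplete covariates eligible for imputation, in update order;
#'   default: those among `covariates` containing NA.
#' @return Data frame with one row per coefficient: pooled `estimate`
#'   (log-OR), `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `df`, and the
#'   between/within variance components; attribute `m`.
#' @export
multivariable_logistic_mi <- function(data, outcome, covariates, m = 20L,
                                      seed = 1L, burnin = 10L,
                                      incomplete = NULL) {
  if (m < 2L) stopf("m must be at least 2 imputations")
  df <- data[, c(outcome, covariates), drop = FALSE]
  for (cl in colnames(df)) df[[cl]] <- as.numeric(df[[cl]])
  incomplete <- incomplete %||% covariates[vapply(covariates, function(v)
    anyNA(df[[v]]), logical(1))]
  if (anyNA(df[[outcome]])) stopf("outcome must be complete")
  complete_cov <- setdiff(covariates, incomplete)
  bad <- complete_cov[vapply(complete_cov, function(v) anyNA(df[[v]]),
                             logical(1))]
  if (length(bad))
    stopf("unexpected missingness in: %s", paste(bad, collapse = ", "))

  if (!length(incomplete)) {
    fit <- fit_logistic(df, outcome, covariates)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    out <- data.frame(
      term = rownames(sm), estimate = est, std_error = se,
      odds_ratio = exp(est),
      ci_lo = exp(est - qnorm(0.975) * se),
      ci_hi = exp(est + qnorm(0.975) * se),
      p_value = 2 * pnorm(-abs(est / se)),
      df = Inf, between_var = 0, within_var = se^2,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "m") <- 1L
    return(out)
  }

  fits <- with_rng(seed, {
    lapply(seq_len(m), function(k) {
      dk <- df
      # fresh random start per imputation, then burn-in cycles
      for (v in incomplete) {
        miss <- is.na(dk[[v]])
        dk[[v]][miss] <- sample(dk[[v]][!miss], sum(miss), replace = TRUE)
      }
      for (cycle in seq_len(burnin)) {
        for (v in incomplete) {
          dk[[v]][is.na(df[[v]])] <- NA
          preds <- c(outcome, setdiff(covariates, v))
          dk <- impute_binary_once(dk, v, preds)
        }
      }
      fit_logistic(dk, outcome, covariates)
    })
  })

  ests <- sapply(fits, coef)
  ses <- sapply(fits, function(f) summary(f)$coefficients[, "Std. Error"])
  qbar <- rowMeans(ests)
  W <- rowMeans(ses^2)
  B <- apply(ests, 1, var)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  # Barnard-Rubin small-sample degrees of freedom
  lambda <- (1 + 1 / m) * B / Tv
  dfcom <- nrow(df) - length(qbar)
  df_old <- (m - 1) / pmax(lambda^2, 1e-12)
  df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  df_adj <- df_old * df_obs / (df_old + df_obs)
  out <- data.frame(
    term = names(qbar), estimate = qbar, std_error = se,
    odds_ratio = exp(qbar),
    ci_lo = exp(qbar - qt(0.975, df_adj) * se),
    ci_hi = exp(qbar + qt(0.975, df_adj) * se),
    p_value = 2 * pt(-abs(qbar / se), df_adj),
    df = df_adj, between_var = B, within_var = W,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}
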