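# Survival analyses stratified by transcript rank: Kaplan-Meier curves
# with log-log confidence intervals, two-group log-rank tests, and Cox
# proportional-hazards models (Efron ties by default) with the gene of
# interest entered either as the binary high/not-high category or as the
# continuous percentile rank. Estimation is delegated to the survival
# package; this module fixes the conventions and the output schema.

#' Kaplan-Meier estimate with median and 95% CI
#'
#' Product-limit estimator with Greenwood variance and log-log confidence
#' intervals; the median is the earliest time at which the survival curve
#' drops to 0.5 or below (NA when the curve never does).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return List with `curve` (data frame time/n_risk/n_event/surv/lo/hi),
#'   `median`, `median_ci` (lower, upper; NA when undefined), `n`,
#'   `n_events`.
#' @export
km_estimate <- function(time, event) {
  check_surv_inputs(time, event)
  if (sum(event) < 1L) warnf("no events: survival curve is uninformative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  sm <- summary(fit)$table
  # median: earliest time at which the curve reaches 0.5 or below (the
  # survfit default instead averages across a flat stretch at exactly 0.5)
  med <- if (any(fit$surv <= 0.5 + 1e-12))
    min(fit$time[fit$surv <= 0.5 + 1e-12]) else NA_real_
  list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv,
                          lower = fit$lower, upper = fit$upper),
       median = med,
       median_ci = c(lower = unname(sm["0.95LCL"]),
                     upper = unname(sm["0.95UCL"])),
       n = unname(sm["records"]), n_events = unname(sm["events"]))
}

#' Two-group log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor/logical stratum per subject.
#' @return List with `chi_sq`, `p_value`, `df` (= 1).
#' @export
logrank_test <- function(time, event, group) {
  check_surv_inputs(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stopf("log-rank comparison needs exactly 2 non-empty strata")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_sq = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction by
#' default; Wald hazard ratios, 95% CIs and p-values per covariate.
#'
#' @param data data frame of covariates.
#' @param time_col,event_col column names of the survival fields.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List with `coefficients` (term, log_hr, hr, ci_lo, ci_hi,
#'   p_value), `n`, `n_events`, `score_chi_sq`, and the fitted `coxph`
#'   object in `fit`.
#' @export
cox_fit <- function(data, time_col, event_col, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_inputs(data[[time_col]], data[[event_col]])
  if (sum(data[[event_col]]) < 1L) stopf("need at least one event")
  X <- model.matrix(
    as.formula(paste("~", paste(covariates, collapse = " + "))), data)
  if (qr(X)$rank < ncol(X)) stopf("covariate design matrix is rank-deficient")
  form <- as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                            ") ~ ", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(form, data = data, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(is.na(coef(fit)))) stopf("Cox fit dropped coefficients (singular)")
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = data.frame(
         term = rownames(co), log_hr = co[, "coef"],
         hr = exp(co[, "coef"]),
         ci_lo = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
         ci_hi = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
         p_value = co[, "Pr(>|z|)"], row.names = NULL,
         stringsAsFactors = FALSE),
       n = sm$n, n_events = sm$nevent,
       score_chi_sq = unname(sm$sctest["test"]),
       fit = fit)
}

check_surv_inputs <- function(time, event) {
  if (anyNA(time) || anyNA(event)) stopf("survival fields contain NA")
  if (any(time <= 0)) stopf("survival times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0/1")
  invisible(TRUE)
}

#' Split a cohort table into the three survival analysis sets
#'
#' Builds (i) overall survival from advanced disease for survival-evaluable
#' patients never exposed to immune checkpoint inhibitors, (ii) overall
#' survival from therapy start for ICI-treated patients, and (iii)
#' progression-free survival (progression or death, whichever first) from
#' therapy start for the same subset. Rows with non-positive or missing
#' durations are dropped and listed.
#'
#' @param table cohort table carrying the survival columns produced by
#'   [generate_study_cohort()].
#' @return List of three data frames (`os_naive`, `os_ici`, `pfs_ici`),
#'   each with `sample_id`, `time_months`, `event` plus all cohort
#'   columns, and a `rejected` character vector of dropped sample ids.
#' @export
build_survival_cohorts <- function(table) {
  take <- function(sel, time_col, event_col) {
    df <- table[sel & !is.na(table[[time_col]]), , drop = FALSE]
    bad <- df$sample_id[df[[time_col]] <= 0 | is.na(df[[event_col]])]
    df <- df[!(df$sample_id %in% bad), , drop = FALSE]
    df$time_months <- df[[time_col]]
    df$event <- df[[event_col]]
    list(df = df, bad = bad)
  }
  naive <- take(table$survival_evaluable & !table$ici_treated,
                "os_adv_months", "os_adv_event")
  os_ici <- take(table$ici_treated, "os_ici_months", "os_ici_event")
  pfs_ici <- take(table$ici_treated, "pfs_ici_months", "pfs_ici_event")
  list(os_naive = naive$df, os_ici = os_ici$df, pfs_ici = pfs_ici$df,
       rejected = unique(c(naive$bad, os_ici$bad, pfs_ici$bad)))
}
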