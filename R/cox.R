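#' Event indicator for a mortality category
#'
#' For cause-specific analyses, deaths from the other cause are treated as
#' censored at their death time (no competing-risks subdistribution).
#'
#' @param cohort cohort with `died` and `cause_category` columns.
#' @param event_type `"total"`, `"cancer"` or `"non_cancer"`.
#' @return integer 0/1 event vector.
#' @export
event_indicator <- function(cohort, event_type = c("total", "cancer",
                                                   "non_cancer")) {
  event_type <- match.arg(event_type)
  died <- isTRUE_vec(cohort$died)
  if (event_type == "total") return(as.integer(died))
  cause <- if ("cause_category" %in% names(cohort)) cohort$cause_category
           else rep(NA_character_, nrow(cohort))
  as.integer(died & !is.na(cause) & cause == event_type)
}

#' Cox proportional hazards fit for a model specification
#'
#' Fits one of the four mortality models — DAnHI only, chronological age
#' (CA) only, CA with DAnHI as complementary risk factors, or biological
#' age (BA = CA + DAnHI) as a single risk factor — by partial likelihood
#' with the Efron correction for tied event times. Per-unit hazard ratios
#' with Wald 95% confidence intervals come from the observed information.
#'
#' @param cohort scored cohort: needs `followup_years`, `died`,
#'   `cause_category`, plus the model covariates (`danhi`,
#'   `chronological_age`).
#' @param model_label one of `"DAnHI"`, `"CA"`, `"CA_with_DAnHI"`, `"BA"`,
#'   or `"custom"` with explicit `covariates`.
#' @param event_type mortality category analysed (see [event_indicator()]).
#' @param covariates covariate names when `model_label = "custom"`.
#' @return a `cox_fit`: `model_label`, `covariate_names`, `hazard_ratios`,
#'   `ci_lower`, `ci_upper`, `p_values`, `n_events`, `risk_score` (linear
#'   predictor per record, centred), and the underlying `survival::coxph`
#'   object in `fit`.
#' @export
fit_cox <- function(cohort,
                    model_label = c("DAnHI", "CA", "CA_with_DAnHI", "BA",
                                    "custom"),
                    event_type = "total", covariates = NULL) {
  model_label <- match.arg(model_label)
  covariates <- switch(model_label,
                       DAnHI = "danhi",
                       CA = "chronological_age",
                       CA_with_DAnHI = c("chronological_age", "danhi"),
                       BA = "biological_age",
                       custom = covariates)
  stopifnot(!is.null(covariates))
  check_cohort(cohort, need_biomarkers = covariates, need_survival = TRUE)
  if (any(cohort$followup_years <= 0)) {
    stop_danhi("danhi_bad_input", "followup_years must be > 0 for Cox fits")
  }
  event <- event_indicator(cohort, event_type)
  if (sum(event) == 0L) {
    stop_danhi("danhi_no_events", "no %s events in the cohort", event_type)
  }
  x <- as.matrix(cohort[covariates])
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop_danhi("danhi_degenerate_design", "collinear Cox covariates")
  }
  df <- data.frame(time = cohort$followup_years, event = event, x)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(colnames(x), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  structure(list(model_label = model_label,
                 event_type = event_type,
                 covariate_names = covariates,
                 hazard_ratios = exp(beta),
                 ci_lower = exp(beta - 1.959964 * se),
                 ci_upper = exp(beta + 1.959964 * se),
                 p_values = 2 * stats::pnorm(-abs(z)),
                 n_events = sum(event),
                 risk_score = unname(fit$linear.predictors),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s (%s mortality), %d events\n",
              x$model_label, x$event_type, x$n_events))
  for (i in seq_along(x$covariate_names)) {
    cat(sprintf("  %-18s HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                x$covariate_names[i], x$hazard_ratios[i], x$ci_lower[i],
                x$ci_upper[i], x$p_values[i]))
  }
  invisible(x)
}

#' Relative influence of DAnHI versus chronological age
#'
#' `(HR_DAnHI - 1) / (HR_CA - 1) * 100` (%): the excess hazard per unit of
#' the index as a percentage of the excess hazard per year of chronological
#' age, both taken from the same age-adjusted Cox model.
#'
#' @param hr_danhi per-unit hazard ratio of DAnHI.
#' @param hr_ca per-year hazard ratio of chronological age.
#' @return the ratio in percent (unrounded).
#' @export
hr_ratio_percent <- function(hr_danhi, hr_ca) {
  if (any(hr_ca == 1)) {
    stop_danhi("danhi_undefined_ratio",
               "HR ratio undefined when the chronological-age HR is 1.0")
  }
  (hr_danhi - 1) / (hr_ca - 1) * 100
}

#' Assign DAnHI risk groups
#'
#' Low risk: DAnHI <= 0; medium: 0 < DAnHI < median of the strictly
#' positive development DAnHIs; high: DAnHI >= that median. The positive
#' median is estimated on the development values and then applied to the
#' cohort being stratified, so validation stratification never uses its own
#' labels.
#'
#' @param development_danhi numeric DAnHI values used to set the threshold.
#' @param danhi numeric DAnHI values to stratify (defaults to
#'   `development_danhi`).
#' @return a `risk_groups` list: `median_positive`, and `group` (factor
#'   `low`/`medium`/`high` per value of `danhi`).
#' @export
assign_risk_groups <- function(development_danhi, danhi = development_danhi) {
  pos <- development_danhi[development_danhi > 0]
  if (!length(pos)) {
    stop_danhi("danhi_no_positive",
               "no positive DAnHI values to define the risk threshold")
  }
  med <- stats::median(pos)
  group <- factor(ifelse(danhi <= 0, "low",
                         ifelse(danhi < med, "medium", "high")),
                  levels = c("low", "medium", "high"))
  structure(list(median_positive = med, group = group),
            class = "risk_groups")
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimate per group and the k-group log-rank
#' chi-square comparing them.
#'
#' @param cohort cohort with `followup_years`, `died`, `cause_category`.
#' @param group factor of group labels (length `nrow(cohort)`), e.g. the
#'   `group` element of [assign_risk_groups()].
#' @param event_type mortality category (see [event_indicator()]).
#' @return a `km_result`: `curves` (data.frame time / survival / n_risk /
#'   n_event / group), `logrank_chisq`, `logrank_df`, `logrank_p`.
#' @export
km_logrank <- function(cohort, group, event_type = "total") {
  check_cohort(cohort, need_survival = TRUE)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) {
    stop_danhi("danhi_single_group", "need >= 2 groups for a log-rank test")
  }
  event <- event_indicator(cohort, event_type)
  df <- data.frame(time = cohort$followup_years, event = event,
                   group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata_labels <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(time = sf$time, survival = sf$surv,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       group = strata_labels, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  df_lr <- nlevels(group) - 1L
  structure(list(curves = curves,
                 logrank_chisq = sd$chisq,
                 logrank_df = df_lr,
                 logrank_p = stats::pchisq(sd$chisq, df_lr,
                                           lower.tail = FALSE)),
            class = "km_result")
}
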