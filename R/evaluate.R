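#' Default age bands for subgroup evaluation
#'
#' Broad bands (at most 39, 40-64, 65 and over), the decades from the 20s
#' to 70-plus, and the pooled cohort.
#'
#' @return named list of `c(lo, hi)` inclusive age bounds.
#' @export
default_age_bands <- function() {
  list(Total = c(20, 200), le39 = c(20, 39), a40_64 = c(40, 64),
       ge65 = c(65, 200),
       a20s = c(20, 29), a30s = c(30, 39), a40s = c(40, 49),
       a50s = c(50, 59), a60s = c(60, 69), a70plus = c(70, 200))
}

eval_one_band <- function(band_cohort, event_type, horizons, risk_group) {
  out <- list(n = nrow(band_cohort),
              n_events = sum(event_indicator(band_cohort, event_type)))
  fits <- list()
  for (lbl in c("DAnHI", "CA", "CA_with_DAnHI", "BA")) {
    fits[[lbl]] <- tryCatch(fit_cox(band_cohort, lbl, event_type),
                            danhi_error = function(e) NULL)
  }
  out$cox <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    list(covariates = f$covariate_names,
         hazard_ratios = unname(f$hazard_ratios),
         ci_lower = unname(f$ci_lower), ci_upper = unname(f$ci_upper),
         p_values = unname(f$p_values), n_events = f$n_events)
  })
  # HR ratio: DAnHI and CA hazard ratios from the same age-adjusted model
  f2 <- fits$CA_with_DAnHI
  out$hr_ratio_percent <-
    if (!is.null(f2) && f2$hazard_ratios[["chronological_age"]] != 1) {
      hr_ratio_percent(f2$hazard_ratios[["danhi"]],
                       f2$hazard_ratios[["chronological_age"]])
    } else NA_real_

  km <- tryCatch(km_logrank(band_cohort, risk_group, event_type),
                 danhi_error = function(e) NULL)
  out$risk_groups <- list(sizes = as.list(table(risk_group)),
                          logrank_chisq = if (is.null(km)) NA_real_
                                          else km$logrank_chisq,
                          logrank_p = if (is.null(km)) NA_real_
                                      else km$logrank_p)

  out$auc <- list()
  for (h in horizons) {
    hrow <- list()
    ref <- fits$CA
    for (lbl in names(fits)) {
      f <- fits[[lbl]]
      if (is.null(f)) { hrow[[lbl]] <- NULL; next }
      a <- tryCatch(horizon_auc(f$risk_score, band_cohort, h, event_type),
                    danhi_error = function(e) NULL)
      if (is.null(a)) next
      entry <- list(auc = a$auc, ci_lower = a$ci_lower,
                    ci_upper = a$ci_upper, n_cases = a$n_cases,
                    n_controls = a$n_controls)
      if (lbl != "CA" && !is.null(ref)) {
        dl <- tryCatch(
          horizon_delong(f$risk_score, ref$risk_score, band_cohort, h,
                         event_type),
          danhi_error = function(e) NULL)
        entry$delong_p_vs_CA <- if (is.null(dl)) NA_real_ else dl$p
      }
      hrow[[lbl]] <- entry
    }
    out$auc[[sprintf("year_%d", h)]] <- hrow
  }
  out
}

#' Subgroup mortality evaluation of a fitted ensemble
#'
#' Scores a validation cohort with development-fitted ensembles and, for
#' every sex, age band and mortality category, reports the four Cox models
#' (DAnHI, CA, CA with DAnHI, BA), the DAnHI-versus-age HR ratio, risk-group
#' Kaplan-Meier / log-rank results, and fixed-horizon AUCs with DeLong
#' comparisons of each DAnHI-including model against the age-only model.
#' Subgroups with no events are reported as not estimable rather than
#' raising an error.
#'
#' @param validation validation cohort (both sexes allowed).
#' @param ensembles named list of `threshold_ensemble`s keyed by sex, or a
#'   single ensemble (then only that sex is evaluated).
#' @param development optional development cohort; when given, the
#'   risk-group threshold (median positive DAnHI) is frozen on
#'   development scores per sex, otherwise it is estimated on the
#'   validation scores.
#' @param age_bands named list of inclusive `c(lo, hi)` bounds; default
#'   [default_age_bands()].
#' @param event_types subset of `c("total", "cancer", "non_cancer")`.
#' @param horizons AUC horizons in years (default 1..10).
#' @return nested list keyed sex / band / event type, each leaf as produced
#'   for one subgroup; per-sex `scores` data.frames and risk-group
#'   thresholds are attached under `scoring`.
#' @export
evaluate_suite <- function(validation, ensembles, development = NULL,
                           age_bands = default_age_bands(),
                           event_types = c("total", "cancer", "non_cancer"),
                           horizons = 1:10) {
  if (inherits(ensembles, "threshold_ensemble")) {
    ensembles <- stats::setNames(list(ensembles), ensembles$sex)
  }
  event_types <- match.arg(event_types, several.ok = TRUE)
  report <- list(scoring = list(), by_sex = list())
  for (s in names(ensembles)) {
    ens <- ensembles[[s]]
    val_s <- validation[validation$sex == s, , drop = FALSE]
    if (!nrow(val_s)) next
    scored <- score_cohort(val_s, ens)
    val_s$danhi <- scored$danhi
    val_s$biological_age <- scored$biological_age

    ref_danhi <- if (!is.null(development)) {
      dev_s <- development[development$sex == s, , drop = FALSE]
      score_cohort(dev_s, ens)$danhi
    } else val_s$danhi
    rg <- assign_risk_groups(ref_danhi, val_s$danhi)

    report$scoring[[s]] <- list(n = nrow(val_s),
                                median_positive_danhi = rg$median_positive,
                                scores = scored)
    sex_report <- list()
    for (b in names(age_bands)) {
      lo <- age_bands[[b]][1]; hi <- age_bands[[b]][2]
      in_band <- val_s$chronological_age >= lo &
        val_s$chronological_age <= hi
      if (!any(in_band)) next
      band_report <- list()
      for (ev in event_types) {
        band_report[[ev]] <- eval_one_band(val_s[in_band, , drop = FALSE],
                                           ev, horizons,
                                           rg$group[in_band])
      }
      sex_report[[b]] <- band_report
    }
    report$by_sex[[s]] <- sex_report
  }
  report
}
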