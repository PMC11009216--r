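# DeLong structural components via midranks. For case scores x (length m)
# and control scores y (length n): V10[i] is case i's placement value
# (fraction of controls it outranks, ties counted 1/2) and V01[j] the
# analogous control placement; mean(V10) = mean(V01) = the Mann-Whitney AUC.
delong_components <- function(x, y) {
  m <- length(x); n <- length(y)
  all_r <- rank(c(x, y), ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Fixed-horizon AUC of a risk score for mortality
#'
#' Discrimination of a risk score for death by a fixed follow-up horizon.
#' Cases are participants who died (of the analysed cause) at or before the
#' horizon; controls are participants whose follow-up reaches the horizon
#' without it (administrative censoring at exactly the horizon counts as
#' complete follow-up); records censored strictly before the horizon
#' without the event are excluded. The AUC is
#' the Mann-Whitney probability that a case's score exceeds a control's
#' (ties count 1/2); its variance and 95% CI come from DeLong's
#' structural-components estimator.
#'
#' @param scores numeric risk scores, one per cohort record (higher = more
#'   at risk), e.g. Cox linear predictors.
#' @param cohort cohort with `followup_years`, `died`, `cause_category`.
#' @param horizon follow-up horizon in years (> 0).
#' @param event_type mortality category (see [event_indicator()]).
#' @return an `auc_result`: `horizon`, `auc`, `variance`, `ci_lower`,
#'   `ci_upper`, `n_cases`, `n_controls`, and the case/control indices used.
#' @export
horizon_auc <- function(scores, cohort, horizon = 10, event_type = "total") {
  stopifnot(horizon > 0, length(scores) == nrow(cohort))
  check_cohort(cohort, need_survival = TRUE)
  event <- event_indicator(cohort, event_type)
  is_case <- event == 1L & cohort$followup_years <= horizon
  is_control <- !is_case & cohort$followup_years >= horizon
  if (!any(is_case) || !any(is_control)) {
    stop_danhi("danhi_no_events",
               "no %s at the %g-year horizon",
               if (!any(is_case)) "cases" else "controls", horizon)
  }
  comp <- delong_components(scores[is_case], scores[is_control])
  var0 <- function(v) if (length(v) < 2) 0 else stats::var(v)
  v <- var0(comp$v10) / sum(is_case) + var0(comp$v01) / sum(is_control)
  se <- sqrt(v)
  structure(list(horizon = horizon, auc = comp$auc, variance = v,
                 ci_lower = max(0, comp$auc - 1.959964 * se),
                 ci_upper = min(1, comp$auc + 1.959964 * se),
                 n_cases = sum(is_case), n_controls = sum(is_control),
                 case_idx = which(is_case), control_idx = which(is_control)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> %g-year AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$horizon, x$auc, x$ci_lower, x$ci_upper, x$n_cases,
              x$n_controls))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two risk scores evaluated on the same cases and
#' controls. The variance of the AUC difference uses the DeLong covariance
#' of the structural components; the two-sided p-value comes from the
#' normal approximation. Scores that rank all pairs identically (for
#' example one score a strictly increasing transform of the other) give an
#' AUC difference of zero and p = 1.
#'
#' @param scores_a,scores_b score vectors for classifiers A and B, aligned
#'   element-wise with `labels`.
#' @param labels 0/1 (or logical) case indicators; both classes present.
#' @return a list: `auc_a`, `auc_b`, `auc_diff`, `variance`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_danhi("danhi_bad_input", "scores and labels must be equal length")
  }
  if (!any(labels) || all(labels)) {
    stop_danhi("danhi_single_class", "labels must contain both classes")
  }
  m <- sum(labels); n <- sum(!labels)
  ca <- delong_components(scores_a[labels], scores_a[!labels])
  cb <- delong_components(scores_b[labels], scores_b[!labels])
  cov0 <- function(a, b) {
    if (length(a) < 2) matrix(0, 2, 2) else stats::cov(cbind(a, b))
  }
  s10 <- cov0(ca$v10, cb$v10)
  s01 <- cov0(ca$v01, cb$v01)
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (v <= .Machine$double.eps^0.5 * max(1, abs(d))) {
    # degenerate: identical rankings (d = 0) give p = 1
    p <- if (abs(d) < 1e-12) 1 else 0
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d, variance = v,
       z = z, p = p)
}

#' Horizon AUC comparison of two risk scores
#'
#' Convenience wrapper: forms the case/control sets at a horizon as in
#' [horizon_auc()] and runs [delong_test()] on the paired scores.
#'
#' @inheritParams horizon_auc
#' @param scores_a,scores_b risk scores per cohort record.
#' @return the [delong_test()] result plus `n_cases` and `n_controls`.
#' @export
horizon_delong <- function(scores_a, scores_b, cohort, horizon = 10,
                           event_type = "total") {
  a <- horizon_auc(scores_a, cohort, horizon, event_type)
  idx <- c(a$case_idx, a$control_idx)
  lab <- c(rep(TRUE, a$n_cases), rep(FALSE, a$n_controls))
  res <- delong_test(scores_a[idx], scores_b[idx], lab)
  res$n_cases <- a$n_cases
  res$n_controls <- a$n_controls
  res
}
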