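#' Fit one dichotomized-age logistic model
#'
#' For model age `n`, participants are labelled by aging status: 0 for
#' chronological age `< n`, 1 for age `>= n`. A multivariable binary
#' logistic regression of this status on the biomarker covariates (on their
#' raw measurement scales, so odds ratios are per natural unit) gives each
#' individual's probability `P` of being differentiated as at least `n`
#' years old. The probability cutoff `C_n` is the Youden-optimal threshold
#' on the fitting-data predictions.
#'
#' @param development development-cohort data.frame.
#' @param n model age in years.
#' @param covariates covariate column names.
#' @return an `age_threshold_model`: `model_age`, `coefficients` (intercept
#'   first), `covariate_names`, `cutoff`, `n_below`, `n_at_or_above`,
#'   `converged`.
#' @export
fit_threshold_model <- function(development, n, covariates) {
  check_cohort(development, need_biomarkers = covariates)
  y <- as.integer(development$chronological_age >= n)
  n_below <- sum(y == 0L)
  n_above <- sum(y == 1L)
  if (n_below == 0L || n_above == 0L) {
    stop_danhi("danhi_empty_class",
               "model age %d: empty aging-status class (%d below, %d at/above)",
               n, n_below, n_above)
  }
  x <- as.matrix(development[covariates])
  if (!all(is.finite(x))) {
    stop_danhi("danhi_bad_input", "non-finite covariate values")
  }
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop_danhi("danhi_degenerate_design",
               "constant covariate(s): %s",
               paste(covariates[apply(x, 2, stats::sd) == 0], collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind("(Intercept)" = 1, x), y,
                   family = stats::binomial()))
  if (anyNA(fit$coefficients)) {
    stop_danhi("danhi_degenerate_design",
               "model age %d: collinear design, coefficients not identifiable", n)
  }
  p <- fit$fitted.values
  cut <- compute_youden_cutoff(p, y)
  structure(list(model_age = as.integer(n),
                 coefficients = fit$coefficients,
                 covariate_names = covariates,
                 cutoff = cut$cutoff,
                 youden_j = cut$j,
                 n_below = n_below,
                 n_at_or_above = n_above,
                 converged = isTRUE(fit$converged)),
            class = "age_threshold_model")
}

#' Predict P (probability of aging status >= model age) for new records
#'
#' @param object an `age_threshold_model`.
#' @param newdata data.frame holding the model covariates.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.age_threshold_model <- function(object, newdata, ...) {
  miss <- setdiff(object$covariate_names, names(newdata))
  if (length(miss)) {
    stop_danhi("danhi_missing_covariate", "missing covariate(s): %s",
               paste(miss, collapse = ", "))
  }
  eta <- drop(cbind(1, as.matrix(newdata[object$covariate_names])) %*%
                object$coefficients)
  stats::plogis(eta)
}

#' Fit the full age-threshold ensemble for one sex
#'
#' Repeats the dichotomize-fit-cutoff procedure for every model age in the
#' span (default 26..75, i.e. exactly 50 models). Models are fitted to the
#' development cohort of one sex only; cutoffs are estimated on the same
#' development predictions and frozen for later validation scoring. In
#' strict mode (default) a non-converged model aborts the fit; in
#' permissive mode such model ages are dropped and the index denominator
#' shrinks accordingly.
#'
#' @param development development cohort restricted to one sex.
#' @param sex `"male"` or `"female"`; must match the cohort.
#' @param n_min,n_max inclusive model-age span (default 26 and 75).
#' @param covariates covariate names shared by all models.
#' @param strict abort on non-convergence (`TRUE`, default) or drop the
#'   offending model ages with a message (`FALSE`).
#' @return a `threshold_ensemble`: `sex`, `n_min`, `n_max`,
#'   `covariate_names`, and `models` (one `age_threshold_model` per age).
#' @export
fit_ensemble <- function(development, sex, n_min = 26L, n_max = 75L,
                         covariates, strict = TRUE) {
  sex <- match.arg(sex, DANHI_SEXES)
  check_cohort(development, need_biomarkers = covariates)
  if (n_min > n_max) {
    stop_danhi("danhi_bad_config", "n_min must be <= n_max")
  }
  if (!all(development$sex == sex)) {
    stop_danhi("danhi_sex_mismatch",
               "development cohort contains records of the other sex")
  }
  span <- seq.int(n_min, n_max)
  ages <- development$chronological_age
  bad <- span[span <= min(ages) | span > max(ages)]
  if (length(bad)) {
    stop_danhi("danhi_empty_class",
               paste0("model age(s) %s have an empty aging-status class; ",
                      "narrow the span to [%d, %d]"),
               paste(bad, collapse = ", "), min(ages) + 1L, max(ages))
  }
  models <- lapply(span, function(n)
    fit_threshold_model(development, n, covariates))
  conv <- vapply(models, `[[`, logical(1), "converged")
  if (!all(conv)) {
    if (strict) {
      stop_danhi("danhi_nonconvergence",
                 "model age(s) %s did not converge (strict mode)",
                 paste(span[!conv], collapse = ", "))
    }
    message(sprintf("dropping non-converged model age(s): %s",
                    paste(span[!conv], collapse = ", ")))
    models <- models[conv]
  }
  structure(list(sex = sex, n_min = as.integer(n_min),
                 n_max = as.integer(n_max),
                 covariate_names = covariates, models = models),
            class = "threshold_ensemble")
}

#' @export
print.threshold_ensemble <- function(x, ...) {
  cat(sprintf("<threshold_ensemble> %s, %d models (ages %d..%d), %d covariates\n",
              x$sex, length(x$models), x$n_min, x$n_max,
              length(x$covariate_names)))
  invisible(x)
}

ensemble_model_ages <- function(ensemble) {
  vapply(ensemble$models, `[[`, integer(1), "model_age")
}

#' Score a cohort against a fitted ensemble
#'
#' For each record and each model age n, computes the probability `P_n` of
#' aging status `>= n`, the deviation `delta_n = P_n - C_n` from that
#' model's Youden cutoff, and aggregates the deviations into the
#' Differential Aging and Health Index
#' `DAnHI = sum_n(n * delta_n) / N_models` — an age-weighted mean of the
#' deviations, on a year-equivalent scale. Biological age is chronological
#' age plus DAnHI.
#'
#' @param cohort records of the ensemble's sex with all covariates present.
#' @param ensemble a fitted `threshold_ensemble`.
#' @param keep_delta if `TRUE`, the per-model delta columns
#'   (`delta_<age>`) are appended to the result.
#' @return data.frame with `id`, `chronological_age`, `danhi`,
#'   `biological_age`, and optionally the delta columns.
#' @export
score_cohort <- function(cohort, ensemble, keep_delta = FALSE) {
  stopifnot(inherits(ensemble, "threshold_ensemble"))
  check_cohort(cohort, need_biomarkers = ensemble$covariate_names)
  if (!all(cohort$sex == ensemble$sex)) {
    stop_danhi("danhi_sex_mismatch",
               "cohort sex does not match the ensemble (%s)", ensemble$sex)
  }
  ages_n <- ensemble_model_ages(ensemble)
  x <- cbind(1, as.matrix(cohort[ensemble$covariate_names]))
  beta <- vapply(ensemble$models, `[[`,
                 numeric(length(ensemble$covariate_names) + 1L),
                 "coefficients")
  p <- stats::plogis(x %*% beta)              # n_records x n_models
  cutoffs <- vapply(ensemble$models, `[[`, numeric(1), "cutoff")
  delta <- sweep(p, 2, cutoffs)
  danhi <- drop(delta %*% ages_n) / length(ages_n)
  out <- data.frame(id = cohort$id,
                    chronological_age = cohort$chronological_age,
                    danhi = danhi,
                    biological_age = cohort$chronological_age + danhi,
                    stringsAsFactors = FALSE)
  if (keep_delta) {
    colnames(delta) <- paste0("delta_", ages_n)
    out <- cbind(out, as.data.frame(delta))
  }
  out
}

#' Score a single participant
#'
#' @param record one-row data.frame (a single `ParticipantRecord`).
#' @param ensemble a fitted `threshold_ensemble`.
#' @return a `delta_profile`: `participant_id`, `model_ages`, `P`, `delta`,
#'   `danhi`, `biological_age`.
#' @export
score_profile <- function(record, ensemble) {
  stopifnot(nrow(record) == 1L)
  scored <- score_cohort(record, ensemble, keep_delta = TRUE)
  ages_n <- ensemble_model_ages(ensemble)
  delta <- as.numeric(scored[1, paste0("delta_", ages_n)])
  cutoffs <- vapply(ensemble$models, `[[`, numeric(1), "cutoff")
  structure(list(participant_id = scored$id[1],
                 model_ages = ages_n,
                 P = delta + cutoffs,
                 delta = delta,
                 danhi = scored$danhi[1],
                 chronological_age = scored$chronological_age[1],
                 biological_age = scored$biological_age[1]),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("<delta_profile> %s: CA %d, DAnHI %+.3f, BA %.2f\n",
              x$participant_id, x$chronological_age, x$danhi,
              x$biological_age))
  invisible(x)
}

#' K-means clustering of delta profiles
#'
#' Groups per-individual deviation profiles (the delta vector over model
#' ages) by Lloyd's k-means with seeded random initial centroids and
#' Euclidean distance, the standard way to surface the characteristic
#' "healthier than peers" / "stable" / "unhealthier" profile shapes.
#'
#' @param delta matrix of delta vectors (rows = participants, columns =
#'   model ages), e.g. the `delta_*` columns of [score_cohort()].
#' @param k number of clusters (default 9).
#' @param seed integer seed for centroid initialization.
#' @return a list with `assignment` (integer cluster per row), `centroids`
#'   (k x n_model_ages matrix of mean delta profiles), and `sizes`.
#' @export
cluster_profiles <- function(delta, k = 9L, seed = 1L) {
  delta <- as.matrix(delta)
  if (k < 1 || k > nrow(delta)) {
    stop_danhi("danhi_bad_config", "k must be in [1, n profiles]")
  }
  fit <- with_seed(child_seed(seed, 2L),
                   stats::kmeans(delta, centers = k, algorithm = "Lloyd",
                                 iter.max = 100L, nstart = 1L))
  list(assignment = fit$cluster, centroids = fit$centers, sizes = fit$size)
}
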