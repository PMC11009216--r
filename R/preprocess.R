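#' Classify an ICD-10 cause-of-death code
#'
#' Uses only the leading letter and two-digit number of the code (any
#' subcode suffix is ignored). Extrinsic causes — accidents, suicide,
#' infectious disease, pregnancy-related and ill-defined deaths — are the
#' ranges A00-B99, O00-O99, Q00-Q99, R95-R99, S00-T98 and V01-Y98; cancer is
#' C00-C97 and D00-D48; everything else is non-cancer.
#'
#' @param icd10_code character vector of ICD-10 codes (letter + two digits,
#'   optional suffix).
#' @return character vector in `{"cancer", "non_cancer", "extrinsic"}`.
#' @export
classify_cause <- function(icd10_code) {
  ok <- grepl("^[A-Za-z][0-9]{2}", icd10_code)
  if (any(!ok)) {
    stop_danhi("danhi_bad_icd10", "malformed ICD-10 code(s): %s",
               paste(utils::head(icd10_code[!ok], 5), collapse = ", "))
  }
  letter <- toupper(substr(icd10_code, 1, 1))
  num <- as.integer(substr(icd10_code, 2, 3))

  in_range <- function(l1, n1, l2, n2) {
    key <- match(letter, LETTERS) * 100L + num
    key >= match(l1, LETTERS) * 100L + n1 & key <= match(l2, LETTERS) * 100L + n2
  }
  extrinsic <- in_range("A", 0L, "B", 99L) | in_range("O", 0L, "O", 99L) |
    in_range("Q", 0L, "Q", 99L) | in_range("R", 95L, "R", 99L) |
    in_range("S", 0L, "T", 98L) | in_range("V", 1L, "Y", 98L)
  cancer <- in_range("C", 0L, "C", 97L) | in_range("D", 0L, "D", 48L)
  ifelse(extrinsic, "extrinsic", ifelse(cancer, "cancer", "non_cancer"))
}

#' Apply the study exclusion rules
#'
#' Removes records in the order the rules are defined: (1) age below 20
#' years, (2) prevalent chronic disease at screening, (3) death from an
#' extrinsic or unknown cause, (4) missing biomarker value. A record failing
#' several rules is counted under the first one, so the per-rule counts in
#' the report are deterministic; the retained cohort itself does not depend
#' on the ordering. If a `cause_code` column of ICD-10 codes is present it
#' is classified with [classify_cause()] and written into `cause_category`;
#' otherwise an existing `cause_category` column is used directly.
#'
#' @param cohort cohort data.frame.
#' @param biomarkers biomarker columns checked for missingness.
#' @return a list with `cohort` (retained records, original order) and
#'   `report` (an `exclusion_report`: `n_input`, `n_excluded_by_rule`,
#'   `n_retained`).
#' @export
apply_exclusions <- function(cohort, biomarkers = DANHI_BIOMARKERS) {
  check_cohort(cohort)
  biomarkers <- intersect(biomarkers, names(cohort))
  n_input <- nrow(cohort)

  if ("cause_code" %in% names(cohort)) {
    cohort$cause_category <- ifelse(
      !is.na(cohort$cause_code) & nzchar(cohort$cause_code),
      vapply(cohort$cause_code, function(cc)
        if (is.na(cc) || !nzchar(cc)) NA_character_ else classify_cause(cc),
        character(1)),
      ifelse(isTRUE_vec(cohort$died), NA_character_, "none"))
  }
  died <- isTRUE_vec(cohort$died)
  cause <- if ("cause_category" %in% names(cohort)) cohort$cause_category
           else ifelse(died, NA_character_, "none")

  fail <- cbind(
    under_20 = cohort$chronological_age < 20,
    chronic_disease = if ("chronic_disease" %in% names(cohort))
      isTRUE_vec(cohort$chronic_disease) else rep(FALSE, n_input),
    extrinsic_or_unknown_cause = died & (is.na(cause) | cause == "extrinsic"),
    missing_biomarker = if (length(biomarkers))
      rowSums(is.na(cohort[biomarkers])) > 0 else rep(FALSE, n_input)
  )
  fail[is.na(fail)] <- TRUE
  first_rule <- apply(fail, 1, function(r) if (any(r)) which(r)[1] else 0L)
  counts <- vapply(seq_len(ncol(fail)),
                   function(j) sum(first_rule == j), integer(1))
  names(counts) <- colnames(fail)

  retained <- cohort[first_rule == 0L, , drop = FALSE]
  report <- structure(list(n_input = n_input,
                           n_excluded_by_rule = as.list(counts),
                           n_retained = nrow(retained)),
                      class = "exclusion_report")
  list(cohort = retained, report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d in, %d retained\n",
              x$n_input, x$n_retained))
  for (r in names(x$n_excluded_by_rule)) {
    cat(sprintf("  %-28s %d\n", r, x$n_excluded_by_rule[[r]]))
  }
  invisible(x)
}

#' Trim extreme biomarker values
#'
#' Removes records carrying any biomarker value strictly below its lower or
#' strictly above its upper sample quantile. Quantiles use the standard
#' linear-interpolation convention (type 7) and are computed once per
#' biomarker within each sex stratum on the cohort as given — the trim is
#' not iterated. Defaults reproduce a 0.05% / 99.95% screen.
#'
#' @param cohort cohort data.frame (post other exclusions).
#' @param lower_q,upper_q quantile bounds, `0 <= lower_q < upper_q <= 1`.
#' @param biomarkers biomarker columns screened.
#' @return a list with `cohort` and an `exclusion_report` whose single rule
#'   is `biomarker_outlier`.
#' @export
trim_outliers <- function(cohort, lower_q = 0.0005, upper_q = 0.9995,
                          biomarkers = DANHI_BIOMARKERS) {
  check_cohort(cohort)
  stopifnot(lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  if (nrow(cohort) < 2) {
    stop_danhi("danhi_too_small", "need >= 2 records to define quantiles")
  }
  biomarkers <- intersect(biomarkers, names(cohort))
  drop <- rep(FALSE, nrow(cohort))
  for (s in unique(cohort$sex)) {
    idx <- which(cohort$sex == s)
    for (bm in biomarkers) {
      v <- cohort[[bm]][idx]
      qs <- stats::quantile(v, c(lower_q, upper_q), na.rm = TRUE,
                            names = FALSE, type = 7)
      drop[idx] <- drop[idx] | (!is.na(v) & (v < qs[1] | v > qs[2]))
    }
  }
  report <- structure(list(n_input = nrow(cohort),
                           n_excluded_by_rule =
                             list(biomarker_outlier = sum(drop)),
                           n_retained = sum(!drop)),
                      class = "exclusion_report")
  list(cohort = cohort[!drop, , drop = FALSE], report = report)
}

#' Split a cohort into development and validation sets
#'
#' Random split performed independently within each sex, so both sets keep
#' the cohort's sex composition; the development set receives
#' `round(dev_fraction * n)` records per sex. Seeded and reproducible.
#'
#' @param cohort cohort data.frame.
#' @param dev_fraction development fraction in (0, 1); default 0.7 (a 7:3
#'   split).
#' @param seed integer seed.
#' @return a list with `development` and `validation` data.frames (original
#'   row order preserved within each).
#' @export
split_cohort <- function(cohort, dev_fraction = 0.7, seed = 1L) {
  check_cohort(cohort)
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  if (nrow(cohort) < 2) {
    stop_danhi("danhi_too_small", "need >= 2 records to split")
  }
  dev_rows <- logical(nrow(cohort))
  with_seed(child_seed(seed, 1L), {
    for (s in unique(cohort$sex)) {
      idx <- which(cohort$sex == s)
      n_dev <- round(dev_fraction * length(idx))
      dev_rows[sample(idx, n_dev)] <- TRUE
    }
  })
  list(development = cohort[dev_rows, , drop = FALSE],
       validation = cohort[!dev_rows, , drop = FALSE])
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary
#' least-squares regression of covariate `j` on all the others (with
#' intercept). A perfectly collinear covariate is reported as `Inf`.
#'
#' @param cohort data.frame holding the covariate columns.
#' @param covariates character vector of at least two covariate names.
#' @return named numeric vector of VIFs (all `>= 1`).
#' @export
compute_vif <- function(cohort, covariates) {
  stopifnot(length(covariates) >= 2,
            all(covariates %in% names(cohort)))
  x <- as.matrix(cohort[covariates])
  if (nrow(x) <= length(covariates) + 1) {
    stop_danhi("danhi_too_small", "need n > p + 1 records for VIF")
  }
  vif <- vapply(seq_along(covariates), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- covariates
  vif
}

#' Iterative VIF-based covariate screen
#'
#' Repeatedly drops the covariate with the largest VIF at or above the
#' threshold (ties broken by input order) and recomputes, stopping when all
#' remaining VIFs are below the threshold. With the default threshold of 3,
#' a standard lipid panel loses total cholesterol to its collinearity with
#' LDL, HDL and triglycerides.
#'
#' @param cohort data.frame with the covariate columns.
#' @param covariates ordered covariate names.
#' @param threshold VIF cutoff (> 1); default 3.
#' @return a `covariate_selection`: `retained` (ordered names), `dropped`
#'   (data.frame of name + VIF at removal), `vif_threshold`, and `vif`
#'   (final VIFs of the retained set).
#' @export
select_covariates <- function(cohort, covariates = DANHI_BIOMARKERS,
                              threshold = 3) {
  stopifnot(threshold > 1)
  retained <- covariates
  dropped <- data.frame(name = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    if (length(retained) < 2) {
      stop_danhi("danhi_too_few_covariates",
                 "fewer than 2 covariates remain in the VIF screen")
    }
    vif <- compute_vif(cohort, retained)
    worst <- which(vif == max(vif))[1]  # ties: first in input order
    if (vif[worst] < threshold) break
    dropped <- rbind(dropped, data.frame(name = retained[worst],
                                         vif = unname(vif[worst])))
    retained <- retained[-worst]
  }
  structure(list(retained = retained, dropped = dropped,
                 vif_threshold = threshold,
                 vif = compute_vif(cohort, retained)),
            class = "covariate_selection")
}

#' @export
print.covariate_selection <- function(x, ...) {
  cat(sprintf("<covariate_selection> %d retained (VIF < %.2g)\n",
              length(x$retained), x$vif_threshold))
  if (nrow(x$dropped)) {
    cat("  dropped:", paste(sprintf("%s (VIF %.2f)", x$dropped$name,
                                    x$dropped$vif), collapse = ", "), "\n")
  }
  invisible(x)
}
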