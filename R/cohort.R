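#' Configure a synthetic screening cohort
#'
#' Defines the study conditions for the simulator: cohort size and
#' composition, the latent aging-acceleration factor Z, and the mortality
#' model. Conditional on age and Z the hazard is constant (exponential):
#' `lambda = exp(a + b * age + c * z)` per year, so closed-form survival
#' checks are available. Defaults give a screening-age population centred in
#' the mid-forties, a Z spread of 5 year-equivalents (the order reported
#' for biological-age-acceleration measures), an age gradient that
#' roughly doubles mortality every 8 years, and 10 years of follow-up with
#' administrative censoring, matching a national screening cohort followed
#' for a decade.
#'
#' @param n_participants number of participants to simulate.
#' @param sex_ratio fraction male, in `[0, 1]`.
#' @param age_distribution data.frame with columns `age` (integer years,
#'   within 20-85) and `weight` (non-negative sampling weights). Default:
#'   ages 20-85 weighted by a normal kernel centred at 47 (sd 14).
#' @param acceleration_sd standard deviation of the latent factor Z at age
#'   20, in year-equivalents (`>= 0`).
#' @param acceleration_growth additional Z standard deviation per year of
#'   age beyond 20 (`>= 0`, default 0): person-to-person heterogeneity in
#'   aging can widen with age.
#' @param hazard_params named numeric vector `c(a = , b = , c = )`: baseline
#'   log-hazard, log-hazard slope per year of age, log-hazard slope per unit Z.
#' @param cancer_fraction fraction of (non-extrinsic) deaths assigned a
#'   cancer cause, independent of Z.
#' @param extrinsic_fraction fraction of deaths assigned an extrinsic cause
#'   (accidents etc.); default 0. Provided so exclusion rules can be
#'   exercised on simulated data.
#' @param chronic_fraction fraction of participants flagged with prevalent
#'   chronic disease at screening; default 0.
#' @param admin_censor_years administrative censoring horizon (years, > 0).
#' @param seed integer root seed; all generator randomness derives from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants,
                              sex_ratio = 0.5,
                              age_distribution = NULL,
                              acceleration_sd = 5,
                              acceleration_growth = 0,
                              hazard_params = c(a = -10, b = 0.09, c = 0.09),
                              cancer_fraction = 0.35,
                              extrinsic_fraction = 0,
                              chronic_fraction = 0,
                              admin_censor_years = 10,
                              seed = 1L) {
  if (is.null(age_distribution)) {
    ages <- 20:85
    age_distribution <- data.frame(age = ages,
                                   weight = stats::dnorm(ages, 47, 14))
  }
  stopifnot(is.data.frame(age_distribution),
            all(c("age", "weight") %in% names(age_distribution)),
            all(age_distribution$weight >= 0),
            sum(age_distribution$weight) > 0)
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 1) {
    stop_danhi("danhi_bad_config", "n_participants must be >= 1")
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    stop_danhi("danhi_bad_config", "sex_ratio must be in [0, 1]")
  }
  if (acceleration_sd < 0 || acceleration_growth < 0) {
    stop_danhi("danhi_bad_config",
               "acceleration_sd and acceleration_growth must be >= 0")
  }
  if (admin_censor_years <= 0) {
    stop_danhi("danhi_bad_config", "admin_censor_years must be > 0")
  }
  hp <- as.numeric(hazard_params[c("a", "b", "c")])
  if (any(is.na(hp))) {
    stop_danhi("danhi_bad_config",
               "hazard_params must be named c(a = , b = , c = )")
  }
  structure(list(n_participants = as.integer(n_participants),
                 sex_ratio = sex_ratio,
                 age_distribution = age_distribution,
                 acceleration_sd = acceleration_sd,
                 acceleration_growth = acceleration_growth,
                 hazard_params = c(a = hp[1], b = hp[2], c = hp[3]),
                 cancer_fraction = cancer_fraction,
                 extrinsic_fraction = extrinsic_fraction,
                 chronic_fraction = chronic_fraction,
                 admin_censor_years = admin_censor_years,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw survival times under an exponential-in-covariates hazard
#'
#' The conditional hazard is constant over time:
#' `lambda = exp(a + b * age + c * z)` per year. The uncensored time is an
#' Exponential(`lambda`) draw; follow-up is censored administratively at
#' `admin_censor_years`. Uses the current RNG stream; seed at the call site
#' for reproducibility.
#'
#' @param age chronological age (years), vectorised.
#' @param z latent acceleration value, vectorised.
#' @param hazard_params named vector `c(a, b, c)` of log-hazard parameters.
#' @param admin_censor_years censoring horizon in years.
#' @return a data.frame with columns `time` (years) and `died` (logical).
#' @export
survival_time <- function(age, z, hazard_params, admin_censor_years = 10) {
  lambda <- exp(hazard_params[["a"]] + hazard_params[["b"]] * age +
                  hazard_params[["c"]] * z)
  if (any(!is.finite(lambda))) {
    stop_danhi("danhi_bad_hazard", "non-finite hazard rate")
  }
  n <- length(lambda)
  draw <- ifelse(lambda > 0, stats::rexp(n, rate = pmax(lambda, 1e-300)), Inf)
  died <- draw < admin_censor_years
  data.frame(time = pmin(draw, admin_censor_years), died = died)
}

#' Generate a synthetic health-screening cohort
#'
#' Simulates one screening visit plus mortality follow-up for
#' `n_participants`. Each biomarker value is
#' `mean_fn(age) + loading * Z + Normal(0, sd_fn(age))` from that
#' biomarker/sex trajectory template, with total cholesterol derived from
#' the other lipids (Friedewald-style) plus noise. Survival is drawn from
#' the configured exponential hazard in age and Z, censored at the
#' administrative horizon; among deaths, causes are assigned extrinsic,
#' cancer, or non-cancer per the configured fractions. Identical
#' `(config, templates)` always yield an identical cohort.
#'
#' @param config a [simulation_config()].
#' @param templates named list of [trajectory_template()]s covering every
#'   panel biomarker for both sexes; defaults to [default_templates()].
#' @return a data.frame with one row per participant: `id`, `sex`,
#'   `chronological_age`, the 14 biomarker columns, `chronic_disease`,
#'   `followup_years`, `died`, `cause_category` (`"cancer"`, `"non_cancer"`,
#'   `"extrinsic"` or `"none"`), and `latent_z` (simulation truth, ignored
#'   by all fitting functions).
#' @export
generate_cohort <- function(config, templates = default_templates()) {
  if (!inherits(config, "simulation_config")) {
    stop_danhi("danhi_bad_config", "config must be a simulation_config")
  }
  need <- as.vector(outer(DANHI_BIOMARKERS, DANHI_SEXES, paste, sep = "."))
  missing_t <- setdiff(need, names(templates))
  if (length(missing_t)) {
    stop_danhi("danhi_missing_template",
               "missing trajectory templates: %s",
               paste(missing_t, collapse = ", "))
  }

  n <- config$n_participants
  with_seed(child_seed(config$seed, 0L), {
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    age <- sample(config$age_distribution$age, n, replace = TRUE,
                  prob = config$age_distribution$weight)
    sd_z <- config$acceleration_sd +
      config$acceleration_growth * pmax(0, age - 20)
    z <- stats::rnorm(n, 0, sd_z)

    bio <- matrix(NA_real_, n, length(DANHI_BIOMARKERS),
                  dimnames = list(NULL, DANHI_BIOMARKERS))
    measured <- setdiff(DANHI_BIOMARKERS, "TCHOL")
    for (bm in measured) {
      for (s in DANHI_SEXES) {
        idx <- which(sex == s)
        if (!length(idx)) next
        tpl <- templates[[paste(bm, s, sep = ".")]]
        mu <- trajectory_mean(tpl, age[idx]) + tpl$loading * z[idx]
        bio[idx, bm] <- stats::rnorm(length(idx), mu,
                                     trajectory_sd(tpl, age[idx]))
      }
    }
    # TCHOL follows the Friedewald relation plus assay noise, so the lipid
    # block is genuinely multicollinear as in real panels.
    for (s in DANHI_SEXES) {
      idx <- which(sex == s)
      if (!length(idx)) next
      tpl <- templates[[paste("TCHOL", s, sep = ".")]]
      bio[idx, "TCHOL"] <- bio[idx, "LDL"] + bio[idx, "HDL"] +
        bio[idx, "TG"] / 5 +
        stats::rnorm(length(idx), 0, trajectory_sd(tpl, age[idx]))
    }

    surv <- survival_time(age, z, config$hazard_params,
                          config$admin_censor_years)
    cause <- rep("none", n)
    dead <- which(surv$died)
    if (length(dead)) {
      u <- stats::runif(length(dead))
      cause[dead] <- ifelse(
        u < config$extrinsic_fraction, "extrinsic",
        ifelse(stats::runif(length(dead)) < config$cancer_fraction,
               "cancer", "non_cancer"))
    }
    chronic <- stats::runif(n) < config$chronic_fraction

    out <- data.frame(id = sprintf("P%07d", seq_len(n)),
                      sex = sex,
                      chronological_age = as.integer(age),
                      chronic_disease = chronic,
                      followup_years = surv$time,
                      died = surv$died,
                      cause_category = cause,
                      latent_z = z,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(bio))
  })
}

#' Write / read a cohort as delimited text
#'
#' Cohorts are exchanged as comma-separated text with a header row. The
#' hidden simulation truth `latent_z` is written to a separate truth file so
#' analysis inputs never carry it.
#'
#' @param cohort a cohort data.frame.
#' @param path CSV path for the cohort (without `latent_z`).
#' @param truth_path optional CSV path for `id` + `latent_z`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  check_cohort(cohort)
  keep <- setdiff(names(cohort), "latent_z")
  utils::write.csv(cohort[keep], path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && "latent_z" %in% names(cohort)) {
    utils::write.csv(cohort[c("id", "latent_z")], truth_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_path = NULL) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    cohort <- merge(cohort, truth, by = "id", sort = FALSE)
  }
  check_cohort(cohort)
}
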