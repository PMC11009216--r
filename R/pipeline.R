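SCHEMA_VERSION <- "1.0"

num_to_str <- function(x) sprintf("%.17g", x)

# FNV-1a hash of the serialized config; stamps artifacts so reruns are
# auditable without external digest libraries.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Serialize / load a fitted ensemble
#'
#' Ensembles are stored as versioned JSON with coefficients and cutoffs
#' encoded as full-precision decimal strings, so a save/load round trip
#' reproduces scores to the last bit. Documents with unknown extra fields
#' load with a warning (forward compatibility); truncated or
#' wrong-version documents raise a schema error.
#'
#' @param ensemble a `threshold_ensemble`.
#' @param path file path; for [serialize_ensemble()] `NULL` returns the
#'   document as a list instead of writing.
#' @return [serialize_ensemble()]: the document (invisibly when written);
#'   [load_ensemble()]: the restored `threshold_ensemble`.
#' @export
serialize_ensemble <- function(ensemble, path = NULL) {
  stopifnot(inherits(ensemble, "threshold_ensemble"))
  doc <- list(
    schema_version = SCHEMA_VERSION,
    type = "threshold_ensemble",
    sex = ensemble$sex,
    n_min = ensemble$n_min, n_max = ensemble$n_max,
    covariate_names = ensemble$covariate_names,
    models = lapply(ensemble$models, function(m) {
      list(model_age = m$model_age,
           coefficients = num_to_str(m$coefficients),
           cutoff = num_to_str(m$cutoff),
           youden_j = num_to_str(m$youden_j),
           n_below = m$n_below, n_at_or_above = m$n_at_or_above,
           converged = m$converged)
    }))
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(doc))
  }
  doc
}

#' @rdname serialize_ensemble
#' @param document a list as produced by [serialize_ensemble()]; ignored
#'   when `path` is given.
#' @export
load_ensemble <- function(path = NULL, document = NULL) {
  doc <- if (!is.null(path)) {
    tryCatch(jsonlite::read_json(path),
             error = function(e) stop_danhi(
               "danhi_schema_error", "unreadable ensemble document: %s",
               conditionMessage(e)))
  } else document
  required <- c("schema_version", "type", "sex", "n_min", "n_max",
                "covariate_names", "models")
  if (!is.list(doc) || !all(required %in% names(doc))) {
    stop_danhi("danhi_schema_error",
               "ensemble document is missing required fields")
  }
  if (!identical(as.character(doc$schema_version), SCHEMA_VERSION)) {
    stop_danhi("danhi_schema_error", "unsupported schema version '%s'",
               as.character(doc$schema_version))
  }
  extra <- setdiff(names(doc), required)
  if (length(extra)) {
    warning(sprintf("ignoring unknown ensemble fields: %s",
                    paste(extra, collapse = ", ")))
  }
  covs <- as.character(unlist(doc$covariate_names))
  models <- lapply(doc$models, function(m) {
    need <- c("model_age", "coefficients", "cutoff")
    if (!all(need %in% names(m))) {
      stop_danhi("danhi_schema_error", "truncated model entry")
    }
    coefs <- as.numeric(unlist(m$coefficients))
    if (length(coefs) != length(covs) + 1L || anyNA(coefs)) {
      stop_danhi("danhi_schema_error", "bad coefficient vector")
    }
    names(coefs) <- c("(Intercept)", covs)
    structure(list(model_age = as.integer(m$model_age),
                   coefficients = coefs,
                   covariate_names = covs,
                   cutoff = as.numeric(m$cutoff),
                   youden_j = if (is.null(m$youden_j)) NA_real_
                              else as.numeric(m$youden_j),
                   n_below = if (is.null(m$n_below)) NA_integer_
                             else as.integer(m$n_below),
                   n_at_or_above = if (is.null(m$n_at_or_above)) NA_integer_
                                   else as.integer(m$n_at_or_above),
                   converged = isTRUE(as.logical(m$converged))),
              class = "age_threshold_model")
  })
  structure(list(sex = match.arg(doc$sex, DANHI_SEXES),
                 n_min = as.integer(doc$n_min),
                 n_max = as.integer(doc$n_max),
                 covariate_names = covs, models = models),
            class = "threshold_ensemble")
}

#' Run the full simulate-cleanse-fit-score-evaluate pipeline
#'
#' Orchestrates one end-to-end run: obtain a cohort (simulated or read from
#' CSV), apply the exclusion rules and outlier trim, screen covariates by
#' VIF, split development/validation per sex, fit the per-sex threshold
#' ensembles on development data, score the validation cohort, and run the
#' subgroup mortality evaluation. All artifacts are written to `out_dir`
#' as JSON/CSV, stamped with the seed and a config hash; a rerun with the
#' same config reproduces identical artifacts.
#'
#' @param config named list (or path to a JSON file) with fields:
#'   `simulate` (arguments to [simulation_config()]) or `input` (cohort CSV
#'   path); optional `covariates` (default: full panel), `n_min`, `n_max`
#'   (default 26/75), `dev_fraction` (0.7), `seed` (1), `event_types`,
#'   `horizons`, `strict`, `out_dir` (required).
#' @return invisibly, a list with the in-memory artifacts (`cohort`,
#'   `exclusions`, `selection`, `ensembles`, `scores`, `evaluation`) and
#'   the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  cfg <- utils::modifyList(
    list(covariates = DANHI_BIOMARKERS, n_min = 26L, n_max = 75L,
         dev_fraction = 0.7, seed = 1L, vif_threshold = 3,
         event_types = c("total", "cancer", "non_cancer"),
         horizons = 1:10, strict = TRUE, out_dir = NULL),
    config)
  if (is.null(cfg$out_dir)) {
    stop_danhi("danhi_bad_config", "config$out_dir is required")
  }
  if (cfg$n_min > cfg$n_max) {
    stop_danhi("danhi_bad_config", "n_min must be <= n_max")
  }
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop_danhi("danhi_bad_config", "config needs either simulate or input")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                schema_version = SCHEMA_VERSION)
  paths <- list()
  wjson <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    jsonlite::write_json(c(list(stamp = stamp), obj), p,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    p
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[danhi] stage=%s seed=%s %s", stage, cfg$seed,
                    sprintf(...)))
  }

  stage <- function(name, expr) {
    tryCatch(expr, danhi_error = function(e) {
      stop_danhi("danhi_pipeline_failure", "stage '%s' failed: %s", name,
                 conditionMessage(e))
    })
  }

  cohort <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      if (!is.null(sim_args$age_distribution)) {
        sim_args$age_distribution <-
          as.data.frame(lapply(sim_args$age_distribution, unlist))
      }
      if (!is.null(sim_args$hazard_params)) {
        sim_args$hazard_params <- unlist(sim_args$hazard_params)
      }
      generate_cohort(do.call(simulation_config, sim_args))
    } else {
      read_cohort(cfg$input)
    }
  })
  log_stage("input", "records=%d", nrow(cohort))

  excl <- stage("exclusions", apply_exclusions(cohort, cfg$covariates))
  trim <- stage("outlier_trim", trim_outliers(excl$cohort,
                                              biomarkers = cfg$covariates))
  cohort <- trim$cohort
  log_stage("cleanse", "records_out=%d", nrow(cohort))
  paths$exclusions <- wjson(list(exclusions = unclass(excl$report),
                                 outlier_trim = unclass(trim$report)),
                            "exclusion_report.json")

  selection <- stage("covariate_selection",
                     select_covariates(cohort, cfg$covariates,
                                       cfg$vif_threshold))
  paths$selection <- wjson(list(retained = selection$retained,
                                dropped = selection$dropped,
                                vif_threshold = selection$vif_threshold,
                                vif = as.list(selection$vif)),
                           "covariate_selection.json")
  log_stage("covariates", "retained=%d dropped=%d",
            length(selection$retained), nrow(selection$dropped))

  split <- stage("split", split_cohort(cohort, cfg$dev_fraction, cfg$seed))

  ensembles <- list()
  for (s in intersect(DANHI_SEXES, unique(cohort$sex))) {
    dev_s <- split$development[split$development$sex == s, , drop = FALSE]
    ensembles[[s]] <- stage(paste0("fit_", s),
                            fit_ensemble(dev_s, s, cfg$n_min, cfg$n_max,
                                         selection$retained,
                                         strict = isTRUE(cfg$strict)))
    p <- file.path(cfg$out_dir, sprintf("ensemble_%s.json", s))
    serialize_ensemble(ensembles[[s]], p)
    paths[[paste0("ensemble_", s)]] <- p
    log_stage(paste0("fit_", s), "models=%d dev_n=%d",
              length(ensembles[[s]]$models), nrow(dev_s))
  }

  scores <- stage("score", do.call(rbind, lapply(names(ensembles), function(s) {
    val_s <- split$validation[split$validation$sex == s, , drop = FALSE]
    sc <- score_cohort(val_s, ensembles[[s]])
    sc$sex <- s
    sc
  })))
  paths$scores <- file.path(cfg$out_dir, "scores.csv")
  utils::write.csv(scores, paths$scores, row.names = FALSE, quote = FALSE)
  log_stage("score", "validation_n=%d", nrow(scores))

  evaluation <- stage("evaluate",
                      evaluate_suite(split$validation, ensembles,
                                     development = split$development,
                                     event_types = cfg$event_types,
                                     horizons = cfg$horizons))
  paths$evaluation <- wjson(
    list(by_sex = evaluation$by_sex,
         scoring = lapply(evaluation$scoring, function(x)
           x[c("n", "median_positive_danhi")])),
    "evaluation.json")
  log_stage("evaluate", "done")

  invisible(list(cohort = cohort, exclusions = excl$report,
                 outlier_trim = trim$report, selection = selection,
                 split = split, ensembles = ensembles, scores = scores,
                 evaluation = evaluation, paths = paths, stamp = stamp))
}
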