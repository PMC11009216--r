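# Shared fixture builders: everything is generated in code at test time.

panel_covariates <- function() setdiff(danhi:::DANHI_BIOMARKERS, "TCHOL")

small_cohort <- function(n = 2000, seed = 11, sex_ratio = 0.5, ...) {
  generate_cohort(simulation_config(n, sex_ratio = sex_ratio, seed = seed,
                                    ...))
}

# Minimal hand-built cohort frame for unit tests that do not need the
# generator's structure.
toy_cohort <- function(age, sex = rep("male", length(age)),
                       followup = rep(5, length(age)),
                       died = rep(FALSE, length(age)),
                       cause = ifelse(died, "non_cancer", "none")) {
  n <- length(age)
  df <- data.frame(id = sprintf("T%03d", seq_len(n)), sex = sex,
                   chronological_age = age, followup_years = followup,
                   died = died, cause_category = cause,
                   stringsAsFactors = FALSE)
  df
}

# Brute-force Youden maximization: J is piecewise constant in the cutoff and
# can only change at observed probability values, so scanning every observed
# value plus one point above the maximum enumerates all achievable J.
youden_j_exhaustive <- function(probs, labels) {
  labels <- as.integer(as.logical(labels))
  thresholds <- c(sort(unique(probs)), max(probs) + 1)
  max(vapply(thresholds, function(t) {
    sum(probs >= t & labels == 1L) / sum(labels == 1L) +
      sum(probs < t & labels == 0L) / sum(labels == 0L) - 1
  }, numeric(1)))
}

# Exhaustive pairwise AUC (ties count 1/2).
auc_pairwise <- function(cases, controls) {
  s <- 0
  for (x in cases) s <- s + sum(x > controls) + 0.5 * sum(x == controls)
  s / (length(cases) * length(controls))
}
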