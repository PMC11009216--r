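#' @keywords internal
"_PACKAGE"

# Biomarker panel: the 14 measured screening columns (TCHOL is measured but
# usually removed by the VIF screen before modelling).
DANHI_BIOMARKERS <- c("BMI", "WST", "SBP", "DBP", "FBS", "TCHOL", "TG",
                      "HDL", "LDL", "HGB", "CR", "AST", "ALT", "GGTP")

DANHI_SEXES <- c("male", "female")

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Stages draw
#' child seeds with `child_seed(seed, k)` for fixed small stage indices `k`,
#' so each stage (cohort generation, split, clustering, ...) is reproducible
#' in isolation and independent of how many random draws earlier stages made.
#' The map is a Lehmer step modulo the Mersenne prime 2^31 - 1, keeping every
#' derived seed a valid 32-bit R integer.
#'
#' @param seed integer root seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(k + 1L)) {
    s <- (s * 48271 + 11) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never perturb
# user-level random streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_danhi <- function(code, msg, ...) {
  stop(structure(class = c(code, "danhi_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_cohort <- function(cohort, need_biomarkers = character(),
                         need_survival = FALSE) {
  if (!is.data.frame(cohort)) {
    stop_danhi("danhi_bad_input", "cohort must be a data.frame")
  }
  base_cols <- c("id", "sex", "chronological_age")
  missing_cols <- setdiff(c(base_cols, need_biomarkers), names(cohort))
  if (need_survival) {
    missing_cols <- c(missing_cols,
                      setdiff(c("followup_years", "died"), names(cohort)))
  }
  if (length(missing_cols)) {
    stop_danhi("danhi_bad_input", "cohort is missing columns: %s",
               paste(unique(missing_cols), collapse = ", "))
  }
  invisible(cohort)
}
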