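#' Trajectory templates for the synthetic cohort generator
#'
#' A trajectory template describes how one biomarker behaves over adult life
#' in one sex: its mean and standard deviation as piecewise-linear functions
#' of age (four knots between ages 20 and 85), and a loading that couples the
#' latent aging-acceleration factor Z (in year-equivalents) to deviations of
#' this biomarker. A loading roughly equal to the biomarker's per-year slope
#' makes one unit of Z shift the biomarker like one extra year of aging.
#'
#' @param biomarker biomarker name (one of the screening panel).
#' @param sex `"male"` or `"female"`.
#' @param knot_ages increasing ages (years) of the interpolation knots.
#' @param knot_means biomarker mean at each knot (biomarker units).
#' @param knot_sds positive standard deviation at each knot.
#' @param loading unitless coefficient linking Z to this biomarker.
#' @param derived logical; if `TRUE` the biomarker is computed from other
#'   biomarkers at generation time (TCHOL) and the knots are ignored.
#' @return an object of class `trajectory_template`.
#' @export
trajectory_template <- function(biomarker, sex, knot_ages, knot_means,
                                knot_sds, loading, derived = FALSE) {
  stopifnot(length(knot_ages) == length(knot_means),
            length(knot_ages) == length(knot_sds),
            !is.unsorted(knot_ages, strictly = TRUE),
            all(knot_sds > 0))
  sex <- match.arg(sex, DANHI_SEXES)
  structure(list(biomarker = biomarker, sex = sex,
                 knot_ages = as.numeric(knot_ages),
                 knot_means = as.numeric(knot_means),
                 knot_sds = as.numeric(knot_sds),
                 loading = as.numeric(loading),
                 derived = isTRUE(derived)),
            class = "trajectory_template")
}

#' @export
print.trajectory_template <- function(x, ...) {
  cat(sprintf("<trajectory_template> %s (%s), loading %.3g%s\n",
              x$biomarker, x$sex, x$loading,
              if (x$derived) ", derived" else ""))
  invisible(x)
}

# Piecewise-linear interpolation, constant beyond the outer knots.
trajectory_mean <- function(template, age) {
  stats::approx(template$knot_ages, template$knot_means, xout = age,
                rule = 2)$y
}

trajectory_sd <- function(template, age) {
  stats::approx(template$knot_ages, template$knot_sds, xout = age,
                rule = 2)$y
}

#' Default biomarker trajectory templates
#'
#' Hand-tuned piecewise-linear trajectories (four knots per biomarker and
#' sex) reproducing the qualitative age patterns seen in large screening
#' cohorts: triglycerides rise into the late thirties and then decline in
#' men while rising monotonically in women; systolic blood pressure rises
#' with age in both sexes; BMI is inverted-U with a mid-thirties peak in men
#' and a mid-sixties peak in women; haemoglobin declines steadily in men and
#' fluctuates in women; waist circumference rises more steeply in women.
#' Total cholesterol is marked derived: the generator computes it as
#' LDL + HDL + TG/5 plus measurement noise, so the panel carries the
#' lipid multicollinearity that covariate screening is designed to detect.
#'
#' @return a named list of `trajectory_template` objects keyed
#'   `"<biomarker>.<sex>"`, covering all 14 panel biomarkers for both sexes.
#' @export
default_templates <- function() {
  # Loadings are scaled so that at the default Z spread (3 year-equivalents)
  # the latent acceleration explains roughly 15% of the age-adjusted variance
  # of each mortality-relevant biomarker (loading ~ 0.14 * mid-age sd), with
  # signs pointing toward "worse health": higher pressure, glucose, lipids,
  # adiposity and liver enzymes, lower HDL and haemoglobin. This encodes the
  # premise the index exploits - a sizeable share of between-person biomarker
  # variance at a given age is stable physiology linked to mortality.
  spec <- list(
    # biomarker, sex, knot ages, means, sds, loading
    list("BMI",  "male",   c(20, 35, 60, 85), c(22.8, 24.6, 24.2, 22.8), c(3.0, 3.2, 3.1, 3.0), 0.43),
    list("BMI",  "female", c(20, 45, 65, 85), c(21.4, 23.3, 24.6, 23.8), c(3.1, 3.2, 3.3, 3.2), 0.45),
    list("WST",  "male",   c(20, 40, 60, 85), c(79, 84.5, 86.5, 87.5),   c(7.5, 8, 8, 8.5),     1.12),
    list("WST",  "female", c(20, 40, 60, 85), c(69, 74, 80, 85),         c(7.5, 8, 8.5, 9),     1.16),
    list("SBP",  "male",   c(20, 40, 60, 85), c(119, 121, 126, 133),     c(11, 12, 13, 15),     1.75),
    list("SBP",  "female", c(20, 40, 60, 85), c(109, 114, 125, 136),     c(11, 12, 14, 16),     1.85),
    list("DBP",  "male",   c(20, 40, 60, 85), c(73, 77, 79, 77),         c(8, 9, 9, 9),         1.22),
    list("DBP",  "female", c(20, 40, 60, 85), c(69, 72, 76, 75),         c(8, 9, 9, 9),         1.22),
    list("FBS",  "male",   c(20, 40, 60, 85), c(88, 94, 101, 105),       c(12, 15, 18, 18),     2.2),
    list("FBS",  "female", c(20, 40, 60, 85), c(84, 89, 98, 104),        c(10, 13, 17, 18),     2.0),
    list("TG",   "male",   c(20, 39, 60, 85), c(108, 168, 150, 132),     c(55, 70, 65, 60),     9.0),
    list("TG",   "female", c(20, 40, 60, 85), c(74, 92, 120, 136),       c(35, 45, 60, 65),     7.0),
    list("HDL",  "male",   c(20, 40, 60, 85), c(52.5, 51, 51, 52),       c(11, 12, 12, 12),     -1.65),
    list("HDL",  "female", c(20, 40, 60, 85), c(58.5, 57.5, 56, 55),     c(12, 12, 13, 13),     -1.75),
    list("LDL",  "male",   c(20, 40, 60, 85), c(108, 124, 121, 113),     c(26, 29, 29, 28),     3.9),
    list("LDL",  "female", c(20, 45, 62, 85), c(104, 118, 134, 128),     c(25, 28, 31, 30),     3.9),
    list("HGB",  "male",   c(20, 40, 60, 85), c(15.7, 15.5, 15.0, 13.9), c(1.0, 1.0, 1.1, 1.3), -0.15),
    list("HGB",  "female", c(20, 40, 55, 85), c(13.0, 12.7, 13.2, 12.9), c(1.1, 1.2, 1.1, 1.2), -0.16),
    list("CR",   "male",   c(20, 40, 60, 85), c(0.95, 0.97, 1.00, 1.06), c(0.14, 0.14, 0.15, 0.18), 0.021),
    list("CR",   "female", c(20, 40, 60, 85), c(0.74, 0.75, 0.78, 0.83), c(0.11, 0.11, 0.12, 0.15), 0.017),
    list("AST",  "male",   c(20, 40, 60, 85), c(23, 26, 27.5, 28.5),     c(7, 9, 10, 10),       1.26),
    list("AST",  "female", c(20, 40, 60, 85), c(19.5, 20.5, 24, 26),     c(5.5, 6.5, 8, 9),     1.0),
    list("ALT",  "male",   c(20, 38, 60, 85), c(25, 29, 26, 21.5),       c(11, 14, 12, 10),     1.7),
    list("ALT",  "female", c(20, 45, 62, 85), c(15.5, 17.5, 21, 19.5),   c(7, 8, 10, 9),        1.2),
    list("GGTP", "male",   c(20, 45, 60, 85), c(33, 46, 43, 36),         c(18, 26, 25, 22),     3.5),
    list("GGTP", "female", c(20, 45, 60, 85), c(15.5, 17.5, 22, 24),     c(7, 9, 12, 13),       1.4),
    list("TCHOL", "male",  c(20, 40, 60, 85), c(182, 208, 202, 191),     c(5, 5, 5, 5),         0),
    list("TCHOL", "female", c(20, 45, 62, 85), c(177, 194, 214, 210),    c(5, 5, 5, 5),         0)
  )
  out <- lapply(spec, function(s) {
    trajectory_template(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]],
                        derived = identical(s[[1]], "TCHOL"))
  })
  names(out) <- vapply(out, function(t) paste(t$biomarker, t$sex, sep = "."),
                       character(1))
  out
}
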