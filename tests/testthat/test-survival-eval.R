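scored_cohort <- function(n = 3000, seed = 1, c_slope = 0.09) {
  coh <- generate_cohort(simulation_config(
    n, sex_ratio = 1, seed = seed,
    hazard_params = c(a = -10, b = 0.09, c = c_slope)))
  sp <- split_cohort(coh, 0.7, seed)
  ens <- fit_ensemble(sp$development, "male", 26, 75, panel_covariates())
  val <- sp$validation
  sc <- score_cohort(val, ens)
  val$danhi <- sc$danhi
  val$biological_age <- sc$biological_age
  val
}

test_that("Cox fit recovers a constructed log-hazard and flags degeneracy", {
  # hazard proportional to exp(0.1 * danhi) by construction
  covered <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    n <- 20000
    danhi <- stats::rnorm(n, 0, 2)
    st <- survival_time(rep(0, n), danhi / 0.09 * 0.1,
                        c(a = -4.2, b = 0, c = 0.09), 10)
    coh <- toy_cohort(age = rep(50, n), followup = st$time, died = st$died)
    coh$danhi <- danhi
    f <- fit_cox(coh, "DAnHI")
    f$ci_lower[1] <= exp(0.1) && exp(0.1) <= f$ci_upper[1]
  }, logical(1))
  expect_gte(mean(covered), 0.84)  # nominal 95% coverage, 25 replicates

  # null covariate: CI covers 1 at roughly the nominal rate
  covered0 <- vapply(1:25, function(s) {
    set.seed(2000 + s)
    n <- 4000
    st <- survival_time(rep(0, n), rep(0, n), c(a = -3.5, b = 0, c = 0), 10)
    coh <- toy_cohort(age = rep(50, n), followup = st$time, died = st$died)
    coh$danhi <- stats::rnorm(n)
    f <- fit_cox(coh, "DAnHI")
    f$ci_lower[1] <= 1 && 1 <= f$ci_upper[1]
  }, logical(1))
  expect_gte(mean(covered0), 0.84)

  val <- scored_cohort(seed = 3)
  val$danhi2 <- val$danhi
  expect_error(fit_cox(val, "custom", covariates = c("danhi", "danhi2")),
               class = "danhi_degenerate_design")
  val0 <- val; val0$died <- FALSE; val0$cause_category <- "none"
  expect_error(fit_cox(val0, "CA"), class = "danhi_no_events")
})

test_that("cause-specific fits censor competing deaths", {
  val <- scored_cohort(4000, seed = 5)
  f_cancer <- fit_cox(val, "CA", event_type = "cancer")
  f_total <- fit_cox(val, "CA", event_type = "total")
  expect_equal(f_cancer$n_events, sum(val$died & val$cause_category == "cancer"))
  expect_gt(f_total$n_events, f_cancer$n_events)
})

test_that("HR ratio arithmetic matches its definition", {
  expect_equal(round(hr_ratio_percent(1.097, 1.105), 1), 92.4)
  expect_equal(hr_ratio_percent(1.0, 1.2), 0)
  expect_equal(round(hr_ratio_percent(1.035, 1.251), 1), 13.9)
  # exact rational arithmetic up to floating point
  a <- 1.3178; b <- 1.0423
  expect_lt(abs(hr_ratio_percent(a, b) - (a - 1) / (b - 1) * 100), 1e-9)
  expect_error(hr_ratio_percent(1.1, 1.0), class = "danhi_undefined_ratio")
})

test_that("risk groups follow the positive-median rule", {
  rg <- assign_risk_groups(c(-1, 0, 0.5, 1, 2))
  expect_equal(rg$median_positive, 1)
  expect_identical(as.character(rg$group),
                   c("low", "low", "medium", "high", "high"))
  expect_error(assign_risk_groups(c(-2, -1, 0)), class = "danhi_no_positive")

  # threshold frozen from development, applied to new values
  rg2 <- assign_risk_groups(c(-1, 0, 0.5, 1, 2), c(0.75, 1.5, -3))
  expect_identical(as.character(rg2$group), c("medium", "high", "low"))

  # group shares on a large sample follow the counting oracle
  set.seed(9)
  d <- stats::rnorm(20000, 0.2, 1)
  rg3 <- assign_risk_groups(d)
  expect_equal(sum(rg3$group == "low"), sum(d <= 0))
  med <- stats::median(d[d > 0])
  expect_equal(sum(rg3$group == "medium"), sum(d > 0 & d < med))
  expect_equal(sum(rg3$group == "high"), sum(d >= med))
})

test_that("log-rank matches a hand-tabulated two-group instance", {
  # all event times distinct; hypergeometric tabulation done by hand below
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  died <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  grp <- c("A", "B", "A", "B", "A", "B", "A", "B")
  coh <- toy_cohort(age = rep(50, 8), followup = time, died = died)
  res <- km_logrank(coh, grp)

  o_a <- 0; e_a <- 0; v <- 0
  for (i in seq_along(time)) {
    if (!died[i]) next
    at_risk <- time >= time[i]
    n <- sum(at_risk); n_a <- sum(at_risk & grp == "A")
    o_a <- o_a + (grp[i] == "A")
    e_a <- e_a + n_a / n
    v <- v + n_a / n * (1 - n_a / n)  # one event per time, no tie term
  }
  expect_equal(res$logrank_chisq, (o_a - e_a)^2 / v, tolerance = 1e-10)
  expect_equal(res$logrank_p,
               stats::pchisq((o_a - e_a)^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("KM curves are valid step functions; no-event groups stay flat", {
  val <- scored_cohort(2000, seed = 7)
  rg <- assign_risk_groups(val$danhi)
  res <- km_logrank(val, rg$group)
  for (g in unique(res$curves$group)) {
    s <- res$curves$survival[res$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # group with no events: flat at 1
  coh <- toy_cohort(age = rep(40, 40), followup = rep(c(2, 8), 20),
                    died = rep(c(TRUE, FALSE), c(10, 30)))
  grp <- rep(c("ev", "none"), each = 20)
  coh$died[21:40] <- FALSE
  coh$cause_category[21:40] <- "none"
  res2 <- km_logrank(coh, grp)
  expect_true(all(res2$curves$survival[res2$curves$group == "none"] == 1))
  expect_error(km_logrank(coh, rep("one", 40)), class = "danhi_single_group")
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(11)
  t_ev <- stats::rexp(300, 0.2)
  coh <- toy_cohort(age = rep(50, 300), followup = t_ev,
                    died = rep(TRUE, 300))
  sf <- survival::survfit(survival::Surv(followup_years, died) ~ 1,
                          data = coh)
  emp <- vapply(sf$time, function(tt) mean(t_ev > tt), numeric(1))
  expect_equal(sf$surv, emp, tolerance = 1e-12)
})

test_that("log-rank type-I error is near nominal under a shared hazard", {
  p <- vapply(1:1000, function(s) {
    set.seed(4000 + s)
    st <- survival_time(rep(0, 300), rep(0, 300),
                        c(a = log(0.05), b = 0, c = 0), 10)
    coh <- toy_cohort(age = rep(50, 300), followup = st$time, died = st$died)
    km_logrank(coh, rep(c("g1", "g2"), 150))$logrank_p
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("horizon AUC equals exhaustive pair enumeration", {
  # worked instance: cases {0.9, 0.7}, controls {0.8, 0.2, 0.1}
  coh <- toy_cohort(age = rep(50, 5),
                    followup = c(3, 6, 10, 10, 10),
                    died = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  res <- horizon_auc(c(0.9, 0.7, 0.8, 0.2, 0.1), coh, 10)
  expect_equal(res$auc, 5 / 6)
  expect_equal(res$n_cases, 2)
  expect_equal(res$n_controls, 3)

  # random instances up to 200 records, against the pairwise oracle
  set.seed(13)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    followup <- stats::runif(n, 0, 12)
    died <- stats::runif(n) < 0.4
    coh <- toy_cohort(age = rep(50, n), followup = followup, died = died)
    scores <- round(stats::rnorm(n), sample(c(0, 1, 6), 1))
    h <- stats::runif(1, 2, 10)
    is_case <- died & followup <= h
    is_control <- !is_case & followup >= h
    if (!any(is_case) || !any(is_control)) next
    got <- horizon_auc(scores, coh, h)
    expect_equal(got$auc, auc_pairwise(scores[is_case], scores[is_control]),
                 tolerance = 1e-12)
    expect_equal(got$n_cases + got$n_controls, sum(is_case) + sum(is_control))
  }
})

test_that("AUC obeys the perfect-ranking and all-ties rules", {
  coh <- toy_cohort(age = rep(50, 10), followup = c(rep(2, 4), rep(10, 6)),
                    died = rep(c(TRUE, FALSE), c(4, 6)))
  expect_equal(horizon_auc(as.numeric(coh$died), coh, 5)$auc, 1)
  expect_equal(horizon_auc(rep(3.3, 10), coh, 5)$auc, 0.5)
  expect_error(horizon_auc(1:10, coh, 1), class = "danhi_no_events")
})

test_that("horizon AUC and DeLong are rank-invariant", {
  val <- scored_cohort(1500, seed = 17)
  f <- fit_cox(val, "CA_with_DAnHI")
  a1 <- horizon_auc(f$risk_score, val, 8)
  a2 <- horizon_auc(3 * f$risk_score + 11, val, 8)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  expect_equal(a1$variance, a2$variance, tolerance = 1e-12)

  lab <- c(rep(TRUE, 30), rep(FALSE, 70))
  set.seed(19)
  s <- stats::rnorm(100) + lab
  res <- delong_test(exp(s), s, lab)
  expect_equal(res$auc_diff, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_equal(delong_test(s, s, lab)$p, 1)
})

test_that("DeLong test agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    n <- 150
    lab <- stats::rbinom(n, 1, 0.4)
    base <- stats::rnorm(n) + lab
    s_a <- base + stats::rnorm(n, 0, 0.7)
    s_b <- 0.5 * base + stats::rnorm(n, 0, 0.9)
    if (length(unique(lab)) < 2) next
    ours <- delong_test(s_a, s_b, lab)
    ref <- pROC::roc.test(
      pROC::roc(lab, s_a, quiet = TRUE, direction = "<"),
      pROC::roc(lab, s_b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(ours$auc_a, unname(as.numeric(ref$estimate[1])),
                 tolerance = 1e-12)
  }
  # single-AUC CI cross-check
  set.seed(29)
  lab <- stats::rbinom(120, 1, 0.5)
  s <- stats::rnorm(120) + 0.8 * lab
  coh <- toy_cohort(age = rep(50, 120), followup = ifelse(lab, 3, 10),
                    died = as.logical(lab))
  ours <- horizon_auc(s, coh, 5)
  ref_ci <- pROC::ci.auc(pROC::roc(lab, s, quiet = TRUE, direction = "<"),
                         method = "delong")
  expect_equal(ours$ci_lower, as.numeric(ref_ci[1]), tolerance = 1e-8)
  expect_equal(ours$ci_upper, as.numeric(ref_ci[3]), tolerance = 1e-8)
})

test_that("DeLong p-value sits within Monte-Carlo error of a permutation oracle", {
  set.seed(31)
  n_case <- 30; n_control <- 30
  base <- c(stats::rnorm(n_case, 1), stats::rnorm(n_control))
  s_a <- base + stats::rnorm(60, 0, 0.8)
  s_b <- base + stats::rnorm(60, 0, 0.8)
  lab <- rep(c(TRUE, FALSE), c(n_case, n_control))
  ours <- delong_test(s_a, s_b, lab)

  stat <- function(perm_lab) {
    ca <- danhi:::delong_components(s_a[perm_lab], s_a[!perm_lab])$auc
    cb <- danhi:::delong_components(s_b[perm_lab], s_b[!perm_lab])$auc
    ca - cb
  }
  obs <- abs(stat(lab))
  perms <- vapply(1:4000, function(i) stat(sample(lab)), numeric(1))
  p_perm <- mean(abs(perms) >= obs - 1e-12)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(ours$p - p_perm), mc_err + 0.05)
})

test_that("DeLong type-I error is near nominal for label-independent scores", {
  p <- vapply(1:1000, function(s) {
    set.seed(6000 + s)
    n <- 200
    lab <- rep(c(TRUE, FALSE), each = n / 2)
    base <- stats::rnorm(n)  # shared structure, independent of labels
    s_a <- base + stats::rnorm(n, 0, 0.6)
    s_b <- base + stats::rnorm(n, 0, 0.6)
    delong_test(s_a, s_b, lab)$p
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("evaluate_suite reports subgroups, improves on CA, and is deterministic", {
  coh <- generate_cohort(simulation_config(
    6000, seed = 37, acceleration_sd = 5,
    hazard_params = c(a = -10.5, b = 0.09, c = 0.2)))
  excl <- apply_exclusions(coh)
  sp <- split_cohort(excl$cohort, 0.7, 37)
  covs <- panel_covariates()
  ens <- list(
    male = fit_ensemble(sp$development[sp$development$sex == "male", ],
                        "male", 26, 75, covs),
    female = fit_ensemble(sp$development[sp$development$sex == "female", ],
                          "female", 26, 75, covs))
  # sparse decade bands can leave coxph short of iterations; those fits are
  # reported as-is, so silence the numeric warnings here
  rep1 <- suppressWarnings(
    evaluate_suite(sp$validation, ens, development = sp$development,
                   event_types = "total", horizons = c(5, 10)))
  expect_named(rep1$by_sex, c("male", "female"))
  tot <- rep1$by_sex$male$Total$total
  expect_true(all(c("DAnHI", "CA", "CA_with_DAnHI", "BA") %in%
                    names(tot$cox)))
  expect_true(is.finite(tot$hr_ratio_percent))
  a10 <- tot$auc$year_10
  expect_gte(a10$CA_with_DAnHI$auc, a10$CA$auc - 0.02)
  expect_true(a10$CA_with_DAnHI$delong_p_vs_CA >= 0 &&
                a10$CA_with_DAnHI$delong_p_vs_CA <= 1)
  expect_lt(tot$risk_groups$logrank_p, 0.05)

  # sparse bands are reported, not raised
  y20 <- rep1$by_sex$male$a20s$total
  expect_true(is.list(y20))

  rep2 <- suppressWarnings(
    evaluate_suite(sp$validation, ens, development = sp$development,
                   event_types = "total", horizons = c(5, 10)))
  expect_identical(rep1, rep2)
})
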