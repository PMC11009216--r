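---
title: "The DAnHI method: model, estimation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DAnHI method: model, estimation, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The Differential Aging and Health Index (DAnHI) summarizes how much an
individual's routine health-screening biomarkers look older or younger
than their chronological age. This vignette documents the model, every
tunable parameter with its default and rationale, the conventions the
implementation commits to, and the method's limitations. All numerical
claims below are enforced by the package's test suite.

## 1. The model

### Dichotomized-age logistic ensemble

For each **model age** $n$ in a span $n_{\min}..n_{\max}$ (default
26..75, i.e. exactly 50 models), participants of one sex in the
*development* cohort are labelled by aging status: class 0 if
chronological age $< n$, class 1 if age $\ge n$. A logistic regression
of that label on the biomarker panel gives each individual $i$ a fitted
probability $P_{i,n}$ of belonging to the older class.

### Youden cutoff

Each model's probability scale is anchored at the cutoff $C_n$ that
maximizes the Youden index $J = \text{sensitivity} + \text{specificity}
- 1$ over the development predictions, predicting class 1 when
$P \ge C_n$. Implementation conventions:

* Candidate cutoffs are the midpoints between adjacent distinct sorted
  probabilities, plus one candidate below the minimum and one above the
  maximum (so "everyone positive" and "everyone negative" are always
  achievable). $J$ is piecewise constant between observed probabilities,
  so this enumerates every achievable value.
* Ties in $J$ are broken toward the **smallest** cutoff.
* The returned cutoff is clamped to the open interval $(0, 1)$.

The tests verify the maximizer against brute-force enumeration on 1 300
random instances (up to $n = 50$, with heavy probability ties).

### The index

The per-model deviation is $\delta_{i,n} = P_{i,n} - C_n \in (-1, 1)$,
and

$$\mathrm{DAnHI}_i \;=\; \frac{\sum_{n=n_{\min}}^{n_{\max}} n\,
\delta_{i,n}}{n_{\max} - n_{\min} + 1},$$

an age-weighted mean of the deviations. **Biological age** is
$\mathrm{BA}_i = \mathrm{CA}_i + \mathrm{DAnHI}_i$. Closed forms used as
test oracles: constant $\delta = c$ gives $50.5\,c$ on the default span
(the mean of 26..75 is 50.5); $\delta = +0.5$ on 26..50 and $-0.5$ on
51..75 gives $-6.25$; and $|\mathrm{DAnHI}| < 50.5$ always.

Cutoffs and coefficients are frozen on the development cohort; scoring a
validation cohort reuses them unchanged. Per-individual $\delta$
profiles across model ages can be clustered with seeded k-means
(`cluster_profiles()`, Lloyd's algorithm) to find typical aging shapes.

```{r}
library(danhi)
cohort <- generate_cohort(simulation_config(6000, seed = 1))
sp <- split_cohort(cohort, dev_fraction = 0.7, seed = 1)
panel <- select_covariates(sp$development, danhi:::DANHI_BIOMARKERS)$retained
ens <- fit_ensemble(sp$development[sp$development$sex == "male", ],
                    "male", covariates = panel)
scores <- score_cohort(sp$validation[sp$validation$sex == "male", ], ens)
head(scores)
```

## 2. Data cleansing

Applied in a fixed order, each record counted under the first rule that
removes it:

1. age under 20;
2. pre-existing chronic disease (generator flag);
3. death from an extrinsic or unknown cause — ICD-10 A00–B99, O00–O99,
   Q00–Q99, R95–R99, S00–T98, V01–Y98 (cancer is C00–C97 and D00–D48);
4. any missing biomarker.

Outlier trimming then removes, **once and per sex**, values strictly
below the 0.05th or strictly above the 99.95th percentile of each
biomarker (type-7 quantiles, R's default; the tests pin this against an
order-statistic oracle).

Multicollinearity screening computes each covariate's variance inflation
factor $\mathrm{VIF} = 1/(1 - R^2)$ from a linear regression on the
remaining covariates and iteratively drops the largest VIF at or above
the threshold (default 3), breaking ties by input order. On simulated
panels this reliably drops total cholesterol, which the generator builds
from LDL, HDL and TG/5 plus noise; the implementation is cross-checked
against `car::vif()`.

## 3. Mortality evaluation

* **Cox models** (`survival::coxph`, Efron ties), per sex, age band and
  cause: DAnHI alone; chronological age (CA) alone; CA with DAnHI; and
  BA alone. Cause-specific fits censor deaths from the other cause.
* **HR ratio (%)** $= (\mathrm{HR}_{\mathrm{DAnHI}} - 1) /
  (\mathrm{HR}_{\mathrm{CA}} - 1) \times 100$, both hazard ratios taken
  from the same CA-with-DAnHI fit; undefined when
  $\mathrm{HR}_{\mathrm{CA}} = 1$. Worked value:
  `hr_ratio_percent(1.097, 1.105)` rounds to 92.4.
* **Risk groups**: low ($\mathrm{DAnHI} \le 0$), medium ($0 <
  \mathrm{DAnHI} <$ median of the strictly positive development
  DAnHIs), high ($\ge$ that median); the threshold is frozen on
  development scores. Groups are compared with Kaplan–Meier curves and
  the $k$-group log-rank test.
* **Horizon AUC**: at horizon $h$, cases are deaths (of the analysed
  cause) with follow-up $\le h$; controls are participants whose
  follow-up reaches $h$ without the event — administrative censoring at
  exactly $h$ counts as complete follow-up, which keeps the 10-year
  horizon estimable under 10-year administrative censoring; records
  censored strictly before $h$ are excluded. The AUC is the
  Mann–Whitney statistic (ties 1/2), verified against exhaustive pair
  enumeration.
* **DeLong's method** supplies AUC variances/CIs and the paired test of
  two correlated AUCs, implemented from mid-rank structural components
  and cross-checked against `pROC::roc.test()` (agreement to $10^{-8}$),
  a 4 000-draw permutation oracle, and a 1 000-replicate null simulation
  (rejection at 0.05 within [0.03, 0.07]). Two scores that rank all
  pairs identically give difference 0 and $p = 1$.

## 4. The synthetic cohort generator

Real screening-cohort data cannot ship with the package, so validation
uses a seeded simulator whose assumptions are explicit and whose latent
truth is recoverable.

For each sex and biomarker, a **trajectory template** holds a
piecewise-linear mean and standard deviation over four age knots
(constant extrapolation outside). A participant's biomarker is

$$x = \mu_{\text{sex}}(\text{age}) + \lambda\, Z +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma_{\text{sex}}(\text{age})^2),$$

where $Z \sim N(0, \sigma_Z^2)$ is a per-person **latent aging
acceleration** in year-equivalents and $\lambda$ the biomarker's
loading. Survival is exponential with
$\log \lambda_{\text{hazard}} = a + b\,\text{age} + c\,Z$ and
administrative censoring at 10 years. Total cholesterol is derived as
LDL + HDL + TG/5 + noise so that the VIF screen has a true positive.
Deaths are assigned a cause (cancer fraction configurable), and
sub-seeds for generation, splitting and clustering are derived from one
user seed by a Lehmer sequence, so every artifact is reproducible from
the config alone.

### Parameters, defaults, rationale

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_participants` | — | persons | study size |
| `sex_ratio` | 0.5 | fraction male | balanced cohort |
| `age_distribution` | $\propto\,N(47, 14^2)$ on 20..85 | years | adult screening-population shape |
| `acceleration_sd` ($\sigma_Z$) | 5 | year-equivalents | spread typical of reported biological-age-acceleration measures |
| `acceleration_growth` | 0 | per year past 20 | optional widening of $\sigma_Z$ with age; used by the age-trend property test |
| loadings $\lambda$ | $\approx 0.14\times$ mid-age biomarker SD | biomarker units per year-equivalent | $Z$ explains a visible but not dominant share of age-adjusted biomarker variance, signed in the unhealthy direction (e.g. positive for SBP, FBS, TG; negative for HDL, HGB) |
| `hazard_params` | $a=-10$, $b=0.09$, $c=0.09$ | log-hazard; per year; per year-equivalent | adult all-cause log-mortality roughly doubles per 8 years ($b \approx \ln 2 / 8$); a year-equivalent of acceleration costs about as much as a calendar year |
| `cancer_fraction` | 0.35 | fraction of deaths | plausible cancer share in mid-life mortality |
| `admin_censor_years` | 10 | years | fixed follow-up window |
| `dev_fraction` | 0.7 | fraction | development/validation split, per sex |
| `vif_threshold` | 3 | — | conservative multicollinearity screen |

These defaults are study conditions: the test suite treats them as
fixed inputs, not tuning knobs.

### Constructions used by the statistical tests

* **Parameter recovery** (Cox): $n = 20\,000$ records with a known
  covariate at true log-HR 0.1 (and a null covariate at 0), 50
  replicates each; 95% Wald CI coverage must be $\ge 86\%$ (three
  binomial standard deviations below nominal).
* **Signal detection**: cohorts where biomarker residuals drive
  mortality — hazard slope $c = 0.2$ with $\sigma_Z = 5$, so the latent
  factor's log-hazard spread is comparable to the age gradient;
  $n = 4\,000$ single-sex, 25 replicates. The 10-year AUC of the
  CA-with-DAnHI risk score must be $\ge$ the CA-only AUC in $\ge 90\%$
  of replicates, and Spearman rank correlation between DAnHI and the
  latent $Z$ must be positive at $p < 0.01$.
* **Null uniformity**: 1 000 replicates each of a two-group log-rank
  test under one shared hazard and a paired DeLong test with
  label-independent scores; rejection at 0.05 must lie in [0.03, 0.07].
* **Latent recovery**: under generator defaults ($c = 0.09$),
  $n = 15\,000$ single-sex, DAnHI correlates positively with $Z$
  (Spearman, $p < 0.01$).

## 5. Reproducibility conventions

* One user seed drives everything; sub-streams (generation, splitting,
  clustering) are derived deterministically and the ambient RNG state is
  restored afterwards.
* `run_pipeline()` stamps every artifact with the seed and a config
  hash; rerunning an identical config reproduces byte-identical
  artifacts.
* Ensembles serialize to versioned JSON with coefficients and cutoffs as
  full-precision decimal strings, so save → load → score is
  bit-identical. Unknown document fields load with a warning; truncated
  or wrong-version documents raise a schema error.

## 6. Limitations

* The logistic models share one covariate panel across all model ages;
  there is no per-age feature selection or regularization, so sparse
  extreme-age classes rely on the global fit.
* $\delta$ values are probability-scale quantities; DAnHI's year scale
  is an interpretation (via BA = CA + DAnHI), not a calibrated mapping
  to remaining lifespan.
* Cause-specific analyses censor competing deaths rather than modelling
  subdistribution hazards, which overstates cause-specific risk when
  competing risks are strong.
* The simulator uses an exponential (constant-in-time) hazard per
  person, linear-in-age log-hazard, Gaussian biomarker noise and a
  single latent factor; real screening cohorts violate all four, so
  simulator-based results demonstrate correctness of the machinery, not
  clinical validity.
* Sparse subgroups (e.g. decade bands with few deaths) can leave
  `coxph()` short of convergence; such fits are reported as-is or as
  not estimable rather than aborting the evaluation.
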