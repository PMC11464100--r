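---
title: "Lifetime cardiovascular risk, competing-risk life tables and treatment benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime cardiovascular risk, competing-risk life tables and treatment benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecvd2)
```

## The model

`lifecvd2` estimates, for an apparently healthy individual aged 35–90, the
10-year risk of a first cardiovascular (CVD) event, the lifetime CVD risk up
to age 80, the CVD-free life expectancy, and the gain in CVD-free life
expectancy from preventive interventions. Three components interlock:

1. **Two cause-specific proportional-hazards risk functions per sex** — one
   for CVD events (fatal plus non-fatal myocardial infarction and stroke),
   one for the competing risk of non-CVD death. Each is parameterised by log
   hazard ratios per stated unit (age per 5 years, SBP per 20 mmHg, total
   cholesterol per 1 mmol/L, HDL per 0.5 mmol/L, current smoking, diabetes),
   log age-interaction hazard ratios per 5 years of centered age, and a
   baseline 1-year event-free survival $S_0(a)$ at every integer attained
   age $a \in [35, 100]$ for the reference individual (age centred at 60,
   SBP at 120 mmHg, TC at 6 mmol/L, HDL at 1.3 mmol/L, non-smoking,
   non-diabetic). The conditional 1-year risk at attained age $a$ is
   $$q(a) = 1 - S_0(\lfloor a\rfloor)^{\exp(\mathrm{LP}(a))}, \qquad
   \mathrm{LP}(a) = \beta_{age} z(a) + \sum_j
   \big(\beta_j + \gamma_j z(a)\big)\,\tilde x_j,$$
   with $z(a) = (a-60)/5$ and $\tilde x_j$ the centered, unit-scaled
   covariates.

2. **A competing-risk life table.** From the current age to the model
   ceiling of 100, 1-year windows are chained:
   $S(a{+}1) = S(a)\,(1-q_{cvd}(a))(1-q_{death}(a))$, the unconditional CVD
   risk of a window is $S(a)\,q_{cvd}(a)$, and its running sum is the
   cumulative CVD incidence. Lifetime risk is that sum over windows starting
   below 80; the 10-year risk sums the first ten windows; CVD-free life
   expectancy is the age at which $S$ crosses 0.5.

3. **Systematic recalibration to a risk region.** Registry CVD mortality is
   converted to total event incidence with a multiplier (and non-CVD
   mortality corrected for people with established CVD), giving observed
   annual risks per 5-year age group. Model-predicted 1-year risks at the
   group-mean risk-factor values are regressed on the cloglog scale,
   $\mathrm{cloglog}(q_{obs}) = s_1 + s_2\,\mathrm{cloglog}(q_{pred})$, and
   the fitted $(s_1, s_2)$ rescale every individual 1-year risk for that
   region, sex and endpoint. Four regions (low, moderate, high, very high)
   follow the standardised-CVD-mortality grouping used by the SCORE2 family
   of models.

Treatment benefit applies a causal hazard ratio, constant over all future
life years, on the hazard (power) scale: $q' = 1-(1-q)^{HR^{dose}}$. The
packaged effect sizes are HR 0.78 per 1 mmol/L LDL-cholesterol reduction,
HR 0.80 per 10 mmHg SBP reduction, and smoking cessation at HR 0.60 on CVD
events plus 0.73 on non-CVD mortality. The benefit measure is the
difference in median CVD-event-free survival age between the treated and
untreated life tables.

## What is published and what is synthetic here

The CVD-event coefficient sets in `published_coefficients()` are the
published sex-specific hazard ratios of the LIFE-CVD2 CVD models. Three
ingredients of the published regional models are **not** redistributable
and are replaced by documented synthetic stand-ins:

* the non-CVD mortality coefficients (`synthetic_noncvd_coefficients()`,
  chosen as epidemiologically plausible magnitudes);
* the registry inputs (WHO mortality, SCORE2 multipliers, NCD-RisC risk
  factor levels), replaced by `generate_registry()`'s closed-form synthetic
  registries;
* consequently the baseline survival and the regional recalibration scales,
  which the package derives from those synthetic registries exactly as it
  would from real ones.

Absolute risk levels and treatment gains from `default_bundle()` are
therefore *illustrative*: they reproduce the qualitative structure (age
gradients, the low &rarr; very-high regional gradient, plausible orders of
magnitude) but not the published regional numbers. Supplying real registry
tables via `read_registry()`/`read_means()` and rebuilding the bundle with
`set_baseline_from_incidence()` and `recalibrate_bundle()` yields a fully
calibrated model with no code changes.

## Synthetic study conditions

`scenario()` fixes the ground truth for all generators, chosen once to
mirror a large multi-cohort derivation population: 43% male, entry ages
uniform on 40–75, SBP 135 (SD 19) mmHg, total cholesterol 5.9 (1.1) mmol/L,
HDL 1.4 (0.4) mmol/L, 15% current smokers, 4.7% diabetes, 2%/year loss to
follow-up, 15 years administrative censoring. Reference Gompertz baselines
(`reference_gompertz()`) place first-CVD-event incidence at roughly 0.6%
(men) / 0.35% (women) per year at age 60, doubling about every 8 years, and
non-CVD mortality at 0.8% / 0.55% per year doubling about every 7 years —
realistic low-risk-European orders of magnitude for a healthy reference
individual. Regional hazard factors 1 : 1.5 : 2.5 : 4 (CVD) and
1 : 1.15 : 1.35 : 1.6 (non-CVD death) follow the approximate gradient of
standardised CVD mortality across the four European risk regions.

The generator simulates *discrete yearly* hazards — a CVD event takes
precedence over non-CVD death within a window — so the life-table engine is
the exact oracle for the generator, and calibration of a bundle on a
validation set simulated from its own hazards is perfect up to sampling
error. What passing tests therefore demonstrate is internal correctness of
the machinery, not fidelity of any absolute risk level to a real
population: the generator has no measurement error, no missing data, no
cohort heterogeneity beyond the stratified baseline, and no secular trends.

## Numerical and design choices

* **Age conventions.** Printed age-interaction terms are relative to age at
  entry, which is how `fit_endpoint_models()` parameterises them and how
  `generate_cohort()` simulates. For prediction, the default evaluates the
  age main effect and all interactions at the *attained* age of each
  window, making 1-year risks a function of attained age only — the
  convention required for age-group recalibration to be self-consistent.
  Both conventions are available via `age_convention` in
  `linear_predictor()`/`build_life_table()`.
* **Median-survival interpolation.** Within the year where survival crosses
  0.5, the age is interpolated assuming a constant hazard (log-linear
  survival). This matches the package-wide rate&harr;probability convention
  $q = 1-e^{-h}$ and is exact for constant hazards; linear interpolation
  would differ by a few thousandths of a year.
* **Baseline lookup and group midpoints.** $S_0$ is looked up at the
  floored attained age; fractional entry ages still get a full first
  window. Five-year registry groups (35–39, …, 95–99) are represented by
  their integer midpoints (37, 42, …, 97), so baseline inversion and
  predicted group risks round-trip exactly at the midpoints; between
  midpoints log hazards are interpolated with a monotone cubic
  (Fritsch–Carlson) and extended log-linearly in the tails.
* **Within-year composition.** CVD and non-CVD events are combined by the
  product form with CVD taking precedence; no half-cycle correction is
  applied (alternatives differ at $O(q^2)$).
* **Recalibration regression.** Unweighted OLS on the cloglog scale across
  age groups. When observed and predicted risks are related by a constant
  hazard ratio $k$, the fit returns exactly $(\ln k, 1)$.
* **Ties.** Efron's approximation is the default for the many ties produced
  by yearly age discretisation; Breslow is available (`ties=`) and is the
  variant under which duplicating every record leaves estimates exactly
  unchanged.
* **Diabetes.** The coefficient is retained for recalibration against
  population statistics that include diabetics, but clinical prediction
  (`clinical = TRUE`, the default) refuses diabetic individuals.
* **LDL proxy.** LDL cholesterol is not a model covariate; the chart layer
  (`benefit_chart(rule = "ldl_40pct")`) approximates it as
  $TC - HDL - 0.8$ mmol/L, and this approximation never leaves that layer.
* **Concordance.** The competing-risk C-index keeps subjects with a
  competing event in the comparison set as non-cases for the full horizon
  (Wolbers-style); censored subjects inform only pairs up to their
  censoring time (standard Harrell handling, no censoring weights). Tied
  predictions count 1/2.
* **Degenerate inputs.** Risks outside $(0,1)$ map to themselves under
  recalibration; lifetime risk from a start age at or past the horizon is
  defined as 0 with a warning; a median never reached by age 100 is
  censored at the ceiling and flagged.

## A worked tour

```{r tour}
b <- default_bundle()
p <- risk_profile("female", 50, smoking = 1, sbp = 140,
                  total_chol = 5.5, hdl_chol = 1.3)
lt <- build_life_table(p, b, region = "very_high")
c(ten_year = ten_year_risk(lt),
  lifetime = lifetime_risk(lt),
  cvd_free_le = as.numeric(cvd_free_life_expectancy(lt)))
as.numeric(smoking_cessation_benefit(p, b, "very_high"))
```

The full derivation &rarr; recalibration &rarr; validation loop on
synthetic data is one call:

```{r pipeline, eval = FALSE}
res <- run_pipeline("artifacts", seed = 1, n = 20000)
res$calibration
```

## Problem sizes used in the test suite

Property tests use cohorts of 3 000–12 000 records and a 200 000-draw
Monte-Carlo check of the life table; the acceptance suite runs the
flagship parameter recovery on a 50 000-subject cohort, a $10^6$-draw
Monte-Carlo oracle, and 6 000–8 000-subject validation sets. These sizes
give Monte-Carlo standard errors comfortably below the asserted tolerances
while keeping the default test run to well under five minutes.

## Known limitations

* Absolute risks, and hence treatment gains, depend on the synthetic
  registries and the synthetic non-CVD coefficients; only the CVD-event
  relative-risk structure is the published one.
* Imputation of missing predictors is out of scope; inputs must be
  complete.
* The model is undefined outside ages 35–100; entry is restricted to 35–90
  so the life table always holds at least ten windows.
* No time-varying adherence, waning of treatment effects, or interactions
  between combined therapies beyond multiplication of hazard ratios.
* Validation utilities estimate observed incidence nonparametrically
  (Aalen–Johansen); very small deciles or sparse age ranges will be noisy.
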