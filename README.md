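# lifecvd2

Lifetime cardiovascular risk prediction with competing risks, regional
recalibration and treatment-benefit estimation, for researchers and
methodologists working on long-horizon CVD prevention models.

Ten-year risk thresholds systematically favour the old: age dominates
short-horizon CVD risk, so a 40-year-old smoker with high blood pressure
can sit below every treatment threshold while having the most to gain from
decades of prevention. This package implements the lifetime alternative: a
pair of sex-specific cause-specific proportional-hazards functions — one
for CVD events, one for the competing risk of non-CVD death — combined in
a year-by-year life table from the current age to age 100.

For an individual with covariates $\tilde x$ (centered and unit-scaled)
the conditional 1-year risk at attained age $a$ is

$$q(a) = 1 - S_0(a)^{\exp(\mathrm{LP}(a))},\qquad
\mathrm{LP}(a)=\beta_{age}\,z(a)+\sum_j(\beta_j+\gamma_j z(a))\,\tilde x_j,
\quad z(a)=\tfrac{a-60}{5},$$

and the life table chains
$S(a{+}1)=S(a)(1-q_{cvd}(a))(1-q_{death}(a))$. From it the package reads
10-year risk, lifetime risk to age 80
($\sum_{a<80} S(a)\,q_{cvd}(a)$), and CVD-free life expectancy (the age
where $S$ crosses 0.5). Risks are recalibrated to one of four European
risk regions by an intercept/slope rescaling on the cloglog scale fitted
against registry incidence (mortality converted to total events by the
multiplier approach). Treatment benefit applies a causal hazard ratio on
the hazard scale, $q'=1-(1-q)^{HR^{dose}}$, and reports the gain in
median CVD-event-free survival age.

The package also contains the surrounding machinery: Cox derivation of the
coefficient sets (age as the time scale, left truncation, cohort strata,
entry-age interactions), competing-risk model validation (Wolbers-style
concordance, decile calibration with Aalen–Johansen observed incidence,
age-scale lifetime calibration), and a synthetic-data module that
generates cohorts, registries and validation sets with known ground truth.
The packaged CVD-event coefficients are the published LIFE-CVD2 hazard
ratios; the non-CVD mortality coefficients, registries, baseline and
regional scales are documented synthetic stand-ins, so absolute levels
from the default bundle are illustrative (see the vignette).

## Worked example

A 50-year-old woman who smokes, SBP 140 mmHg, total cholesterol
5.5 mmol/L, HDL 1.3 mmol/L, in the very-high-risk region:

```r
library(lifecvd2)
b <- default_bundle()
p <- risk_profile("female", 50, smoking = 1, sbp = 140,
                  total_chol = 5.5, hdl_chol = 1.3)
run_predict(list(p), b, region = "very_high")
#>      sex age ten_year_risk lifetime_risk_to_80 cvd_free_le le_censored
#> 1 female  50     0.2264917           0.6576274    64.18044       FALSE
run_benefit(p, "quit-smoking", b, region = "very_high")[c("gain")]
#> $gain
#> [1] 3.666467
```

Read: under the synthetic very-high-risk calibration her 10-year CVD risk
is 22.6%, her probability of a first CVD event before age 80 is 65.8%, the
median age at which she is still alive and CVD-free drops below one half
at 64.2 years — and quitting smoking (hazard ratios 0.60 on CVD events,
0.73 on non-CVD death, constant for life) would move that median up by
3.7 years. The same quantities under `region = "low"` are smaller, and the
gain shrinks with them: the regional gradient in absolute risk carries
through to treatment benefit.

The full synthetic loop — simulate a cohort, fit the four Cox models,
derive the baseline from low-region incidence, recalibrate to all regions,
and check calibration on a self-simulated validation set — is
`run_pipeline("artifacts", seed = 1)`.

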