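# srscore

Residual-based resilience analysis for multi-wave questionnaire cohorts.

## The problem

In longitudinal studies of populations under stress (the motivating setting is
hospital staff followed across three survey waves of a health crisis), raw
symptom scores confound two things: how much adversity a person actually faced
and how strongly they reacted to it. A fall in average depression scores can
reflect genuine adaptation — or simply less exposure. `srscore` implements the
stressor-reactivity (SR) approach to separating the two: resilience is
quantified as the deviation of an individual's mental-health burden from the
burden *normatively expected at their exposure level*.

Concretely, with `E` the proportional stressor-exposure score (percent of
administered stressor items endorsed, from a 17-item workplace/pandemic
stressor bank) and `P` a symptom total (PHQ-9 depression, 0–27, or GHQ-12
general distress, 0–36), the sample's normative line is the OLS polynomial fit

    P = b0 + b1 E (+ b2 E^2) + e,

with the linear-vs-quadratic choice decided per line by a chi-squared
likelihood-ratio test (statistic `n log(RSS1/RSS2)` on 1 df). An individual's
SR score is their residual

    SR = P_observed − P_expected(E),

negative SR meaning fewer problems than expected for the exposure faced (a
resilient outcome). SR is computed on two bases (`dep` = PHQ-9, `dis` =
GHQ-12), either pooled across waves on the complete-case sample (for trend
comparisons) or per cross-sectional wave (for everything else), and is
z-standardised within its fit scope by default.

Around that core the package provides the full inference chain used in this
design: time-trend models on complete cases, cumulative effects of baseline
exposure on later reactivity (with a quadratic "steeling" probe),
resilience-factor associations (support from colleagues, trust in the
workplace, and REC — the perceived ability to recover from stress — unadjusted
and age/gender-adjusted), a joint multivariate model, exposure-moderated
regression with simple slopes at mean ± 1 SD of exposure, and Baron–Kenny
mediation (support → REC → SR) with a seeded case-resampling bootstrap of the
indirect effect `a·b`.

Because the original cohort is not redistributable, the package ships a
calibrated synthetic-cohort generator: compound-symmetric ordinal item blocks
whose thresholds and inter-item correlations are solved by a moment-matching
routine so that the default configuration reproduces the published baseline
moments, scale reliabilities (α ≈ 0.88 / 0.85 / 0.80), exposure–symptom
correlations, the SR basis correlation and the probable-MDD share, together
with dropout, new entrants per wave and configurable structural effects whose
observed-scale truths are recoverable by OLS.

## Worked example

```r
library(srscore)

cohort <- generate_cohort(default_config(), seed = 1)
cohort
#> Multi-wave cohort: 4766 observations, 3072 participants
#>   wave 1: n = 2422
#>   wave 2: n = 1836
#>   wave 3: n = 508

fit <- sr_fit(cohort, basis = "dep", mode = "per_wave")
fit
#> Stressor reactivity fit: basis = dep, mode = per_wave
#>   wave_1: degree 1 (LRT p = 0.298), n = 1763
#>   wave_2: degree 2 (LRT p = 0.00695), n = 1611
#>   wave_3: degree 1 (LRT p = 0.121), n = 425
#>   3799 SR scores computed
coef(fit)$wave_1
#>     beta0     beta1
#> 2.4231053 0.1221071
```

The wave-1 normative line says a respondent endorsing half the stressor bank
(E = 50) is expected to score about `2.42 + 0.122 * 50 ≈ 8.5` PHQ-9 points;
someone scoring 5 at that exposure has SR ≈ −3.5 raw (resilient side). Per-wave
raw residuals average exactly zero by construction (here SD ≈ 4.9 points at
baseline).

Prospective association of baseline support with wave-2 reactivity, and the
mediation through REC:

```r
sc   <- score_cohort(cohort)
base <- sc[sc$wave == 1, ]
d <- merge(base, fit$scores[fit$scores$wave == 2,
                            c("participant_id", "standardised")],
           by = "participant_id")

fit_rf_association(d$support, d$standardised, adjust = TRUE,
                   age = d$age, gender = d$gender)
#> OLS: SR ~ RF + age + gender  (n = 802, R^2 = 0.023, ...)
#>  rf  -0.2093  se 0.0508  CI (-0.3091, -0.1096)  p 0.0000

bootstrap_indirect(d$support, d$rec, d$standardised,
                   config = sr_config(n_bootstrap = 5000, rng_seed = 1))
#> Baron-Kenny mediation (x -> m -> y)
#>   a = 0.1670, b = -0.3489, c = -0.1742, c' = -0.1160  (n = 638)
#>   indirect a*b = -0.0583
#>   mean bootstrapped indirect = -0.0578, 95% CI (-0.0923, -0.0269), 5000 iterations, seed 1
```

Each additional point of perceived colleague support predicts about 0.21 SD
lower stressor reactivity a year later; roughly a third of its total effect
runs through higher perceived recovery ability (the indirect path is negative
and its bootstrap CI excludes zero). `run_pipeline()` executes the whole chain
(scoring → reliability → SR → trends → association grid → moderation →
mediation → complete-case sensitivity) and `write_report()` serialises the
bundle to CSV/JSON/SVG.

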