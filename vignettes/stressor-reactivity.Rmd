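---
title: "Stressor reactivity: model, scoring rules, and the calibrated cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stressor reactivity: model, scoring rules, and the calibrated cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Resilience is treated as an *outcome relative to adversity*, not a trait.
For person $i$ at wave $w$, let $E_{iw} \in [0, 100]$ be the percentage of
administered stressor items endorsed and $P_{iw}$ a symptom total (PHQ-9 for
the depression basis, GHQ-12 for general distress). The sample's normative
reaction is the OLS polynomial

$$P = \beta_0 + \beta_1 E + \beta_2 E^2 + \varepsilon,$$

with $\beta_2$ included only when a chi-squared likelihood-ratio comparison of
the nested fits prefers the quadratic. The stressor-reactivity score is the
residual $SR_{iw} = P_{iw} - \hat P(E_{iw})$: negative values mean fewer
problems than expected at that exposure (resilience), positive values an
over-reaction. Two scoping rules are supported and serve different questions:

* **pooled complete cases** — one line fitted on all three waves of the
  participants with $E$ and $P$ at every wave; residuals are then comparable
  across waves and support trend models ("did resilience change?");
* **per wave** — one line per cross-sectional wave on all rows with $E$ and
  $P$ there. The exposure–symptom correlation differs visibly across waves in
  data of this kind, so per-wave lines give better-fitting norms for the
  association analyses.

Degree selection is done per line, independently. The "chi-squared comparison"
is realised as the Gaussian likelihood-ratio statistic
$n \log(\mathrm{RSS}_1 / \mathrm{RSS}_2)$ on 1 df with the quadratic chosen at
$p < \alpha$ (default 0.05); the statistic is the natural LRT for nested OLS
models and its type-I behaviour is verified by simulation in the test suite.
When the quadratic wins, residuals are taken from the quadratic fit only — no
averaging across degrees.

**Standardisation.** SR scores are z-standardised within their fit scope by
default, so downstream coefficients read as SD units of reactivity per unit of
predictor; residual standard errors near 0.9 in the multivariate model are the
signature of this scale. Raw residuals (symptom points) are always retained
alongside, and `sr_config(standardise_sr = FALSE)` switches the default.

## Scoring rules and their edge cases

* **Exposure.** Stressor items are dichotomised (occurred / did not occur) and
  $E = 100 \times$ endorsed / answered, where the denominator is the number of
  items the *person answered* among those administered at that wave. The
  battery-level denominator ("sum of possible stressors") would silently treat
  unanswered items as non-exposure; the person-level denominator avoids that,
  at the price of a coverage requirement: when fewer than
  `min_item_coverage` (default 80%) of the administered items are answered,
  $E$ is missing. The alternative reading — unanswered = did not occur, full
  battery denominator — is available as `impute_unanswered = TRUE`.
* **PHQ-9 / GHQ-12.** Item sums on 0–3 responses (ranges 0–27 and 0–36). The
  GHQ-12 uses 0–1–2–3 Likert scoring, which the 0–36 range forces; the
  binary 0-0-1-1 method is not offered. A total is missing whenever any item
  is missing (listwise per scale); pro-rating of answered items is available
  behind a flag but is not the default, as the simplest defensible policy.
* **REC** (perceived ability to recover from stress, 6 items, half
  reverse-keyed) is scored as the *mean of recoded items on 1–5*. Instrument
  descriptions sometimes state a summed 0–6 range for this scale, which is
  arithmetically incompatible with the reported mean near 3.2 and SD near 0.7;
  the 1–5 mean is the only reading consistent with those moments and is used
  throughout. The discrepancy is deliberately documented rather than silently
  reconciled.
* **Probable depression** uses the standard PHQ-9 cutoff: total ≥ 10.
* **Reliability.** Cronbach's alpha with the Feldt F-based 95% interval
  (the F quantiles on $(n-1, (n-1)(k-1))$ df applied to $1-\hat\alpha$); no
  method was mandated, and the Feldt interval is exact under the parallel-items
  model.
* **Gender** is a three-level categorical (female / male / unknown);
  "unknown" is a level, not missingness, so those respondents stay in adjusted
  models.

## The regression layer

Trends are fit on the complete-case sample with wave as numeric 1–3 (a
categorical-wave variant exists behind a flag). Cumulative-exposure models
regress follow-up SR on baseline $E$, optionally adding $E^2$: a negative
quadratic with a null linear term is the "steeling" signature, a positive
linear term the allostatic-load pattern. Resilience-factor models come in
unadjusted/adjusted pairs (age + gender), the multivariate model enters all
three factors plus baseline exposure jointly, and moderation models add the
factor × exposure product, summarised by simple slopes at exposure mean ± 1 SD
with delta-rule CIs (verified against a parametric bootstrap). All CIs are
Wald-type at 95%; no multiplicity correction is applied in the primary output,
matching the reporting convention of this literature — a Benjamini–Hochberg
summary is emitted as supplementary output only.

Mediation follows the Baron–Kenny three-regression decomposition on a single
listwise-complete row set, where $c = c' + ab$ holds as an algebraic identity
(checked to 1e-10 at run time). The indirect effect is bootstrapped by case
resampling — whole rows, preserving the joint $(x, m, y)$ distribution — with
a percentile 95% interval (BCa behind a flag) and 5,000 iterations by default;
resampling happens within the regression row set, since resampling the full
sample and re-deleting incomplete rows would make replicate sizes random.
Covariates can be included symmetrically in all three regressions but default
to off, matching the unadjusted reporting of this analysis. An
exposure × mediator interaction pre-check warns (without aborting) when the
product term is significant, since the decomposition assumes its absence.
Only cross-sectional mediation is offered.

## The synthetic cohort generator

The generator exists so the full pipeline can be exercised, tested and
calibrated without the (non-redistributable) original data. It emulates:

* three waves with baseline $n = 2422$, retention 0.50 then 0.274, and 616 /
  34 new entrants — figures chosen once to reproduce the published wave sizes
  (≈ 1,830 and ≈ 540) and the ≈ 330 participants present at all three waves;
* declining exposure across waves (mean E 39 / 34 / 30 percent, SD 15 at
  baseline) with within-person autocorrelation 0.5 in the latent propensity;
* item-level structure: each scale is a compound-symmetric latent block
  discretised by thresholds shared across its items, so Cronbach's alpha has
  the closed form $kr/(1+(k-1)r)$ on the latent scale
  (`calibrate_scale_correlation()` is its exact inversion) and discretisation
  effects are handled by calibration;
* a stable per-person reactivity intercept (40% of the non-exposure residual
  variance) plus wave-level noise shared between the dep and dis bases, so the
  two SR scores correlate ≈ 0.68 at baseline;
* resilience factors with a built-in support → REC → SR mediation path,
  exposure-moderated effects, and a cumulative carry-over of baseline exposure
  onto later reactivity;
* block-level missingness per wave (baseline rates taken from the published
  "unknown" counts; halved at follow-ups) and missing-completely-at-random
  dropout, with an optional distress-dependent dropout mode for sensitivity
  experiments on attrition bias.

**Residual skew.** Symptom totals in mostly-healthy populations are
right-skewed: a mean of 7.3, an SD of 5.4 and only 27% of respondents at or
above 10 cannot coexist under a symmetric latent. The wave-level residual
components therefore use a standardised skew-normal (shape 0.95); this leaves
every OLS recovery property intact (the noise is exogenous) while making the
mean/SD/tail triple jointly attainable.

**Calibration.** `calibrate_generator()` produces all constants in two layers.
First, semi-analytic solves under a standard-normal person factor: category
probabilities, total-score moments, alpha and (for the PHQ-9) the ≥ 10 tail
are computed by numerical integration over the person factor, and thresholds
plus inter-item correlation are optimised against the targets; single-item
thresholds (support, trust) and the stressor-item loading (target E SD) have
their own exact solves. Second, pilot corrections against the full generator
(pilot n = 100,000): the structural person factor is only approximately
normal, so the analytic targets are bias-corrected against pilot moments in a
damped fixed-point loop; the exposure slope and the shared-residual
correlation are tuned to the exposure–symptom and SR-basis correlation
targets; and *probe regressions* measure the attenuation each structural path
suffers on its way through the ordinal items, storing per-estimand gains
(direct path, mediator path, moderation, cumulative) that the generator
divides out. Structural coefficients in `generator_config()` are therefore
expressed on the scale an analyst actually estimates — standardised-SR units
per observed unit of the predictor — and are recoverable by OLS at the
calibration's reference conditions (paths near a = 0.5, b = −0.4, c′ = −0.22,
moderation −0.003). Configurations far from those conditions, or with several
large paths active at once, shift the implied estimands (omitted-variable and
variance-scale effects), which is a property of the estimands rather than a
generator defect. The shipped constants are the frozen output of one
calibration run; re-running the routine reproduces them to pilot Monte-Carlo
error.

**What the generator does not emulate.** Joint distributions beyond the
calibrated moments and correlations; profession or workplace clustering;
measurement non-invariance across waves; informative missingness (default is
MCAR); the real batteries' wave-specific item subsets (the availability mask
defaults to all 17 items at every wave, with a 16-item wave-2 mask exercised
in the tests as an example). Passing tests on synthetic cohorts therefore
demonstrate that the *pipeline* is correct and calibrated, not that any
substantive conclusion transfers to real data.

## Numerical choices and degenerate inputs

* OLS is delegated to `stats::lm` (fast path `stats::.lm.fit` inside the
  bootstrap); residual identities (mean zero, design orthogonality) are
  asserted at 1e-8, the mediation identity at 1e-10.
* Constant exposure, constant factors, or a single-level gender are singular
  designs: the first two error, the third drops the covariate with a warning.
* A wave with fewer than `min_n` (default 10) scored rows is skipped with a
  warning in per-wave mode.
* With reactivity and residual noise switched off the E–P relation becomes
  deterministic up to item discretisation; per-wave raw residual SDs then
  collapse to below ~2 symptom points (the granularity floor), against ≈ 5
  under the default noise.
* Standardisation uses the n−1 sample SD, so the standardised scores have
  sample SD exactly 1 in their fit scope.
* Bootstrap replicates with singular designs are redrawn and counted; the
  count is reported.

## Problem sizes in the test suite

The suite favours a few deep checks per operation: oracle equivalence against
a normal-equations solver on instances of n ≤ 50; type-I calibration of the
degree-selection LRT, interaction and cumulative tests at 1,000 replicates of
n = 300–1,000; bootstrap CI coverage at 200 outer replicates of n = 400 with
999 inner iterations; parameter recovery at n ≈ 2,000; and the
stability phenomenon (declining E and P with flat SR under constant
reactivity) at 200 replicates of n = 250. These sizes keep the full suite
under a minute on one core while leaving each Monte-Carlo band (± 2% on
type-I error, 93–97% on coverage) comfortably estimable.

## Known limitations

The normative line is a population regression, so SR is always relative to the
sample analysed — scores from different cohorts are not directly comparable.
No mixed-effects or time-varying-coefficient normative models are offered, and
no causal machinery (the mediation is associational, with no sensitivity
analysis for sequential ignorability). The generator's structural truths are
calibrated at reference conditions; extreme configurations should be validated
against their own pilot before being used as ground truth.
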