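---
title: "Change-score models, longitudinal mediation, and clinical significance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change-score models, longitudinal mediation, and clinical significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsmediate)
```

# The analysis problem

`lcsmediate` analyzes two-arm randomized trials in which a bounded sum-score
outcome (a depression inventory) and several candidate mechanism scales
(behavioral activation, cognitive distortions, perseverative thinking) are
measured at four waves: baseline and three monthly follow-ups. The questions
it answers are the standard ones for such a design:

1. Does the treated arm change more than the control arm, month by month?
2. Is the treatment effect on the outcome transmitted through changes in the
   mechanism scales (mediation), and how much of it?
3. Is the change clinically meaningful for individuals (high-end-state
   functioning, reliable change), and how large is it in standardized units
   (Cohen's *d*)?

Because participant-level trial data of this kind are rarely shareable, the
package pairs the analysis machinery with a synthetic-trial generator whose
ground truth is known exactly, so every stage can be validated end to end.

# The latent change score model

## Why differences, and why this parameterization

A latent change score (LCS) for a single-indicator construct is built in a
structural model by fixing the autoregression between adjacent waves to 1 and
attaching a latent factor with unit loading to the later wave. With those
constraints the latent change is *algebraically identical* to the observed
difference `score(t+1) - score(t)`. `lcsmediate` exploits this identity: the
engine fits the implied regression system directly by least squares rather
than routing through a general structural-equation optimizer. This is a
deliberate design decision — the estimates are exact solutions of the normal
equations, transparent to test (every fit is checked against an independent
normal-equations oracle in the test suite), and free of optimizer
convergence concerns. The trade-off is scope: the engine covers exactly the
fixed-loading, single-indicator LCS family, not general latent-variable
models (no multi-indicator measurement models, no fit indices).

## The equation system

`fit_change_model()` fits, for an outcome measured at waves 0–3:

* a **baseline balance** equation: baseline level on the centered treatment
  indicator (in a randomized trial this coefficient should be ~0);
* three **monthly change** equations: each wave-to-wave change regressed on
  the centered treatment, the (centered) prior-month level, and the
  (centered) baseline level. Conditioning on the previous level adjusts for
  regression to the mean; conditioning on baseline absorbs the association
  between initial severity and subsequent change.

All depression levels are centered on the *pretreatment* mean, and the
treatment indicator is centered on its observed mean (with 50 treated of 103
the centered codes are 0.51/−0.49). Intercepts then read as "the change from
the previous month for a participant at average pretreatment severity,
averaged across arms". Centering is a pure reparameterization: slopes are
unchanged (a property test asserts this), only intercepts shift.

## Standard errors, tests, intervals

The default residual-variance denominator is `n` ("ML"), matching the
convention of maximum-likelihood structural-equation software; `n − p`
("OLS") is available and the output labels which was used. Tests are Wald:
`z = estimate/SE`, two-sided p from the standard normal (not *t*), and
`CI = estimate ± z_crit · SE`. For trial-sized samples (n ≈ 100) the ML/OLS
distinction changes SEs by under 2%.

## Missing data

Listwise deletion per equation is the default; each equation reports its own
`n` so attrition is visible. A full-information maximum-likelihood (FIML)
option is provided for sensitivity: the joint (response, predictors) vector
is modeled as multivariate normal, the mean and covariance are estimated by
EM over missingness patterns, and the regression coefficients are read off
the fitted joint distribution. FIML standard errors come from the
numerically evaluated observed information, delta-methoded to the
coefficient scale. On complete data FIML reproduces the listwise estimates
(a test asserts agreement to 1e−6); under wave-level missingness at the
rates this design produces, the two typically agree closely, which is why
the simpler listwise route is the default.

## Numerics

The normal equations are solved through a rank-revealing QR decomposition.
A design whose rank is deficient, or whose condition number exceeds 1e12,
raises a classed singularity error naming the collinear predictors —
silent dropping of columns would disguise specification errors in a
mediation system. Noiseless inputs (zero residual variance) are legal and
produce zero SEs with undefined z/p rather than failures.

# Mediation

## Path system

For a single mediator *M* and outcome *Y*, both expressed as
baseline-to-3-month changes:

* **a path**: ΔM ~ treatment (centered) + M₀ + Y₀
* **b, c′ paths**: ΔY ~ ΔM + treatment (centered) + M₀ + Y₀

The indirect effect is `a·b`, the total effect `a·b + c′`, percent mediated
`100·(a·b)/(a·b + c′)`. The multi-mediator model fits one a-equation per
mediator (all baselines as covariates) and a single outcome equation
containing all three mediator changes; independent indirects are `aⱼ·bⱼ`,
the combined indirect their sum. Two identities hold *exactly* by
construction and are asserted on every fit: combined = Σ independent, and
total = combined + c′. A zero total effect flags percent mediated as
undefined rather than erroring, so batch summaries keep flowing.

Window defaults differ by model, following the trial's specification:
single-mediator models use 0→3 for both changes; the multi-mediator model
uses 0→2 for mediator changes and 0→3 for the outcome change. Both are
overridable. Whether the single-mediator outcome equation should also
condition on intermediate-wave levels was genuinely open; the package
follows the plainer specification (baselines only), which also keeps the
single- and multi-mediator systems directly comparable.

## Bias-corrected bootstrap

Indirect effects are products of coefficients; their sampling distributions
are skewed and Wald intervals misbehave. `bc_bootstrap_ci()` resamples
*whole participants* with replacement (preserving within-person correlation
across waves), recomputes the indirect effect(s) per draw, and applies the
bias-corrected percentile construction: `z₀ = Φ⁻¹(fraction of draws below
the point estimate)`, with endpoints at the bootstrap quantiles
`Φ(2z₀ + z_{α/2})` and `Φ(2z₀ + z_{1−α/2})`.

Numerical choices, each of which was open:

* **Bias correction only** — no acceleration constant. The method
  implemented is the plain BC interval, not BCa; the acceleration term
  would change the construction, and BC is what the analysis this package
  operationalizes used.
* **Ties**: draws exactly equal to the point estimate count half toward the
  "below" fraction (mid-p convention).
* **Degenerate fractions** (0 or 1) are clamped to `1/(m+1)` and `m/(m+1)`
  with a warning, avoiding infinite z₀ while preserving one-sided extremity.
* **Failed draws** (singular refits on a resample) are dropped and counted,
  never silently redrawn; the count is part of the output.
* **Quantiles** use R's default type-7 interpolation.
* Resampling is unstratified by default; within-arm stratified resampling is
  available as an option.

Determinism is part of the contract: identical seed and draw count give
identical intervals.

# Clinical significance

* **High-end-state functioning**: the fraction of non-missing endpoint
  scores in the none-to-minimal band (0–13 for the 21-item depression
  inventory, boundaries inclusive).
* **Reliable change index**: `RCI = (post − pre)/S_diff` with
  `S_diff = √(2·(SD_pre·√(1−r))²)`, the Jacobson–Truax form; `|RCI| > 1.96`
  marks reliable change at 95% confidence. The reliability `r` defaults to
  0.83, a typical baseline internal-consistency value for this instrument
  in clinically depressed samples, and should be replaced by the sample's
  own baseline Cronbach's alpha when item-level data are available
  (`cronbach_alpha()`). Because a single published RCI can be either an
  individual-level or a group-level quantity, the summary reports **both**:
  per-participant RCIs and the group mean-change RCI, labeled.
* **Cohen's d**: between-group *d* on baseline-to-endpoint change scores
  with the SD pooled over arms using n−1 weights (the default); a
  baseline-SD denominator is available because published effect sizes do
  not always state which variant they used, and the report labels the one
  computed.

# The synthetic trial generator

## What it emulates

`generate_trial()` reproduces the *design* of a 103-participant two-arm
trial: an 84.5% female sample, stratified permuted-block randomization by
sex with blocks of 10 (every complete block splits 5/5; the marginal
imbalance can never exceed strata × block/2), baseline eligibility requiring
at least moderate depression severity (baseline score ≥ 20 on the 0–63
outcome), four assessment waves, and independent per-wave retention
defaulting to (0.97, 0.96, 0.97) — mild attrition of the size visible in
trials with strong incentive structures, leaving ~97 of 103 at the
endpoint. A monotone-dropout mode is available.

The structural core generates total baseline-to-3-month changes from the
mediation model itself — `ΔM = μ_M + a·T + ε`, `ΔY = μ_Y + Σbⱼ·ΔMⱼ + c′·T +
ε` — and apportions each systematic change across the three monthly
intervals with weights (0.55, 0.20, 0.25), mirroring the qualitative
pattern that the first treatment month moves scores the most. Interval
residuals get spread `√wᵢ·σ`, so the residual spread of the *total* change
is exactly σ and the structural model holds on the 0→3 window by
construction. Observed scores accumulate interval changes with rounding and
clipping to the instrument ranges.

The message stream is emulated too: 474 texts over a 64-day period,
delivered every other day (32 treatment days, mean 14.8 texts/day), split
within weeks by largest remainder; 198 response prompts allocated
proportionally to daily message counts; engagement simulated binomially per
day with a completion threshold of 192 responses.

## Default structural parameters, and why they are mild

Defaults: outcome baseline 33 (SD 6.5), control-arm total change −7,
residual spread 5.5, direct effect c′ = −3.5; mediator a-paths +7
(activation), −12 (distortions), −8 (perseverative thinking) with b-paths
−0.25, 0.05, 0.20. These produce a treated-arm endpoint mean near 19 and a
standardized treatment effect in the medium-to-large range.

A deliberate design choice deserves emphasis: the default effect sizes are
chosen so that simulated trajectories stay inside the instrument bounds
with ≥99% probability. Real trials of moderately-to-severely depressed
samples drive many treated participants toward the instrument floor; a
generator that reproduced endpoint means near 12 with realistic spreads
would clip 5–15% of scores at 0. Floor truncation attenuates the fitted
b path and breaks the generator's central contract — that the fitting
engine recovers the generating parameters within Monte-Carlo error. The
package chooses interpretability of the ground truth over maximal realism
of floor compression, and documents the difference: *passing the recovery
suite demonstrates correctness of the estimator under the structural model,
not robustness to the censoring-like distortion that bounded instruments
impose on real data*. Users who want to study that distortion can simply
raise the effect sizes or lower the baseline mean in their own
`structural_parameters()` — truncation is always active, the defaults just
rarely engage it.

Other generator features real data would not share: missingness is
completely at random (no MNAR mechanism), mediator residuals are mutually
independent given treatment, and item-level responses are not generated
(scores are drawn directly on the sum-score scale).

## Seeds

Every stochastic operation takes an explicit seed and restores the caller's
RNG state. A trial-level seed derives per-operation streams (sex,
randomization, scores, attrition) by fixed offsets, so fixtures are
reproducible bitwise while the streams stay independent.

# Validation studies and the problem sizes used

The test suite validates the statistical contracts at these scales, chosen
to make Monte-Carlo error small relative to the tolerances while keeping a
full run in minutes:

* **Oracle equivalence**: every random complete-data fixture is fit both by
  the engine and by explicit normal-equations arithmetic; agreement to
  1e−8 (25 random fixtures).
* **Generator recovery, large n**: one n = 4000 trial per configuration;
  fitted a/b/c′ within 3 Monte-Carlo SDs of truth, the SDs frozen from an
  independent 200-replicate study of the same design.
* **Recovery at the design size**: 100 trials at n = 103 under default
  parameters; mean fitted paths within 3 Monte-Carlo SEs of truth for all
  three mediators.
* **Bootstrap coverage**: 500 replicates at n = 103 with a known indirect
  effect of −4.2, 999 draws each; empirical 95% interval coverage within 3
  binomial SEs of nominal (observed ≈ 0.93–0.95 — the small liberal bias of
  BC intervals for coefficient products at this sample size is visible but
  inside the band).
* **Randomization**: 1,000 random stratum configurations; the marginal
  imbalance bound never violated.

# Known limitations

* The engine is not a general SEM: no measurement models, no fit indices,
  no growth curves.
* FIML SEs rely on a finite-difference observed information; for the small
  systems fitted here (≤ 6 variables) this is fast and accurate, but it is
  not optimized for wide problems.
* The generator's sum scores are drawn directly; Cronbach's alpha
  computations therefore need item-level input supplied by the user.
* Percent mediated is unstable when the total effect is near zero; the
  package flags exact zeros but near-zero totals still produce large,
  poorly determined percentages — interpret them with the bootstrap
  interval for the indirect effect, not alone.
* The scale whose published response anchors run "0 = never" to "7 = all
  the time" is stored with the 0–7 range as printed (8 response options);
  if the instrument is actually scored 1–7, adjust the registry entry via
  `instrument_spec()`.
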