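---
title: "Models and methods in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

`mrmediate` implements a three-stage causal-inference chain for an
exposure–biomarker–disease triad: bidirectional two-sample Mendelian
randomization (MR) to establish which way the exposure–biomarker causation
runs, Cox proportional-hazards modelling of both against a rare
time-to-event outcome in a cohort, and a counterfactual mediation
decomposition quantifying how much of the exposure's effect travels through
the biomarker. This vignette documents the models, the defaults and why
they are what they are, the numerical choices, and what the synthetic-data
generators do and do not establish about real data.

## Two-sample MR

### Setting and assumptions

Each instrument is a SNP with an estimated per-allele effect on the
exposure (`beta_exposure`, `se_exposure`) from one GWAS and on the outcome
(`beta_outcome`, `se_outcome`) from an independent GWAS. The causal
interpretation needs the usual three instrumental-variable assumptions:
association with the exposure, no association with confounders, and no
effect on the outcome except through the exposure. The first is screened
with the per-SNP F-statistic and the genome-wide significance filter; the
second and third are addressed by a pleiotropy exclusion list (variants
known to associate with other traits) and by the MR-PRESSO outlier test.

### Harmonization

The two GWAS may report a SNP on opposite alleles. `harmonize()` inner-joins
on SNP id and aligns the outcome effect to the exposure's effect allele:
swapped allele pairs flip the outcome beta's sign, inconsistent pairs are
dropped and counted, and SNPs missing from the outcome table are dropped
and counted. Palindromic (A/T, C/G) variants cannot be strand-checked
without allele frequencies, which many summary files omit; they are kept
with a warning by default and `drop_palindromic = TRUE` removes them. The
bookkeeping identity `retained + dropped_missing + dropped_inconsistent =
input` is tested as an invariant.

### Estimators

* **IVW (fixed effect).** Closed form
  `β̂ = Σ wⱼ β_Xj β_Yj / Σ wⱼ β_Xj²`, `wⱼ = 1/se_Yj²`, equal to the
  weighted least-squares slope of outcome betas on exposure betas through
  the origin; the tests verify agreement with an `lm()` oracle to 1e-10.
  The fixed-effect standard error `(Σ wⱼ β_Xj²)^{-1/2}` assumes one common
  causal effect; no multiplicative random-effect inflation is offered in
  this version.
* **Weighted median.** Wald ratios are ordered; with normalized weights
  `wⱼ ∝ 1/se_ratioⱼ²` the estimate is the linear interpolation of the
  ratio at cumulative-midpoint weight 0.5. Ties in the ratio ordering are
  broken by input order (a stable sort). The method tolerates up to half
  the weight on invalid instruments, which the tests exercise with a
  planted wild ratio. The weight definition deserves a note: descriptions
  of the estimator sometimes say "weight equal to the inverse of the
  standard error", but the conventional implementation — and the one here —
  uses the inverse variance `1/se²`. The standard error comes from a
  parametric bootstrap (default `n_boot = 1000`) redrawing both betas from
  their sampling distributions; the point estimate is deterministic, only
  the SE/CI are seed-dependent.
* **MR-PRESSO.** For each SNP the leave-one-out IVW slope predicts its
  outcome beta; the observed weighted residual sum of squares is compared
  against `n_sim` (default 1000) simulated tables drawn under the
  no-pleiotropy model. The global p-value uses the `(1 + #{sim ≥ obs}) /
  (n_sim + 1)` continuity form, so it is never exactly zero. Per-SNP
  outlier p-values are Bonferroni-adjusted by the number of instruments
  and flagged at `outlier_alpha = 0.05`; with 50 instruments this means at
  least 1000 simulations are needed for a flag to be reachable, which is
  why the default is not lower. The corrected estimate is the IVW on
  non-outliers. The original method's distortion test is deliberately not
  implemented: the analysis chain this package supports uses outlier
  removal and the corrected estimate only.

All confidence intervals are normal-theory on the estimate scale
(`±qnorm(0.975)·SE`) with two-sided normal p-values.

## Cohort models

Follow-up runs from enrollment to the earliest of diagnosis, death, loss to
follow-up, or the administrative end of follow-up, in years of 365.25 days;
the event indicator is set only when the earliest date is a diagnosis.
Exposures are coded three ways: continuous per sample SD (denominator
n−1, complete cases), binary at a threshold (default 24 kg/m² — the
overweight cut-off for BMI; 80 cm is the analogous waist value), and
quartiles from linear-interpolation percentiles with boundary ties going to
the lower group and Q1 as the reference.

The three nested covariate sets mirror a typical epidemiological analysis:
model 1 adjusts for demographics and lifestyle (age, smoking, drinking,
education, marital status, enrollment batch); model 2 adds reproductive
history and medication use (parity, age at menopause, mastitis history,
diuretics, antibiotics, hormone replacement therapy); model 3 additionally
adjusts the exposure for the paired biomarker and vice versa. Missing data
are handled by complete-case exclusion per model — no imputation.

Partial-likelihood maximisation is delegated to `survival::coxph` with
Efron tie handling (the less biased choice under the day-level ties real
cohorts have; Breslow is available and the tests confirm the two coincide
on untied data) and tight convergence control (`eps = 1e-10`, up to 100
iterations). The Cox coefficient is checked in the tests against a
grid search of the hand-written partial likelihood on a small fixture.
The proportional-hazards assumption is assessed with scaled Schoenfeld
residuals against follow-up time (`survival::cox.zph`, identity
transform) rather than by episode-splitting a time × exposure product term:
the residual test examines the same null, needs no data surgery, and is
the field's standard diagnostic. A first-year-exclusion sensitivity
analysis (drop subjects *diagnosed* within one year; keep early censorings)
guards against reverse causation.

## Mediation

With a linear mediator model `M = β₀ + β₁A + β₂'C + ε` and a Cox outcome
model with log-hazard `θ₁A + θ₂M + θ₃'C` (no exposure–mediator
interaction), the counterfactual natural effects on the log hazard-ratio
scale are, for an exposure contrast `Δa`:

* natural direct effect `NDE = θ₁Δa`,
* natural indirect effect `NIE = θ₂β₁Δa`,
* total effect `TE = NDE + NIE` (an identity, exact by construction),
* proportion mediated `PM = NIE / TE`.

This product-method decomposition is valid under the rare-outcome
approximation (hazard ratios approximately collapse like odds ratios when
cumulative incidence is low; the synthetic cohort keeps incidence near 1%
so the approximation error is negligible) and requires no
exposure-induced mediator–outcome confounding. The no-interaction form is
the default because the intended analyses found interaction terms
immaterial; an interaction-aware extension is a possible future addition
but is not part of this version.

Two CI constructions are offered. The delta method treats the mediator-
and outcome-model estimates as independent (they share the same subjects,
but the cross-covariance is not identified from separate fits; treating
them as independent is standard two-model practice):
`Var(NDE) = Δa²Var(θ₁)` and `Var(NIE) = Δa²(β₁²Var(θ₂) + θ₂²Var(β₁))`.
The subject-resampling bootstrap (`mediation_bootstrap`, percentile
95% CIs, point estimates kept at their full-data values, at least 200
replicates, erroring if more than 10% fail) avoids the independence
assumption and is the recommended interval for publication-grade runs.
`Δa` defaults to one sample SD of the exposure, with the reference level
immaterial under the no-interaction specification. Degenerate cases are
surfaced, not hidden: a zero total effect yields `NA` with a warning, and
opposite-signed NDE/NIE trigger an out-of-[0,1] warning on the proportion.

PM is invariant to rescaling the mediator (θ₂ scales by 1/c, β₁ by c),
which the tests verify numerically.

## Synthetic data: what it emulates and what it does not

`simulate_gwas()` draws exposure betas from a normal distribution
re-drawn (truncated) to genome-wide significance — instruments taken from
a GWAS are significant by construction — and forms outcome betas as
`θ·β_X + α + ε` with per-SNP noise at the stated standard errors.
Pleiotropy is injected via `α`: mean-zero for balanced, positive-mean for
directional (the regime MR-PRESSO is exercised against). Defaults: 50
independent SNPs, `θ = 0.2`, exposure betas `N(0.03, 0.01)` with SEs of
0.003 on both sides — instrument strength (F ≈ 100) typical of a
biobank-scale GWAS of an anthropometric trait.

`simulate_cohort()` emulates a cohort of postmenopausal women: BMI-like
exposure `N(24.3, 3.5)` kg/m²; uric-acid-like mediator with slope 5 μmol/l
per kg/m² (matching the observed exposure–mediator correlation of ≈0.23
given the marginal SDs) and residual SD 72 so the marginal SD is ≈75
μmol/l; a correlated waist measurement; a covariate block drawn at the
cohort's baseline prevalences, independent of the exposure by default
(`confounded = TRUE` ties age to both exposure and hazard to test
adjustment behaviour); and event times from a Weibull baseline hazard
multiplied by `exp(θ₁·BMI + θ₂·UA)` via inverse-transform sampling, with
administrative censoring at 8.2 years. The baseline rate is calibrated in
closed form from lognormal moments of the relative risk so expected
cumulative incidence matches the target (211/19,518 ≈ 1.08%); the
first-order approximation used is accurate to well under the binomial
sampling error at this incidence. Default hazards are HR 1.25 per exposure
SD direct and 1.05 per SD through the mediator, giving a generating truth
for the proportion mediated of `log(1.05)/log(1.3125) ≈ 0.178` — recorded,
with every other parameter, in the `truth` attribute and the fixture-suite
manifest so recovery tests are self-describing.

What passing these tests shows: the estimators are consistent, unbiased at
the study scale, and correctly seeded; the bookkeeping identities hold; the
pipeline runs end to end reproducibly. What they cannot show: behaviour
under linkage disequilibrium between instruments, population
stratification, strand ambiguity resolved by allele frequency, informative
censoring, measurement error in the mediator, or real-world missingness
patterns — none of which the generators model. Conclusions about any real
dataset still require the usual sensitivity analyses on that dataset.

## Numerical and design choices

* Instrument F-statistics use the squared Wald ratio `(β/SE)²`, the only
  form computable from summary data.
* Selection filters apply in a fixed order (significance, strength,
  pleiotropy list); a SNP failing several is counted once, under the first.
  The retained set is order-insensitive; only the removal attribution
  depends on the order.
* When a simulated bootstrap draw makes an exposure beta exactly zero the
  corresponding ratio is dropped for that replicate rather than producing
  an infinite ratio.
* CI multipliers use `qnorm(0.975)` = 1.959964, not the rounded 1.96.
* Dates are ISO-8601; years are 365.25 days; all text I/O is tab-separated
  UTF-8 with "." as the decimal point.
* Replicate counts in the test suite (50 synthetic cohorts for parameter
  recovery, 200 seeds for the outlier-test error rates, 1000 simulations
  per MR-PRESSO run) were chosen so Monte-Carlo error is small relative to
  the tolerances being checked while the whole suite stays fast enough to
  run on every change.

## Known limitations

* No MR-Egger, mode-based, contamination-mixture or multivariable MR
  estimators; no LD clumping (input GWAS are assumed to report independent
  SNPs).
* No competing-risks or time-varying-covariate survival models; no
  multiple imputation.
* Single mediator only; no exposure-induced mediator–outcome confounding;
  the mediation decomposition leans on the rare-outcome approximation and
  will drift for common outcomes.
* The published per-SNP instrument tables of the motivating analyses are
  access-restricted, so the package's acceptance checks against those
  published estimates can only run where the user supplies the tables
  (`inst/extdata/instruments/`); everything else is validated against
  synthetic ground truth and independent oracles.
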