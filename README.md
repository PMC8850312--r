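# mrmediate

Causal-inference toolchain for the question "does an exposure raise a
biomarker, and does that biomarker carry part of the exposure's effect on a
rare disease?" — the archetype being body-mass index (BMI), serum uric acid
(UA) and incident postmenopausal breast cancer. The package chains three
analyses that are usually run with three different tools:

1. **Bidirectional two-sample Mendelian randomization (MR)** on GWAS
   summary statistics, to establish the causal direction between exposure
   and biomarker. Genetic variants serve as instrumental variables: each
   SNP *j* contributes a Wald ratio `β_Yj / β_Xj`, and the instruments are
   combined by
   - the **fixed-effect inverse-variance weighted (IVW)** estimator
     `β̂ = Σ w_j β_Xj β_Yj / Σ w_j β_Xj²` with `w_j = 1/se_Yj²` and
     `SE = (Σ w_j β_Xj²)^(-1/2)`;
   - the **weighted median** (the 50%-cumulative-weight point of the
     ordered Wald ratios, weights `1/se_ratio²`; parametric-bootstrap SE),
     consistent when valid instruments carry ≥ 50% of the weight;
   - **MR-PRESSO**, a residual-sum-of-squares resampling test that detects
     horizontally pleiotropic outlier SNPs and reports an outlier-corrected
     IVW estimate.
   Instrument QC (per-SNP F-statistic `(β/SE)²` with the conventional
   F ≥ 10 cut, genome-wide significance `p < 5×10⁻⁸`, and a pleiotropy
   exclusion list) and allele harmonization (sign-flipping allele-swapped
   records, dropping inconsistent or missing SNPs) are built in.
2. **Cox proportional-hazards modelling** of the exposure and the mediator
   against the time-to-event outcome in a prospective cohort, with three
   nested covariate sets, per-SD / binary / quartile exposure codings,
   person-years bookkeeping, a first-year-exclusion sensitivity analysis,
   and a scaled-Schoenfeld-residual check of the proportional-hazards
   assumption.
3. **Counterfactual mediation for the survival outcome** under the
   rare-outcome approximation, combining the linear mediator model
   (`M = β₀ + β₁ A + β₂'C + ε`) with the Cox outcome model (log-hazard
   `θ₁ A + θ₂ M + θ₃'C`, no exposure–mediator interaction):

   ```
   NDE = θ₁ Δa      NIE = θ₂ β₁ Δa      TE = NDE + NIE
   proportion mediated = NIE / TE        (log hazard-ratio scale)
   ```

   with delta-method or subject-resampling bootstrap confidence intervals;
   `Δa` defaults to one sample SD of the exposure.

Because the real inputs (national-biobank GWAS summary files, an
individual-level cohort) are access-restricted, the package ships
seed-deterministic generators — `simulate_gwas()` and `simulate_cohort()` —
whose defaults emulate the study setting (50 independent instruments with a
causal effect of 0.2; 19,518 women with BMI-like exposure, UA-like mediator
and ~1% cumulative incidence over 8.2 years) and whose ground truth is
recorded, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(mrmediate)

# forward MR: does the exposure raise the biomarker?
gwas <- simulate_gwas(n_snps = 50, true_theta = 0.2, seed = 42)
mr_ivw(gwas)
#> IVW: beta = 0.2086 (95% CI 0.1843, 0.2329), p = 1.07e-63, n_snps = 50
mr_weighted_median(gwas, seed = 42)
#> weighted_median: beta = 0.2186 (95% CI 0.1836, 0.2536), p = 2.07e-34, n_snps = 50
mr_presso(gwas, seed = 42)
#> MR-PRESSO: global p = 0.6354 (RSS_obs = 47.38, 1000 simulations)
#>   no outliers detected
#> MR_PRESSO: beta = 0.2086 (95% CI 0.1843, 0.2329), p = 1.07e-63, n_snps = 50
```

All three estimators recover the generating causal effect 0.2 within their
confidence intervals, and the pleiotropy test is quiet on a clean table.

```r
# cohort mediation: how much of the exposure effect runs through the mediator?
cohort <- simulate_cohort(seed = 42)   # 19,518 subjects, 211 events
mediate_survival(cohort, "bmi", "ua", covariates = model_covariates(2))
#> Mediation (delta CIs, exposure contrast 3.547):
#>  effect  log_hr      se    hr ci_low ci_high     pval
#>     NDE 0.14470 0.07099 1.156  1.006   1.328 0.041510
#>     NIE 0.04457 0.01620 1.046  1.013   1.079 0.005938
#>      TE 0.18927 0.07281 1.208  1.048   1.394 0.009336
#> Proportion mediated (log-HR scale): 23.6%
```

The NDE row is the hazard ratio per exposure SD holding the mediator at its
natural value; the NIE row is the part transmitted through the mediator.
The generator's true proportion mediated is
`log(1.05)/log(1.3125) ≈ 17.9%`; a single cohort's estimate scatters around
that (23.6% here), and averaging over replicate cohorts recovers the truth
(see the test suite).

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/mrmediate.R mr --exposure exp.tsv --outcome out.tsv \
    --method all --seed 1 --out results.tsv
```

with subcommands `mr`, `presso`, `cox`, `mediate`, `simulate-gwas`,
`simulate-cohort`; every run writes a tab-separated results file plus a
JSON metadata sidecar.

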