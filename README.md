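# dosetrend

Two-stage dose-response meta-analysis for published category-level cohort
results, built around the setting where a liver-enzyme exposure (baseline
alanine aminotransferase, ALT, in U/L) is related to the risk of incident
metabolic syndrome across several prospective cohorts that each report
adjusted relative risks for three or more ordered ALT categories.

Published tables give, per category, an adjusted RR with a 95% CI plus the
category margins (events and participants or person-time). Because every
category is compared against the same reference group, the log RRs within a
study are correlated, and naive weighted regression of log RR on dose
understates uncertainty. `dosetrend` implements the standard machinery for
this problem:

- **Greenland–Longnecker covariance reconstruction.** For each study, fitted
  pseudo-cases `a_i` are found such that the design's crude RR formula
  applied to `(a_i, n_i)` reproduces each adjusted log RR exactly while
  conserving the total-case margin (solved by bisection on the reference
  cell `a_0`). The fitted reference cell yields the shared covariance of the
  log RRs (e.g. `1/a_0 − 1/n_0` for cumulative-incidence designs); reported
  variances stay on the diagonal.
- **Generalized least-squares trend estimation.** Per study,
  `β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹L` with `L` the non-reference log RRs, `C` the
  reconstructed covariance and `X` the dose contrast with the reference
  category — either linear (`d − d_ref`) or a restricted cubic spline with 3
  knots at the 25th/50th/75th weighted percentiles of the pooled dose
  distribution (two coefficients; the second captures departure from
  linearity).
- **Pooling.** Sex/subgroup strata are combined within study by fixed-effect
  inverse variance; studies are combined by fixed effects and by
  DerSimonian–Laird random effects (`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`,
  with a scalar-τ² multivariate analogue for the spline coefficients).
  Heterogeneity is summarized by Cochran's Q and `I² = max(0, 100(Q − df)/Q)`
  with the Higgins test-based CI on the ln H scale.
- **Diagnostics.** Wald test of the second spline coefficient
  (nonlinearity), Egger regression and Begg rank-correlation tests for
  funnel-plot asymmetry, and leave-one-out sensitivity re-pooling.
- **Synthetic cohorts.** A generator produces category-level cohort studies
  with a known true dose-risk curve (linear, threshold, or custom), sized
  like the five published cohorts (29,815 participants, ~2,125 events), so
  the whole pipeline is testable without access to unpublished
  category-level data.

Trends are reported as the RR for a 5 U/L increment in ALT, and the pooled
curve is anchored at RR = 1 at 6 U/L (the median of the lowest reference
range in the published analysis).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 01
simulates a five-cohort study table with a true RR of 1.14 per 5 U/L; steps
02–04 fit, pool and diagnose it:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_trend_fit.R
Rscript analysis/03_pool_curve.R
Rscript analysis/04_bias_sensitivity.R
```

which prints (seed 20140429):

```
Pooled dose-response (random effects) -> results/pipeline/
  RR per 5 U/L: 1.162 (95% CI 1.135-1.189)
  heterogeneity: Q = 0.05 on 4 df (p = 1.00), I2 = 0.0% (95% CI 0-79%), tau2 = 0
  spline knots at 10.2 / 17.9 / 23.0 U/L
  P for nonlinearity: 0.79 (fixed), 0.79 (random)
  curve: 100 points over 6-37 U/L, RR(6) = 1.00
  ...
  Egger: intercept 0.141 (se 0.211), p = 0.55  [k = 5; low power at this k]
  leave-one-out RRs range 1.161 to 1.162
```

The pooled RR of 1.162 is one realization's estimate of the true 1.14 (its
95% CI spans roughly ±0.03); the heterogeneity, nonlinearity and bias
diagnostics are all null, as they should be for homogeneous linear truth.
Programmatically the same run is:

```r
library(dosetrend)
studies <- generate_meta_dataset(sim_spec(), true_curve(slope = log(1.14)/5),
                                 seed = 20140429)
res <- run_pipeline(studies, run_config(increment = 5, reference_dose = 6))
res$summary$pooling$rr_per_increment
```

`run_pipeline()` also accepts a study-table CSV path (long format, one row
per category; see `?read_study_table`) and an `out_dir` to write the summary
JSON, curve/per-study/funnel TSVs and a run manifest.

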