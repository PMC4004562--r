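---
title: "Dose-response meta-analysis of category-level cohort data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response meta-analysis of category-level cohort data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosetrend)
```

## The problem

Prospective cohort studies of a continuous exposure — here baseline alanine
aminotransferase (ALT, U/L) and incident metabolic syndrome — usually publish
their results as a small table: three to five ordered exposure categories,
each with an adjusted relative risk and 95% CI against the lowest (reference)
category, plus the number of events and participants per category. A
dose-response meta-analysis has to turn each such table into a study-level
trend (log RR per U/L) with an honest variance, and then combine trends
across studies. Two statistical obstacles drive the design:

1. **Within-study correlation.** All category RRs share the reference group,
   so their log RRs are positively correlated. Treating them as independent
   understates the trend variance.
2. **Only summary data.** The adjusted RRs come from covariate-adjusted
   models we cannot refit; all we have are the published RRs, CIs and
   category margins.

## Stage one: per-study trends

### Dose scoring

Each category needs one scalar dose. The rules, in priority order: a
reported category median is used verbatim; a closed interval gets its
midpoint; an open-ended interval gets the closed bound plus/minus half the
width of the adjacent closed category, floored at 0 U/L (ALT cannot be
negative). The open-interval convention is the standard one in this
literature; the source publications do not state how their open categories
should be scored, so it is a documented package choice, not an extracted
fact. Categories are sorted by dose first, making the assignment invariant
to input order, and the resulting doses must be strictly increasing.

### Covariance reconstruction (Greenland–Longnecker)

Let `L_i = ln RR_i` for the non-reference categories, with reported
variances `V_i = ((ln ci_high − ln ci_low)/(2z))²`. We reconstruct the
off-diagonal covariance by finding pseudo-cases `a_i ≥ 0` such that

- the design's *crude* RR formula applied to `(a_i, n_i)` reproduces each
  adjusted `L_i` exactly (cumulative incidence and incidence rate:
  `(a_i/n_i)/(a_0/n_0)`; case-control: the odds ratio
  `(a_i b_0)/(a_0 b_i)`, `b_i = n_i − a_i`), and
- the fitted cases conserve the study's total-case margin `Σ a_i = A`.

Every `a_i` is an explicit function of the reference cell `a_0`, and the
margin is strictly increasing in `a_0`, so the system reduces to a
one-dimensional root-finding problem. We solve it by bisection on
`(ε, min(A, n_0))` with `ε = 10⁻⁹A`, a residual tolerance of `10⁻¹⁰` and an
iteration cap of 200 — bisection rather than Newton because the bracket
guarantees convergence for any feasible input. For the cumulative-incidence
and incidence-rate designs the margin equation happens to be linear in
`a_0`, but one code path covers all three designs. Infeasible inputs (no
root in the bracket, or fitted cells exceeding category totals) are
reported as data errors, not silently adjusted.

The covariance is then assembled with the *reported* variances on the
diagonal and the reconstructed terms off it: `C_ij = 1/a_0 − 1/n_0`
(cumulative incidence), `1/a_0` (incidence rate), `1/a_0 + 1/b_0`
(case-control), `i ≠ j`. Keeping the reported variances preserves the
covariate adjustment baked into the published CIs. Positive definiteness is
checked; a failure is surfaced as a data-review error. Two degenerate
situations are handled explicitly: a category with zero observed events
gets 0.5 added to its case count before fitting (with a warning), and a
study missing counts altogether degrades to a diagonal (independence)
covariance with a prominent warning.

### GLS trend and splines

With `C` in hand, the study trend is generalized least squares through the
reference origin: `β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹L`, `cov(β) = (XᵀC⁻¹X)⁻¹`. The linear
model uses `X_i = d_i − d_ref`. The nonlinear model uses a restricted cubic
spline with 3 knots `k1 < k2 < k3`: `s1(d) = d` and

    s2(d) = [(d−k1)₊³ − (d−k2)₊³ (k3−k1)/(k3−k2) + (d−k3)₊³ (k2−k1)/(k3−k2)] / (k3−k1)²

so the curve is linear below `k1` and beyond `k3`, and the second
coefficient measures departure from linearity. Fitting a spline needs at
least three non-reference categories; studies with only three categories
contribute to the linear pooling but not the spline pooling.

Knots are placed at the 25th/50th/75th percentiles of the pooled vector of
assigned category doses across all studies, weighted by category totals.
"The distribution" is ambiguous in this setting — it could mean the pooled
participant-level exposure distribution, which is unavailable — so the
package defines it precisely: weighted empirical quantiles with linear
interpolation on the cumulative-weight scale, positions
`u_k = (C_k − w_k)/(W − w_k)`, which reduce to the standard type-7 sample
quantile under equal weights and are invariant to rescaling all weights.

Matrix solves go through Cholesky factorization with a reciprocal-condition
threshold of `10⁻¹²`; a singular GLS information matrix (e.g. a spline
requested with two non-reference categories) is a rank error.

## Stage two: pooling

Strata of one cohort (e.g. sexes) are first combined by multivariate
fixed-effect inverse variance. Across studies, both fixed- and
random-effects summaries are computed. Random effects use the
DerSimonian–Laird moment estimator; for the bivariate spline coefficients a
single scalar `τ²` is added to each coefficient's variance, moment-matched
on the multivariate `Q` with denominator `Σ tr(W_i) − tr((ΣW_i)⁻¹ ΣW_i²)`
(the exact univariate DL formula when the dimension is 1). A full
unstructured between-study covariance is deliberately out of reach: five
studies cannot support three extra variance parameters. `τ²` is truncated
at zero, and with `τ² = 0` random effects collapse onto fixed effects
exactly.

Heterogeneity is reported as Cochran's `Q` (multivariate generalization
`Σ(β_i − β_FE)ᵀ cov_i⁻¹ (β_i − β_FE)`, df `= p(k−1)`) and
`I² = max(0, 100(Q − df)/Q)`. The I² confidence interval is the
Higgins–Thompson test-based one: `H = sqrt(Q/(k−1))` truncated at 1,
`se(ln H)` from the large-Q formula when `Q > k` and from the small-Q
formula otherwise, CI formed on the ln H scale and mapped through
`I² = 100(H² − 1)/H²` with final truncation to [0, 100]. Truncating `H`
before the CI is what reproduces the conventional printed intervals (for
`k = 5` and a Q p-value of 0.59 this yields 0% with upper bound 79%); the
[0, 100] truncation of I² itself is applied only after mapping.

Nonlinearity is a Wald test of the pooled second spline coefficient,
`z = β₂/se(β₂)`, two-sided normal p. Both the fixed- and random-effects
versions are computed and reported, since with homogeneous data they
usually coincide; under a homogeneous truth the fixed-effect version is the
calibrated one (estimating `τ²` can only add noise and makes the
random-effects test mildly conservative), which is why the package's
calibration checks target it. All CIs use standard-normal multipliers, the
conventional meta-analytic choice.

## Bias and sensitivity

Egger's test is the classical unweighted form: OLS of the standardized
effect `β_i/se_i` on precision `1/se_i`, two-sided t-test on the intercept
with `k − 2` df. Begg's test is Kendall's tau between the
variance-stabilized deviations `(β_i − β_FE)/sqrt(var_i − var_FE)` and the
variances, with tie-adjusted score variance and a continuity correction
(|S| − 1) in the normal approximation; a study with `var_i ≤ var_FE` gets a
tolerance floor (logged). With five studies both tests are severely
underpowered, and the output carries `k` so readers can judge that.
Leave-one-out re-pools the remaining `k − 1` studies by random effects and
reports each result per increment.

## The synthetic generator

`sim_spec()` / `generate_meta_dataset()` emulate the five-cohort setting the
package was built around:

- cohort sizes fixed at the published 3,545 / 1,097 / 21,535 / 2,957 / 681
  participants, with baseline risk calibrated so expected events match the
  published 309 / 226 / 802 / 608 / 180;
- 4 / 4 / 5 / 4 / 4 exposure categories (quartile/quintile-style splits)
  spanning 6–40 U/L, interior boundaries jittered by a truncated
  `N(0, 1 U/L)` per cohort so category layouts differ across studies;
- participants allocated to categories by a lognormal ALT distribution
  (meanlog `log(18)`, sdlog 0.5, truncated to 6–40 U/L). Population ALT is
  right-skewed, so the lowest (reference) category is the most populous —
  as in real cohorts — which also keeps the reference pseudo-cell well
  estimated;
- events drawn binomially with risk `baseline · exp(logRR(d) − logRR(d_ref))`
  evaluated at the category midpoint; crude RRs with log-scale Wald CIs
  (0.5 continuity correction for zero cells) reported against the lowest
  category;
- between-study `τ² = 0` by default, matching the observed absence of
  heterogeneity (`I² = 0%`); study-specific slopes are drawn from
  `N(slope, τ²)` when heterogeneity is wanted;
- true curves: linear (default slope `ln(1.14)/5` per U/L), threshold
  (flat, then linear), or any user-supplied log-RR function.

What the generator does *not* emulate: covariate adjustment (the simulated
RRs are crude; the pipeline consumes RR + CI regardless of how they were
adjusted, and simulating confounding would add untestable degrees of
freedom), within-person variation in ALT, person-time reporting for
incidence-rate designs (the published table gives no person-time, so those
parameters would be free choices), and non-lognormal exposure shapes.
Passing recovery tests therefore demonstrates that the *statistical
machinery* is unbiased and calibrated under realistic sizes and category
structures — not that any particular published estimate is free of
confounding or measurement artefacts.

## Calibration results computed by this package

The test suite and `scripts/acceptance.R` compute (not assert from
constants): recovery of a true per-5 U/L RR of 1.14 by the full pipeline
over 500 synthetic five-cohort meta-datasets, with mean bias required to be
within 2 Monte-Carlo standard errors; type-I error of the (fixed-effect)
nonlinearity Wald test within 5% ± 2% over 1000 linear-truth replicates; a
directional power check that a threshold-shaped truth is flagged more often
than a linear one; and oracle agreement of every stage (grid search for the
pseudo-counts, explicit matrix algebra for GLS, hand OLS for Egger,
exhaustive pair counting for Begg, `metafor` for DL pooling). Those problem
sizes — 500 and 1000 replicates at the five published cohort sizes — were
chosen as the smallest at which the Monte-Carlo error is well below the
effects being checked.

## Known limitations

- Two-stage estimation with the moment `τ²`; no REML or Paule–Mandel
  estimators, no meta-regression.
- Scalar-`τ²` spline random effects (see above); the pooling interface
  would accommodate a full multivariate estimator if study counts ever
  justified one.
- The Greenland–Longnecker construction assumes the reported categories are
  internally consistent (margins compatible with the RRs); the Hamling
  variant, which relaxes the variance treatment, is not implemented.
- Exact design information (cumulative incidence vs incidence rate vs
  case-control) is a required input column; the covariance formulas differ
  and the package refuses to guess.
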