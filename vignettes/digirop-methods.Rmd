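---
title: "Methods: a birth-based piecewise-exponential risk model for ROP treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a birth-based piecewise-exponential risk model for ROP treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digirop)
```

## The model and its assumptions

Retinopathy of prematurity (ROP) screening decisions hinge on how likely an
infant is to progress to treatment-requiring disease.  The model implemented
here predicts that risk from three quantities fixed at birth — gestational
age (GA, weeks+days), sex, and the birth-weight SD score (BWSDS) — by
modelling the *hazard* of treatment on the postnatal-age time axis and
integrating it into a cumulative risk
$F(t) = 1 - S(t) = 1 - \exp\{-\int_0^t h(u)\,du\}$.

The log hazard is piecewise linear in postnatal age with knots at 8 and 12
weeks (the momentary risk rises to a peak near 12 weeks and falls
afterwards, regardless of GA), piecewise linear in GA with a knot at 27
weeks, piecewise linear in BWSDS with a knot at −1 SDS, and includes three
interaction blocks: postnatal age × GA, sex × GA, and postnatal age ×
BWSDS.  Sex enters numerically as its code (1 = boy, 2 = girl) both in the
main effect and in the sex × GA product.  All spline bases are in
*segment-slope* form — `min(t, 8)`, `clamp(t − 8, 0, 4)`, `max(t − 12, 0)`
and analogously for GA and BWSDS — so each published coefficient is the
log-hazard slope per unit within its labelled range.

Key modelling assumptions, inherited with the functional form:

* the hazard is a smooth (continuous, piecewise log-linear) function of
  postnatal age: no left truncation, with risk accumulating from birth
  (the hazard implied by the intercept is negligible in the first weeks,
  so this is immaterial in practice);
* covariates act proportionally on the hazard, with the time-interactions
  allowing segment slopes to tilt by GA and BWSDS;
* follow-up beyond 20 postnatal weeks is out of model support: the
  cumulative risk is reported at a 20-week horizon and extrapolation is
  refused unless explicitly requested.

Because the log hazard is linear on each segment, the cumulative hazard has
the closed form $\sum_s (e^{a_s + b_s t_2} - e^{a_s + b_s t_1})/b_s$ with
the constant-hazard limit $e^{a_s}(t_2 - t_1)$ substituted when
$|b_s| < 10^{-10}$ (guarding catastrophic cancellation).  Tests verify the
closed form against adaptive quadrature to $10^{-8}$ relative error.

## Resolving the unprinted encoding constants

The published coefficient table fixes 14 estimates, but two conventions are
not printed: the centering constants of the GA and BWSDS bases, and which
postnatal-age quantity multiplies the interaction terms.  These are
resolved by inversion: the printed 20-week risks for eight covariate
profiles (girls/boys at GA 24 and 25 weeks with BWSDS −3 and 0) are treated
as constraints on the encoding with the coefficients held fixed, and
`calibrate_encoding()` searches a deterministic coarse grid followed by
Nelder–Mead refinement over `c_ga_main` and `c_bwsds`, crossed with the
structural choice of interaction time quantity.  The printed girl-vs-boy
hazard ratios (0.83 at GA 25, 0.50 at GA 27) independently pin the GA
centering of the sex × GA product at 28, since
$\mathrm{HR}(g) = \exp\{\beta_{sex} + \beta_{sex \times GA}(g - c)\}$
reproduces both printed values only at $c = 28$.

The search lands at `c_ga_main` ≈ 27.9–28.1 and `c_bwsds` ≈ 0 with
interactions multiplying raw $t$; the shipped encoding uses the round
values `c_ga_main = 28`, `c_bwsds = 0`, which reproduce all eight printed
risks to within 0.11 percentage points (tolerance 0.005 in probability
units, since the printed values carry three significant digits).  The
alternative structural form (interactions multiplying `min(t, 8)`) fits
clearly worse and is rejected by the search.  The problem is
over-determined — eight risk constraints plus two hazard-ratio constraints
against two free constants — which is why the inversion is trusted.
Calibration never touches the coefficient vector.

```{r calibration}
cal <- calibrate_encoding()
cal
verify_hr_consistency(cal$encoding)$hr
```

Worked-example GA values are interpreted as exact completed weeks (24+0,
25+0); this convention reproduces the printed risks, whereas mid-week
interpretations do not.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| horizon | 20 | weeks | risk is interpreted over 20 postnatal weeks; predictive ability plateaus after ~15 weeks |
| `interval_width` (fitting) | 1 | weeks | screening is weekly; a 0.5-week sensitivity check is in the test suite |
| `t_eval` | midpoint | — | midpoint evaluation reduces discretization bias for steeply rising hazards; `"left"` available |
| `n_draws` (bands) | 1000 | draws | matches the published resampling count |
| screening threshold | 0.001 | probability | the cumulative-risk level below which a first exam is considered safe to defer |
| interaction retention | 0.10 | p-value | the forward-selection rule used to build the final model |

## Uncertainty

Confidence bands for $F(t)$ are parametric bootstrap: coefficient vectors
are drawn from a multivariate normal with the model's covariance (Cholesky,
with an eigendecomposition fallback for semi-definite matrices), $F(t)$ is
recomputed under each draw, and the band is the 2.5/97.5 percentile per
grid point.  The percentile form was chosen over a normal approximation as
the natural reading of a resampling-based interval; the normal version is
available via `method = "normal"`.  The point estimate is always the
original coefficient vector's risk, never the draw mean.  Since
$F = 1 - e^{-H}$ with $H \ge 0$, draws never need clipping.

The published report provides standard errors but not the full covariance,
so `digirop_model()` carries a *synthetic* diagonal covariance
(`diag(se²)`), clearly flagged.  Diagonal covariances grossly overstate
band widths for this model (the intercept SE alone spans several log-hazard
units; in a real fit it is strongly negatively correlated with the slope
coefficients), so meaningful bands should come from a model refitted on
cohort data, whose inverse-information covariance carries the correlation
structure.  Coverage of the full fit-then-band pipeline is checked on
simulated cohorts in the test suite.

## Fitting pipeline

`digirop_fit()` reproduces the estimation machinery: follow-up is expanded
into person-time intervals, each interval contributes a Poisson
observation with log-exposure offset, and the 14-column design is evaluated
at the interval midpoint.  The likelihood is maximized by iteratively
reweighted least squares (base R's `glm` machinery); the covariance is the
inverse observed information, verified against a numerical Hessian to
$10^{-4}$ relative error in the tests.  Closed-form sanity anchors:
an intercept-only fit returns events/exposure exactly, and a saturated
two-stratum fit returns per-stratum rates exactly.  `interaction_screen()`
implements the forward P < .10 retention rule with joint Wald tests for
multi-column terms (chosen over likelihood-ratio tests for determinism and
speed; LR is available), testing candidates in the fixed order
postnatal-age × GA, sex × GA, postnatal-age × BWSDS.

The original interval construction is not stated in the source material;
width 1 week and midpoint evaluation are this package's conventions, both
configurable.

## The synthetic cohort generator

`simulate_cohort()` emulates a national very-preterm screening cohort: GA
weights default to the per-GA-week totals of the Swedish register cohort
(436/620/801/949/1179/1479/1791 for weeks 24–30) with days uniform within
the week; 54.6% boys; BWSDS from a normal(−0.5, 1.3) truncated to [−5, 3],
a left-shifted mix approximating the growth restriction prevalent in this
population.  Event times are drawn *exactly* from the model's piecewise
log-linear hazard by inverting $H(t) = -\log(1-U)$ segment by segment in
closed form, then administratively censored at 20 weeks (or a GA-dependent
rule).  Under the published coefficients this yields a treated fraction of
roughly 4–6%, consistent with national screening experience.

What the generator does *not* emulate: ROP stages and zones, longitudinal
weight gain, competing mortality, transfer-related censoring patterns, and
the exact covariate joint distribution of the source register.  Passing tests therefore
demonstrate internal correctness (the sampler matches the analytic
survival; the fitting pipeline recovers generating parameters with nominal
CI coverage; discrimination of the 20-week risk falls in a plausible 0.85 to
0.95 AUC envelope) — they do not re-establish the published real-cohort
AUCs, specificities, threshold ages, or avoided-visit counts, all of which
require registry data.

## Screening-schedule logic

`suggested_first_exam()` implements the published safety rule: the integer
part of the earliest observed treatment age in a GA stratum minus one week.
`risk_threshold_age()` finds, on a 0.1-week grid (the precision of the
published schedule table), the latest age at which cumulative risk is still
below 0.001.  The threshold age is read as *population-averaged* over the
stratum's empirical sex/BWSDS mix — the published footnote names the
population's covariate distribution — with a per-infant (most conservative)
variant exposed as an option.  `avoided_visits()` counts one visit per week
from schedule start to each infant's screening end; an earlier new start
never counts negatively.

## Numerical choices and degenerate inputs

* Constant-hazard limit at $|b| < 10^{-10}$ in both integration and
  inverse-CDF sampling.
* Log-hazard continuity at the knots holds by construction of the
  segment-slope basis; tested to $10^{-9}$.
* Cumulative-risk evaluation refuses $t$ beyond the horizon unless
  `allow_extrapolation = TRUE`.
* Non-positive follow-up rows are rejected with their ids; single-class
  inputs to ROC computation, missing covariance in `wald_hr()`, and
  `n_bins > n/5` in calibration are errors, not silent degradation.
* Classification metrics with an empty denominator are `NA`, never 0.
* Rank-deficient designs abort the fit naming the collinear columns;
  ill-conditioned covariances are dropped with a warning rather than
  propagated.

## Problem sizes in the shipped checks

The test suite and acceptance checks run at sizes chosen to make Monte
Carlo error small relative to the property being checked while remaining
quick on a laptop: 200 simulated cohorts of n = 3000 for CI coverage
(pooled binomial error ≈ 0.4%, checked against a 95% ± 3% band), 20 000
infants for the survival-function and discrimination checks, 50 000 for
moment checks of the exponential special case, and 100 000 draws for the
sampler covariance check.

## Known limitations

* The model is supported only for GA 24 weeks 0 days through 30 weeks
  6 days; infants below 24 weeks need a different (and necessarily
  simpler) model, and BWSDS references typically do not cover them.
* BWSDS must be supplied: computing it from raw birth weight requires a
  population reference that is not part of this package.
* The shipped covariance is diagonal and synthetic (see above).
* Real-cohort operating characteristics (AUC ≈ 0.87–0.94 in published
  internal/external validations) cannot be verified from simulation alone;
  the package verifies the machinery, not those numbers.
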