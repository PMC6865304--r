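# digirop

Individualized prediction of the risk that a very preterm infant will need
treatment for retinopathy of prematurity (ROP), using only data available at
birth: gestational age (GA), sex, and the birth-weight SD score (BWSDS).
The package is aimed at biostatisticians and ophthalmology researchers who
want to apply, refit, validate, or stress-test birth-based ROP risk models
and the screening schedules derived from them.

## The model

The hazard of ROP treatment at postnatal age *t* (weeks) is piecewise
log-linear:

    log h(t) = β₀ + β₁·min(t,8) + β₂·clamp(t−8, 0, 4) + β₃·max(t−12, 0)
             + β₄·(min(GA,27) − 28) + β₅·max(GA−27, 0)
             + β₆·sex + β₇·min(BWSDS,−1) + β₈·max(BWSDS+1, 0)
             + t·[β₉·(min(GA,27) − 28) + β₁₀·max(GA−27, 0)]
             + β₁₁·sex·(GA − 28)
             + t·[β₁₂·min(BWSDS,−1) + β₁₃·max(BWSDS+1, 0)]

with sex coded 1 = boy, 2 = girl.  Every coefficient is a per-unit
log-hazard slope within its segment, so the published estimates are used
verbatim.  Because log h is linear in *t* on each of the three segments
(0–8, 8–12, >12 weeks), the cumulative hazard H(t) = ∫₀ᵗ h has the closed
form Σ (e^{a+b·t₂} − e^{a+b·t₁})/b, and the cumulative risk is
F(t) = 1 − exp(−H(t)), reported over a 20-week horizon.  The GA and BWSDS
centering constants, which the original report does not print, are resolved
by inverting its printed worked-example risks (see the methods vignette and
`calibrate_encoding()`).

Around that risk engine the package provides:

- `digirop_model()` / `read_coefficients()` — the published 14-coefficient
  model as a classed S3 object with `coef`, `vcov`, `predict`, `summary`,
  `plot`, `simulate` methods;
- `digirop_fit()` — the estimation pipeline: person-time expansion
  (`expand_person_time()`) and Poisson regression with a log-exposure
  offset, plus `wald_hr()` and the `interaction_screen()` forward P < .10
  rule;
- `risk_band()` — parametric-bootstrap 95% bands from 1000 multivariate
  normal coefficient draws;
- `roc_auc()`, `confusion_metrics()`, `calibration_bins()`,
  `cross_validate()` — validation machinery;
- `simulate_cohort()` — cohorts with event times drawn exactly from the
  piecewise hazard by closed-form inverse-CDF sampling;
- `suggested_first_exam()`, `risk_threshold_age()`, `avoided_visits()`,
  `schedule_table()` — screening-schedule logic.

A command-line front end ships at `system.file("cli", "digirop.R",
package = "digirop")` with subcommands `predict`, `fit`, `validate`,
`simulate`, `calibrate-encoding`, and `schedule`.

## Worked example

```r
library(digirop)
m <- digirop_model()

baby <- infant("24+3", "girl", bwsds = -1.5)
cumulative_risk(baby, t = 20, model = m)
#> [1] 0.3104083

girl_vs_boy_hr(c(25, 27), m)
#> [1] 0.83 0.50   (rounded)
```

The infant born at 24 weeks + 3 days has a 31% probability of needing ROP
treatment within 20 postnatal weeks; girls face 0.83 times the boys' hazard
at GA 25 weeks and 0.50 times at 27 weeks.  For uncertainty bands, use a
model with a full covariance — for example one refitted on a cohort (the
published report provides standard errors only, so `digirop_model()`
carries a synthetic diagonal covariance):

```r
co  <- simulate_cohort(n = 6000, seed = 1)   # synthetic national-style cohort
fit <- digirop_fit(co)
risk_band(baby, fit, grid = c(10, 15, 20), n_draws = 1000, seed = 20071101)
#>   t_weeks cum_risk lower upper
#> 1      10    0.048 0.031 0.075
#> 2      15    0.229 0.176 0.298
#> 3      20    0.254 0.197 0.327
```

Discrimination of the 20-week risk on a 3000-infant simulated cohort:

```r
co <- simulate_cohort(n = 3000, seed = 1)
scores <- cumulative_risk(co[, c("ga_weeks", "sex", "bwsds")], 20, m)
roc_auc(scores, co$event)$auc
#> [1] 0.927
```

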