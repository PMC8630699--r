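---
title: "Model and methods: ipilimumab plus anti-PD-1 rechallenge in anti-PD-(L)1-resistant melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Patients with metastatic melanoma whose disease progresses on anti-PD-(L)1
monotherapy can be rechallenged with ipilimumab alone or with ipilimumab plus
an anti-PD-1 antibody (nivolumab or pembrolizumab). The combination roughly
halves the overall-survival hazard but adds substantial drug cost, in
particular open-ended anti-PD-1 maintenance until progression. `ipicea`
implements a US-payer cohort model that weighs these against each other:
discounted lifetime costs, life-years (LYs) and quality-adjusted life-years
(QALYs) per strategy, their ratio as the incremental cost-effectiveness
ratio (ICER), and the usual sensitivity machinery around it.

```{r}
library(ipicea)
run_base_case()
```

## Disease model

Three health states: progression-free (PF, split into *response* and
*stable disease* sub-states), progressed disease (PD, on best supportive
care), and death. All patients enter progression-free.

State occupancy is read directly off the two survival curves (a partitioned
survival analysis): `PF(t) = min(PFS(t), OS(t))`, `PD(t) = OS(t) - PF(t)`,
`dead(t) = 1 - OS(t)`. The `min` clamp guards against an adjusted PFS curve
crossing above OS; occupancies can then never go negative. A
transition-probability mode (per-cycle probabilities from interval survival
ratios, the classical Markov formulation) is available behind
`model_config(occupancy_mode=)` for comparison; on these curves the two
agree closely because both are driven by the same interval ratios.

The PF split is a constant, arm-specific response share (0.31 combination,
0.13 ipilimumab): a single response percentage is all the source comparison
reports, so no time course of response is modelled.

### Survival inputs

The ipilimumab arm's OS and PFS are log-logistic fits,

$$S(t) = \frac{1}{1 + \theta t^{\kappa}}, \qquad t \text{ in months},$$

with (θ = 0.03916796, κ = 1.52458) for OS and (θ = 0.1380415, κ = 1.922389)
for PFS. The time unit and functional form are not stated alongside the
published coefficients; months with this parameterization is the calibrated
reading — it puts the PFS median at 2.80 months and reproduces the published
per-arm life-years, and both choices are exposed (`surv_spec`,
`apply_hazard_ratio`) rather than hard-wired.

The combination arm is derived by proportional hazards,
$S_1(t) = S_0(t)^{HR}$, with HR 0.50 (OS) and 0.69 (PFS). Whether the source
analysis applied the ratio on the hazard or the accelerated-time scale is
not reported; `model_config(hr_method = "aft")` switches to the
time-acceleration reading $S_1(t) = S_0(HR \cdot t)$.

### Cycle grid, horizon, discounting

* **Cycle**: 3 weeks, i.e. 21/30.4375 ≈ 0.69 months. Horizons are rounded
  up to whole cycles.
* **Horizon**: 480 months (40 years) by default, operationalizing
  "lifetime" for this cohort. The log-logistic OS tail is heavy: at a
  10-year cutoff the combination arm still has ~13% of the cohort alive and
  its published 3.80 life-years are unreachable, whereas by 40 years the
  discounted accruals of both arms have converged (the last doubling of the
  horizon moves the ICER by a few percent). `horizon_months` is a plain
  config field for scenario analysis.
* **Discounting**: 3% per annum, applied as $(1.03)^{-t/12}$ at each
  cycle's evaluation time; one-off costs (doses, progression, death) are
  discounted at their attachment times.
* **Half-cycle correction**: on by default; state membership is evaluated
  at cycle midpoints, which is a midpoint-rule integral of the survival
  curves (halving the cycle length moves discounted LYs by well under
  0.5%).

## Costing

All prices are 2021 USD (drug prices at 106% of average sales price, mg
billing, no wastage). A 70-kg patient is assumed for per-kg dosing.

* **Induction**: ipilimumab 3 mg/kg (+ nivolumab 1 mg/kg, or for the
  pembrolizumab regimen ipilimumab 1 mg/kg + pembrolizumab 2 mg/kg) every
  3 weeks for 4 doses. Each scheduled dose accrues with the probability of
  still being progression-free at that visit — with the fitted PFS curve the
  ipilimumab arm receives 3.37 of its 4 scheduled doses in expectation.
* **Maintenance**: nivolumab 240 mg every 2 weeks (1.5 expected
  administrations per 3-week cycle) or pembrolizumab 200 mg every 3 weeks,
  until progression; no duration cap by default (none is described), a cap
  is available via `arm_cost_config(maintenance_cap_months=)`. The
  combination arm mixes the two regimens 99%/1%.
* **Administration**: CMS-style infusion billing — first hour $148, each
  started additional hour $31. Ipilimumab is a 90-minute infusion, anti-PD-1
  30 minutes (label-standard durations; not stated in the costing source),
  and same-day components share one first hour.
* **PF disease management**: $189 per week while on treatment, $590 per
  week off treatment. "On treatment" means any drug is still scheduled:
  the first four cycles in the ipilimumab arm, until progression in the
  combination arm.
* **Best supportive care**: $4,492 attached once on entry into PD (default
  `bsc_unit = "once_at_progression"`). The published cost carries no unit;
  reading it as *per cycle* is arithmetically incompatible with the
  published totals — the combination arm spends roughly 2.9 discounted
  life-years progressed, which at $4,492 per 3-week cycle would exceed its
  entire published total cost — while the one-time reading ("the overall
  costs of BSC") reproduces them. `per_cycle` and `per_week` remain
  available as scenario settings.
* **Terminal care**: $18,042 once per death, attached to per-cycle incident
  deaths.

Adverse-event costs and disutilities are deliberately out of scope (the
arms' grade ≥3 rates are similar), as are testing/hospitalization costs
(equal across arms) and any inflation adjustment.

## Utilities

Response 0.88, stable disease 0.80, progressed disease 0.52. QALYs weight
the per-cycle state occupancies by these values; with all utilities at 1
the QALY accrual equals the LY accrual exactly, which the tests exploit.

## Sensitivity analyses

**One-way (tornado)**: every parameter with a published range (95% CI for
the hazard ratios, ±20% otherwise) is set to its minimum and maximum with
all else at baseline; parameters are ranked by the width of the resulting
ICER interval.

**Probabilistic**: 10,000 Monte Carlo draws. Costs are gamma, hazard ratios
lognormal, utilities and probabilities beta. Distributions are moment
matched with `sd = (max − min)/3.92` (the normal 95% divisor; log scale for
the hazard ratios, so the sampled 2.5/97.5 percentiles reproduce the
reported CI). The survival-curve coefficients stay fixed — no uncertainty
distribution is published for them. The acceptability curve (CEAC) is the
fraction of draws in which the combination arm has the higher net monetary
benefit, `NMB = WTP × QALY − cost`, on a $0–200k WTP grid in $5k steps.
Draws are seeded and bit-reproducible.

**Subgroups**: each subgroup row replaces both hazard ratios (point and CI)
and leaves everything else at base values, including the PSA distributions
of the non-HR parameters — whether the source subgroup probabilities
resampled those too is unstated, and this is the self-consistent choice.

## Kaplan-Meier reconstruction

The source curves themselves are unpublished; the package therefore ships
the machinery to regenerate such inputs and validates it on synthetic data:

1. `simulate_ipd()` draws event times by inverse CDF from a known
   distribution, with uniform accrual and administrative cutoff producing
   staggered censoring (seed mandatory, no global RNG state leaks).
2. `km_estimate()` computes the product-limit curve and a number-at-risk
   table; `digitize_curve()` samples it on an equally spaced grid (40
   points in the test protocol), emulating plot digitization.
3. `reconstruct_ipd()` inverts the estimator interval by interval between
   risk-table times, iteratively allocating censorings (uniform within each
   interval) until the implied numbers at risk match the table, and
   rounding event counts against the digitized steps. Events detected at a
   grid coordinate are placed at the midpoint of the preceding interval:
   for grid-sampled curves this is the unbiased location (right-endpoint
   placement systematically inflates early event times by half a grid
   step, which biases the fitted scale parameter), and when a digitization
   records both corners of a step the interval has zero width and the
   placement is exact.
4. `fit_parametric()` refits any of six families (exponential, Weibull,
   lognormal, log-logistic, Gompertz, generalized gamma) by right-censored
   maximum likelihood; `select_best()` picks the minimum-AIC fit with ties
   broken by parsimony and then by the fixed family order. A Gompertz fit
   with negative shape is allowed but flagged, since its improper survival
   has no finite extrapolated mean. "Visual inspection", which accompanies
   AIC selection in practice, is not mechanizable and is replaced by these
   deterministic tie rules.

What the synthetic generator does *not* emulate: reporting granularity of
real plots (pixel noise, clipped axes), informative censoring, and delayed
treatment effects. Passing round-trip tests therefore demonstrate
correctness of the inversion and fitting machinery, not robustness to every
flaw of real digitizations.

## Numerical choices and degenerate inputs

* Fitting uses a tight relative tolerance (1e-12 on the log-likelihood);
  an exponential fit agrees with the analytic estimator
  `events / person-time` to ~1e-8, which the tests assert.
* A flat digitized curve reconstructs to all-censored records; a curve with
  no events refuses to fit; fewer than 10 records refuse to fit;
  non-convergence is reported as a fit status, never silently dropped.
* Zero QALY increments leave the ICER undefined (`NA`) rather than
  infinite; dominance is flagged separately.
* Beta moment-matching that would require variance above `m(1-m)` is
  clamped with a warning; degenerate ranges (`min == max`) collapse to
  constants.
* Test problem sizes: survival grids of ~1,000 points, reconstruction
  cohorts of 200–500 subjects over 3 seeds, recovery fits at n = 1,000–2,000,
  PSA reproducibility at 1,500–2,000 draws with the full 10,000-draw run
  reserved for the acceptance checks.

## Known limitations

* The response/stable split is time-constant; real response rates evolve.
* Proportional hazards on a log-logistic baseline is internally slightly
  inconsistent (the log-logistic family is not closed under PH); it is the
  standard practice this type of analysis uses, and the AFT switch is the
  alternative reading.
* Costing conventions under-determined by the published totals (BSC unit,
  infusion durations, on/off-treatment management) are fixed at the
  documented defaults and exposed in config; totals are accordingly only
  reproducible to within the published tables' own tolerance, not to the
  dollar.
* No adverse-event costs/disutilities, no indirect comparison against
  anti-PD-1 monotherapy, no value-of-information analysis.
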