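---
title: "A lifetime cost-effectiveness model of tranexamic acid for acute gastrointestinal bleeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime cost-effectiveness model of tranexamic acid for acute gastrointestinal bleeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Tranexamic acid (TXA) is an inexpensive antifibrinolytic that reduces
bleeding deaths in trauma and postpartum haemorrhage. For acute
gastrointestinal bleeding (AGIB) the largest randomised evidence shows no
reduction in all-cause 28-day mortality (risk ratio 1.03, 95% CI 0.92 to
1.16), while earlier meta-analyses of small, bias-prone trials had suggested
a large benefit (pooled RR 0.60). `txace` implements the full economic
evaluation of this decision from a UK health-service perspective: lifetime
costs, life years (LYs) and quality-adjusted life years (QALYs) of treating
AGIB with TXA versus usual care alone, with deterministic and probabilistic
uncertainty analysis, and a scenario showing what the pre-trial meta-analytic
evidence would have implied.

## Model structure

The model is a two-state (*alive* / *dead*) Markov cohort simulation.
A cohort enters alive at mean age 58.1 years and is followed to an age cap
of 100:

* **Days 1-28 (daily cycles).** Deaths follow a 28-day trial-period curve.
  The control arm's cumulative risk is 0.0916 (548/5981). The distribution
  of deaths across days is not published; the package ships a front-loaded
  geometric shape (each day carries 0.9 times the previous day's share of
  deaths, reflecting that deaths from an acute bleed cluster early) and a
  uniform alternative, both config-selectable (`trial_curve`). Lifetime
  results are dominated by the cumulative risk, not the shape. The treatment
  effect is applied as the all-cause mortality risk ratio *on the 28-day
  cumulative risk*, preserving the daily shape, because the trial estimate
  is a 28-day risk ratio; applying it to daily conditional probabilities
  would differ only in the fourth decimal at these magnitudes. The effect
  acts only inside the 28-day window: the trial observed nothing beyond it.
* **Days 29-365 (daily cycles).** Survivors face general-population annual
  mortality at the attained (floored) age, multiplied on the hazard scale by
  a standardised mortality ratio (SMR) of 5.21 for the first year after a
  bleed, converted to daily probabilities under a constant within-year
  hazard.
* **Years 2+ (annual 365-day cycles).** The same construction with the
  year-2-onwards SMR of 1.74, applied for the remainder of the horizon.
  Any cohort fraction still alive at the age cap accrues nothing further.

SMRs act on the hazard (`1 - (1 - q)^smr`), not by multiplying
probabilities: with an SMR of 5.21, probability-scale multiplication
exceeds 1 from moderately old ages onwards, whereas the power transform is
always a probability. A model year is 365 days; leap years are ignored.

## Life table

The long-term mortality input is a standard period life table
(`age,q_annual` CSV). Because no specific national table is redistributed
here, the package vendors a **synthetic UK-style table**
(`life_table_uk_synthetic.csv`, ages 35-100) generated from a
Gompertz-Makeham law, `h(x) = A + B c^x`, with `A = 1.0e-3`,
`B = 7.4e-6`, `c = 1.116` fitted to published UK all-persons mortality
rates; it gives a period life expectancy at age 58 of about 25.2 years,
within half a year of the published national figure. The generator
(`gompertz_makeham_life_table()`) is exported so tests and users can build
tables at any mortality level; `read_life_table()` accepts a real national
table wherever one is available, and headline results should be expected to
shift by a few percent with the vintage and sex mix of the table used.

## Utilities and discounting

Survivors carry a utility of 0.735 (95% CI 0.70 to 0.77) from day 0 until
death, with age-band decrements (0 below 65, 0.02 for 65-74, 0.07 from 75)
applied at the attained age each cycle. Costs and QALYs are discounted at
3.5% per annum with a continuous-time exponent applied at each cycle's
start time, `(1 + r)^(-t/365)`; year-1 daily cycles are therefore almost
undiscounted, which matches usual practice when no explicit timing rule is
given.

**Half-cycle correction.** Whether the original spreadsheet model credited
within-cycle deaths half a cycle of accrual is unknowable from the outside.
The package defaults to the half-cycle convention (deaths accrue half a
cycle of LYs, QALYs and alive-state costs) and exposes
`half_cycle_correction = FALSE` for the end-of-cycle convention. Daily
cycles make the choice irrelevant in year 1; for the annual tail it moves
discounted life expectancy by roughly a quarter of a discounted life year,
and the test suite exercises both conventions against closed forms.

## Costs (GBP, 2021 prices)

One-off entry costs at t = 0 per arm comprise:

* TXA administration (TXA arm only): drug £12, needle £0.05, syringe £0.07,
  infusion bag £0.59, isotonic solution £2.96, nurse time £14.35 (stored as
  the printed aggregate for 21 minutes of a Band 5 nurse; the underlying
  hourly rate is not separately published). The itemised sum is £30.02; the
  source quotes the rounded £30.01.
* Inpatient stay: mean length of stay split into ICU (£1594/day) and
  non-ICU (£338/day) bed-days.
* Procedures: probability (exact event counts) x unit cost for diagnostic
  and therapeutic endoscopy, surgery, and diagnostic and therapeutic
  radiology.
* Transfusions: probability x mean units x unit cost for red cells, fresh
  frozen plasma and platelets. The stored mean units are **conditional on
  receiving the product** - this is the convention under which
  probability x mean x unit cost reproduces the published per-arm
  transfusion costs, and it is fixed once here and mirrored by the
  synthetic-trial simulator.

Post-discharge (monitoring) costs accrue to the alive state: £4350 in
year 1, £1980 in year 2, £1938 in year 3, and one-third of the year-3
amount (£646) from year 4 onwards, stored as a *fraction* so the
full-monitoring and no-monitoring-beyond-year-3 scenarios are one-key
changes. The year-1 amount is spread over days 29-365 only (the costed
inpatient stay already covers the trial window), pro-rata per day; later
years are pro-rata over their cycles. Year boundaries are measured from
model entry. No inflation or currency conversion machinery is provided.

## Uncertainty analysis

Distributions are fitted from the published summary form of each parameter:

| Parameter | Distribution | Fitted from |
|---|---|---|
| SMRs, mortality RR | log-normal | point as log-scale median, sigma from the CI width |
| 28-day risk, procedure/transfusion probabilities | beta | exact event counts (k, n - k) |
| survivor utility | beta | method of moments, SE = CI width / 3.92 |
| stays, ICU days, transfusion units | gamma | mean and SE |
| post-discharge costs | gamma | SE = 50% of the mean (base case; configurable) |

Parameters with no published uncertainty (unit costs, discount rates,
utility decrements, TXA administration) are held fixed. The log-scale
median choice for log-normals reflects that RR and SMR point estimates sit
at the geometric centre of their CIs. All draws are independent across
parameters and arms; no correlation structure is published. Each Monte
Carlo draw uses a substream seeded from `(master seed, draw index)`, so
results are independent of execution order; draws violating a structural
precondition (ICU days above the total stay, or RR x risk reaching 1) are
rejected and redrawn with a logged count. The probabilistic analysis uses
10 000 draws in the base case and reports the cost-effectiveness
acceptability curve (share of draws with positive incremental net monetary
benefit at each threshold, ties split evenly) and the cost-effectiveness
plane quadrant shares (axis draws counted on the non-negative side).

The deterministic scenario set covers: full year-4+ monitoring; no
monitoring beyond year 3; 0% and 6% discounting (applied jointly to costs
and QALYs - the joint reading of the guidance; separate rates remain
configurable); utility 0.5; reduced year-1 monitoring; the RR at both CI
bounds; free TXA; and the pre-trial meta-analysis scenario (28-day risk
71/850 with RR 0.60, 95% CI 0.42 to 0.87). For the "year-1 inpatient-type
costs excluded" scenario no separate outpatient-only year-1 estimate is
published; the package sets year 1 to the year-2 level (£1980) and treats
the scenario as qualitative.

Incremental results are always TXA minus no-TXA internally; in the
south-west quadrant the ICER reads as money saved per LY or QALY forgone
(equivalently, the comparator's ICER).

## The synthetic trial generator

`simulate_trial()` emulates patient-level records of a two-arm trial with
the structure the model assumes (the real individual-level data are only
available on request from the trialists): ~6000 patients per arm; 28-day
deaths drawn from the daily curve (control risk 0.0916, TXA risk scaled by
the RR); gamma lengths of stay and ICU days (ICU resampled until it fits
within the stay - the truncation bias is negligible at a 0.4-day ICU mean
against a 5.8-day stay); Bernoulli procedure and transfusion indicators at
the stored count proportions; and Poisson unit counts among transfusion
recipients at the stored conditional means, so unconditional means equal
probability x conditional mean. `estimate_parameters()` recovers the
trial-derived parameter slots (risk, RR with log-scale CI, means, counts)
and `patch_parameters()` feeds them back into a runnable parameter set,
closing the loop from raw-data emulation to model inputs.

What the simulator does **not** emulate: correlated resource use within a
patient (a sicker patient plausibly has longer stays *and* more
transfusions), post-28-day individual outcomes, and any covariate
structure. Passing recovery tests therefore demonstrates estimator
correctness under the model's own assumptions, not robustness to real-data
features.

## Numerical choices and problem sizes

* Survival-product identity of the daily curve and probability/rate
  round-trips hold to 1e-12; the engine matches constant-hazard
  geometric-series closed forms to 1e-9.
* A null treatment effect with identical arm resource use yields exactly
  zero incrementals (the trial curve is reused bit-for-bit when RR = 1).
* Degenerate inputs: zero cumulative risk gives an all-zero curve;
  event counts of 0 or n collapse to point masses; zero-SE (or zero-mean)
  gamma inputs are held fixed rather than sampled.
* The test suite runs the full 10 000-draw probabilistic analysis three
  times (base case, 20%-SE variant, meta-analysis scenario) and a 200
  replicate x 6000-patients-per-arm coverage study of the RR estimator;
  together these complete in a few minutes on one core.

## Known limitations

* The vendored life table is synthetic (parametric); headline lifetime
  totals shift by a few percent with the table used, although ICERs are
  insensitive because both arms shift together.
* Published base-case incremental results could only be matched to within
  a few percent: the printed per-arm totals and the printed incrementals
  of the source analysis are not exactly mutually consistent under the
  rounded published risk ratio, so this implementation reproduces ICERs
  and probabilistic results closely while its absolute incrementals sit
  within ~5-7% of print.
* No value-of-information analysis, no microsimulation, no competing-risk
  split of bleeding versus other deaths, and no adverse-event costing
  beyond what the stay/procedure/transfusion inputs already contain.
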