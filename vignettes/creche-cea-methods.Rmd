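---
title: "Methods: the crèche drowning-prevention cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the crèche drowning-prevention cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crecheCEA)
```

This vignette documents the model implemented by `creche_cea()`, the
assumptions behind each stage, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The decision problem

Community crèches supervise rural Bangladeshi children aged roughly 1–4
years during peak drowning hours (9am–1pm, six days a week). The model
compares a scaled crèche program against the status quo for a hypothetical
cohort of 100,000 children, from two perspectives: the program payer
(budget outlays only) and society (adding unpaid volunteer time and the
economic value of parents' freed-up childcare time).

## Effectiveness

The cohort is partitioned into three one-year age bands with population
shares 32.898/34.548/32.554%. Each band carries an annual cumulative
drowning incidence per 100,000 under each scenario, with 95% CIs; band
deaths are fractional expectations `N_a I_a / 1e5` (the model never rounds
children — `expected_deaths()` reports 41.27 deaths, not 41). Cohort-level
CI bounds are the sums of band-level bound deaths, and SDs are recovered
from 95% bounds by the rate-SE identity `(hi − lo)/(2 × 1.96)`
(`sd_from_ci()`).

Two published inputs need care:

* The lives-saved CI block is **carried as data**, not re-derived: no
  standard propagation of the scenario CIs reproduces the published
  bounds, and the 12–23-month bounds do not even bracket their own point
  estimate. `validate_config()` therefore surfaces this as a *note* —
  data worth flagging — rather than an error that would block the run.
* The creche-scenario incidences are equivalent to applying age-specific
  risk ratios to baseline; `incidence_from_rr()` exposes that form, and a
  round-trip test confirms `RR = I¹/I⁰` regenerates the scenario deaths.

## DALYs

Years lived with disability are set to zero: in this setting submersed
children either die within a day or survive intact, so DALYs equal years
of life lost. YLL per death uses *continuous-time* discounting,

$$\mathrm{YLL} = \frac{1 - e^{-r(L - a)}}{r},$$

with defaults r = 0.03/year, L = 72.2 years, a = 2.3 years, giving 29.24
discounted years. The continuous form was chosen over the
annual-compounding annuity (which gives 29.12) because it matches the WHO
DALY-template convention the analysis follows; no age weighting is
applied. At `r = 0` the implementation returns the exact limit `L − a`.

## Program costs

Costing is ingredients-based over nine categories. Fixed categories
(start-up, equipment, trainings, crèche maintenance) have useful lives of
10, 7.5, 5 and 3 years and are annualized with the equivalent-annual-cost
factor `r/(1 − (1+r)^(−life))` at a 3% rate (`annualize_fixed()`).

`build_annual_summary()` models the steady-state year of a 10-year
projection: each category's annual cost is its *capacity-month* run rate ×
12, where a capacity month has program-wide enrollment of at least 50% of
the observed maximum (the threshold is a parameter; "mid-to-full capacity"
has no published operational definition, so 50% was fixed once as the
natural reading). Caseload and crèche counts are capacity-month means.
Two conventions are supported for fixed categories because the published
annual column does not state which it uses: by default ledger amounts are
taken as already-annualized monthly equivalents; `fixed_as_investment =
TRUE` instead sums raw outlays and applies the annuity factor. The direct
path `annual_summary_from_totals()` consumes category annual totals as
published.

Internal arithmetic is never rounded; reported tables round for display
only. This is why subtotals can differ from published figures by up to $1
(the published table rounds category-wise) and why the average cost per
crèche evaluates to $416.39 where the publication prints $416.35 (a
difference consistent with area-weighted averaging of unpublished
per-area figures; both are accepted within 0.05%).

`normalize_ledger()` handles the pre-processing contract: inflation
adjustment to 2015 taka, conversion to 2015 USD, and multiplication by the
crèche-attributable percent-effort share, erroring with the offending year
when a deflator or exchange rate is missing. Deflator and exchange-rate
series default to 1 — the published analysis does not print them, so the
default ledger is interpreted as already normalized.

## Societal costs

All time is valued off the rural minimum monthly wage (8000 BDT ≈ $78.48
in 2015 USD):

* **Crèche workers** — two volunteers per crèche at 50% of the minimum
  wage each (part-time: 4 h/day × 6 days ≈ half a work week), $941.76 per
  crèche-year, 2304 volunteer hours.
* **Committee members (VIPC/UIPC)** — person-hours = 7 members × 3 h ×
  meetings/month × 12, valued at the hourly wage `w/192`. The full-time
  month of 192 h (48-h week × 4 weeks) is the only hourly basis that
  reproduces the published $56.70 from 138.7 h; the per-crèche meeting
  rate 0.5505/month is likewise the calibrated value consistent with the
  published cost (committees serve many crèches), and both are exposed as
  configuration.
* **Parents** — one parent per enrolled child is freed for half the work
  week, valued at 50% of the wage, scaled by utilization
  `U = 0.58 × Σ shareᵢ × weightᵢ` with frequency-tier weights
  {1, 1/2, 1/6} of a 6-day week. Those weights are the natural "≥5 days ≈
  full week, 2–4 days ≈ half, <2 days ≈ one day" reading and reproduce the
  published −$213.48 per child exactly; they are configurable. The
  published parents' hours-per-crèche figure is not consistent with any
  hourly basis that reproduces its dollar value, so dollar values are
  authoritative and hours are reported descriptively only.

## ICERs, thresholds, break-even

`cea_engine()` (internal) evaluates the whole model as a vectorized
function of its parameters; the deterministic point estimate, the PSA, the
tornado and the sweeps all call the same engine, so there is exactly one
implementation of the model arithmetic. Per-child costs enter incremental
costs *unrounded* (rounding first changes the cohort totals by up to ~$15
per 100,000). Negative ICERs are reported raw with the label "dominant
(cost-saving)" — the sign convention of the source tables — rather than
suppressed, and `classify_wtp()` brackets per-DALY ICERs against 1× and 3×
GDP per capita ($1248.48, $3745.44). `breakeven()` inverts the threshold
equation on either the per-child-cost axis (`wtp × DALYs / N`) or the
effect axis (`ΔC / (wtp × YLL)`); the published break-even narration
(e.g. $103.47, 45.41 lives) cannot be reproduced exactly from printed
inputs — the implementation returns the internally consistent values
(≈$104.48 and ≈43.9) and the tests assert those.

## Uncertainty

**PSA.** Each varied input gets a `fitted_input`: a parametric family,
truncation bounds at the observed minimum/maximum, and recentering to the
costing-model mean. Recentering is implemented as *post-truncation* mean
matching: a location shift (normal/uniform) or scale change
(lognormal/gamma/Poisson) is solved numerically so the truncated
distribution's mean equals the target. This makes the simulation agree
with the deterministic model in expectation, which is the property the
recentering exists to deliver; the alternative (recenter the untruncated
mean, then truncate) can shift input means far from the costing model when
bounds are asymmetric. Sampling is inverse-CDF within the truncation
window — exact, rejection-free, and reproducible under a seed.

Varied inputs: the nine cost categories (annual scale; normal with 12× the
monthly SD and bounds), the effect size, the minimum wage, the committee
meeting rate, and children per crèche. Meeting hours and members per
meeting stay fixed. The effect is lognormal by *arithmetic* moment
matching (`σ² = log(1 + (s/m)²)`, `μ = log m − σ²/2`), guaranteeing
positive draws. Three inputs have no published dispersion and were fixed
once: the wage SD is $16.49/month with bounds at mean ± 2 SD (standing in
for the unpublished 10-year GDP-per-capita proxy series), the committee
meeting rate gets a 25% CV truncated at [0, 2×mean], and children per
crèche uses the published monthly SD 6 with bounds [18, 30].

The published PSA intervals were fitted to the real (undeposited) ledger,
so they are qualitative references only; the tests instead assert the
properties that do not depend on the unavailable data — seeded
determinism, interval collapse under degenerate inputs, containment of the
deterministic ICER across 50 seeds at 5,000 iterations, widening with
input CV, and the SD-from-CI identity shared with the effectiveness stage.

**Tornado and sweeps.** `tornado()` perturbs each input ±1 SD holding
others fixed and ranks percent ICER changes; `proportional_sweep()`
evaluates an ICER along a multiplier grid (default ±20% steps), exactly
linear in cost parameters and hyperbolic in the effect, flagging an
undefined ICER (`NA`) where a multiplier zeroes the effect.

**Distribution fitting.** `fit_input()` fits candidate families by maximum
likelihood (via fitdistrplus) and selects by AIC — the named fitting
software of the original analysis is proprietary and its criterion
unstated, so a standard, reproducible criterion is used. The uniform is
available but not a default candidate: its range-MLE likelihood depends on
the support and systematically dominates AIC on bounded samples, which
would misclassify clearly normal data. Zero-variance series degrade to
point masses.

## The synthetic ledger

`generate_ledger()` emulates the 54 area-month expenditure records (31
calendar months for area 1, the final 23 for area 2). For each category it
draws program-month totals from a truncated normal with the published SD
and bounds, with the underlying location solved so the **truncated mean
equals the published monthly mean**. The published mean/SD/range triplets
are jointly unattainable by any truncated normal (the real series mixes
ramp-up and capacity months and is effectively bimodal), so the generator
privileges the mean — which drives every downstream total — and respects
the bounds exactly, accepting an approximate SD. Enrollment and crèche
counts follow a start-up ramp (9 and 4 months to plateau) whose plateau is
calibrated so the time-average matches the published means, clipped to the
published ranges, with 4% multiplicative noise.

What the generator does *not* emulate: seasonality and the Friday-closure
pattern (excluded from the source estimate), cross-category correlation,
per-area cost heterogeneity beyond a configurable share split, and the
true bimodal shape of the expenditure series. Passing pipeline tests on
synthetic ledgers therefore demonstrate correctness of the costing
arithmetic and the fitting/simulation machinery, not fidelity to the real
accounting records.

`generate_cohort_outcomes()` microsimulates individual children (band,
attendance tier, Bernoulli death at the band/scenario incidence) for
parameter-recovery checks of the effectiveness stage.

## Numerical choices and degenerate inputs

* SD from a 95% CI always uses `(hi − lo)/3.92`; the same function backs
  the cohort tables and the PSA effect input.
* `r = 0` is handled by exact limits in both the YLL formula and the
  annuity factor, not by small-epsilon evaluation.
* Recentering roots are found by scanning outward for a finite sign change
  before `uniroot` (far shifts can empty the truncation window).
* Zero caseload, empty ledgers, reversed CIs, zero incremental effect and
  infeasible moments (`max < mean`) all raise immediate, named errors;
  configuration problems are returned as data by `validate_config()` with
  severities `error` (blocking) and `note` (informational).

## Problem sizes

The test suite runs the deterministic pipeline at full published scale
(it is closed-form arithmetic), the PSA properties at 2,000–20,000
iterations plus a 50-seed × 5,000-iteration containment check, and the
microsimulation recovery at 10⁶ children per scenario — sizes at which the
binomial standard error (≈3.6 lives per 100,000) makes the 2-SE recovery
criterion meaningful. The full 100,000-iteration PSA runs in a few
seconds.

## Limitations

The model consumes the published effectiveness estimates as parameters; it
does not re-estimate risk ratios from surveillance data. Healthcare costs
of near-drowning survivors are excluded (negligible in this setting, not
in higher-income ones), as are long-term developmental benefits of
daycare. The societal valuation of parents' time rests on the
minimum-wage placeholder assumption; the break-even and tornado results
should be read with that in mind.
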