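---
title: "Methods: a Markov cohort model for risk-reducing mastectomy thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for risk-reducing mastectomy thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmcea)
```

## The question and the model

`rrmcea` models a healthy woman at elevated lifetime breast-cancer (BC)
risk choosing at some age between bilateral risk-reducing mastectomy (RRM)
and risk-stratified screening with medical prevention, and asks at what
lifetime risk RRM becomes cost-effective from a payer perspective.

The engine is a deterministic Markov cohort model with annual cycles from
the start age (30–60 years) to age 80. The state space is: healthy; five
diagnosis stages (DCIS and stages 1–4), each expanded into a tunnel indexed
by years since diagnosis 1–20 so survival and recurrence can depend on time
since diagnosis; distant recurrence; long-term survivor; BC death; and
other-cause death. Stage at diagnosis is drawn from a context-dependent
stage distribution — an earlier-stage-shifted distribution while the woman
is inside her screening programme's age window, the general-population
distribution otherwise — which is how the benefit of screening (stage shift)
enters the model; screening does not alter incidence.

### Elevated risk

Lifetime risk is the cumulative probability of a first BC diagnosis over
ages 20–80 under competing mortality,
$R = \sum_a p_a \prod_{b<a} (1-p_b)(1-m_b)$, with UK general-population
value 10.79%. An assumed lifetime risk $r$ is imposed by scaling
age-specific incidence with the lifetime-average hazard ratio
$\mathrm{HR} = \ln(1-r)/\ln(1-0.1079)$, held constant over age. Two
approximations deserve note. First, the HR multiplies annual
*probabilities*, not hazards; for the annual probabilities involved
(peaking near 0.02 even at a 50% lifetime risk) the induced error on the
recomputed lifetime risk is below 0.2% relative, and a property test bounds
it at 5%. Second, the log-complement transform ignores competing mortality;
since the baseline is calibrated with mortality included, the recomputed
risk stays on target (the same property test covers this).

### Within-cycle event order

A discrete-cycle model must fix an order for same-year events. The package's
convention, applied identically everywhere:

* healthy state: BC diagnosis is resolved first; only the non-diagnosed are
  then exposed to other-cause death. This makes the cohort's cumulative
  incidence agree *exactly* (to 1e-9 in tests) with the life-table
  definition of lifetime risk above, so the risk calibration and the cohort
  engine cannot drift apart.
* diagnosed tunnels: other-cause death, then stage- and
  years-since-diagnosis-specific BC death, then distant recurrence (which
  moves the woman to the distant-recurrence state, with its own annual BC
  mortality) and local recurrence (an event that accrues cost but keeps her
  advancing through her tunnel, since stage is fixed at diagnosis).
* women alive and free of distant recurrence 20 years after diagnosis
  become long-term survivors and face general-population mortality only.

No half-cycle correction is applied; with annual cycles over a 50-year
horizon this is a known, deliberate source of small divergence from
continuous-time results, and it applies equally to both arms.

Because a tunnel cell at years-since-diagnosis $j$ in the cycle at age $a$
was necessarily diagnosed at age $a-j$, the screened-vs-general parameter
context of every tunnel cell is recovered on the fly from the diagnosis
age; no extra states are needed. Probability mass is checked every cycle
and a leak beyond 1e-9 aborts the run (conservation holds to 1e-12 in
tests). The engine is verified against an independent brute-force
enumeration of every individual event path on 3-cycle models.

## Interventions

**RRM** multiplies incidence by a residual hazard ratio (default 0.09, i.e.
~91% risk reduction, deterministic range 0.02–0.38) from the surgery age
onward; cancers arising after RRM use post-RRM survival parameters and the
general-population stage distribution. A surgery cost and a surgery-year
disutility are charged once. No BC-mortality benefit beyond incidence
reduction is assumed.

**Screening** follows the UK risk-tiered programme (half-open tiers, 45%
inclusive at the top): annual mammography 40–49 then triennial to 69 for
[17%, 32%); annual mammography 40–59 then triennial for [32%, 45%); annual
MRI 30–49 plus annual mammography 50–69 for ≥45%. Women below 17% keep
routine triennial screening 50–68 — a deliberately conservative comparator
rather than "no intervention". Triennial runs step by 3 from the first
eligible age while ≤69; events before the cohort start age are dropped at
run time. Screens cost per event, carry a 1/52-year disutility, and
generate false positives at per-modality rates with recall/biopsy costs
and a 5/52-year disutility.

**Medical prevention** (five years, uptake 16.3%, starting at 30 for ≥30%
risk, else 40) multiplies incidence by $(1-u) + u\,\mathrm{HR}$ during
treatment plus a carryover window. Open choices resolved as package
defaults, each configurable:

* the premenopausal/postmenopausal switch (tamoxifen → anastrozole) happens
  at a fixed menopause age, default 51 (UK median);
* prevention reduces *all* incidence, not only ER-positive disease — the
  conservative simple choice absent subtype-specific natural history;
* the carryover of risk reduction after treatment is 5 years at the full
  treatment hazard ratio, consistent with the extended effects reported in
  the prevention trials;
* drug costs and the prevention disutility are charged to takers only
  (uptake-weighted) and only during the 5 treatment years, not carryover.

## Economics

Costs (GBP, payer perspective, taken as already price-year-adjusted) and
QALYs are discounted at 3.5%/year, independently configurable for costs and
effects because the tornado varies them separately. Utilities use the
multiplicative age adjustment: state utility × age-specific population
norm. Stage treatment costs distinguish first year, subsequent years and
terminal care (charged in the cycle of BC death); pathology-mix weighting
(`weight_treatment_costs()`) folds ER/ERBB2/node/menopausal proportions
into expected per-stage costs as a convex combination. Event disutility
durations are fixed at 1/52 year (screen) and 5/52 year (false positive);
their magnitudes are bundle inputs. A cycle utility pushed below zero by
decrements is clamped at zero with a warning. First-year treatment cost and
the first-year state utility attach to the tunnel-year-1 occupancy, i.e.
the cycle after the diagnosis event; diagnoses in the final model year
therefore accrue no treatment cost — a half-open accrual convention that
affects both arms alike.

Comparison is screening-referenced: `icer()` classifies dominance before
dividing, `find_threshold()` walks a 1%-step risk grid (17%–50%) and
returns the smallest risk whose ICER falls at or below the
willingness-to-pay value, logging any non-monotonicity rather than hiding
it. The probabilistic sensitivity analysis redraws all spec'd parameters
jointly — gamma for costs (moment-matched), beta for probabilities (method
of moments, standard error shrunk to feasibility when needed), lognormal
for utility scores truncated at 1, the utility value itself being sampled —
from one seeded RNG stream, with no parameter correlation. Default
dispersion is a standard error of 10% of the point value, mirroring the
±10% deterministic convention; deterministic ranges default to ±10% for
probabilities and utilities and ±30% for costs.

## What the synthetic bundles are — and are not

Detailed real-world parameter tables (stage-specific survival and
recurrence, unit costs, utilities) are not freely available.
`generate_fixture()` therefore builds *synthetic* bundles:

* the `"paper_like"` bundle embeds the headline reference values —
  the 10.79% baseline (incidence shape
  $0.004\,e^{-(a-65)^2/(2\cdot18^2)}$, a log-quadratic curve peaking in the
  mid-60s, calibrated by bisection to hit 10.79% exactly against a Gompertz
  mortality curve $e^{-11.6+0.1a}$ approximating UK female all-cause
  rates); uptake 0.163; discount 0.035; RRM hazard ratio 0.09 (0.02–0.38);
  WTP pair £20 000/£30 000; horizon 80; 20-year survivor cutoff; 1/52 and
  5/52 disutility durations; the published prevalence mix and 58 756 annual
  cases for the impact module. Everything else (20-year stage survival,
  recurrence rates, unit costs, state utilities) is a plausible documented
  default.
* `"random_valid"` bundles jitter the paper-like values within ranges under
  a seed, for property tests; screening costs stay tied to tier and the RRM
  cost flat so the ICER remains monotone in risk by construction.

Annual BC-death probabilities derive from 20-year stage survival through a
single constant annual hazard per stage; recurrence is active in years 1–10
since diagnosis and zero afterwards, consistent with the 20-year
recurrence-free survivor rule.

Consequently, tests on these fixtures demonstrate *structural* correctness —
conservation, oracle equivalence, monotonicities, tier steps, threshold
logic, CEAC behaviour and the exactly reproducible desk-scale numbers (the
hazard-ratio transforms and the population-impact arithmetic) — but
absolute ICERs and risk thresholds are fixture-dependent. The worked
threshold on the shipped fixture (22% at £30 000/QALY, age 30) reflects the
synthetic cost and disease inputs, not a real-world estimate.

## Numerical choices

* Baseline calibration: bisection (`uniroot`) on a single multiplier,
  tolerance 1e-14 on the multiplier, hitting the target risk to 1e-10; a
  target only reachable by clamping probabilities at 1 is an error.
* Incidence scaling clamps at probability 1 with a warning.
* Reported integer counts and currency round half away from zero (so
  6537.86 → 6538); the population-impact case fraction is carried
  unrounded into the prevented-case product, since rounding it first
  perturbs the counts by one.
* Tier boundaries are half-open from below ([0.17, 0.32), [0.32, 0.45),
  ≥0.45), matching the "45% or higher" phrasing of the top tier.
* PSA draws that fail bundle validation are redrawn and counted; a redraw
  rate above 1% errors. With the shipped distributions every draw is valid
  by construction, so redraws indicate a user-supplied spec problem.

## Interface note

The package is function-first: bundles, traces, results and draws are
tibbles or small S3 objects with `tidy()`/`glance()`/`autoplot()` methods,
and analyses compose with the pipe. Parameter bundles serialize to a
directory of one YAML config plus diff-able CSV side tables
(`write_params()`/`read_params()`, exact round trip, unknown keys
rejected); no shell entry point is provided because the intended users work
from R.

## Problem sizes used in the tests

The shipped suite exercises the full 50-cycle engine throughout, 100 random
bundles for conservation, 3-cycle models against the enumeration oracle
(whose path count grows too fast for longer horizons), PSA runs of 40–150
draws for determinism/shape checks plus a timing extrapolation to the
10 000-draw reference analysis, and coarse risk grids (steps of 0.02–0.05)
for the threshold-logic tests; the 1%-step grid remains the analysis
default.

## Known limitations

* Cohort, not microsimulation: no individual heterogeneity beyond the risk
  profile, no screening-attendance or RRM-uptake behaviour (both set to
  100% by design to measure absolute differences between arms).
* No tumour natural history: screening benefit enters only through the
  stage-shift between the two diagnosis-stage distributions.
* Constant lifetime hazard ratio; no age-varying risk elevation.
* Local recurrence is a cost event only; it neither resets the tunnel nor
  blocks eventual survivor status.
* No parameter correlation in the PSA; no value-of-information analysis.
* Thresholds computed on synthetic bundles are illustrative of the method,
  not policy estimates.
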