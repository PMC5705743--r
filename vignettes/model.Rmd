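---
title: "A patient-level Markov model of CIED battery longevity: methods and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A patient-level Markov model of CIED battery longevity: methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciedsim)
```

## The decision problem

Pulse generators of implantable cardioverter defibrillators (ICDs) and
cardiac resynchronisation therapy defibrillators (CRT-Ds) deplete their
batteries after a handful of years, and every elective generator change is
a repeat surgery that carries operative risk and opens a fresh window of
infection and complication risk. A battery that lasts longer therefore buys
more than convenience: it removes surgeries, and with them a share of the
infections, revisions and payer costs that follow. `ciedsim` quantifies
that trade-off for a Medicare-age implant cohort by simulating individual
patients through a quarterly state-transition model for 15 years or until
death, separately per device type and battery-longevity class, and
comparing paired scenarios under common random numbers.

## States, cycles and within-cycle order

The Markov states are primary implantation (A), postoperative maintenance
(B), battery replacement (C), revision (D) and dead (E, absorbing). All
patients enter at A in cycle 0; cycles are calendar quarters; the horizon
is 60 cycles. Because event risks depend on elapsed clocks (quarters since
generator placement, quarters since the last procedure, and which procedure
that was), the patient-level simulation carries those clocks explicitly.

The model is silent in no place that matters for reproducibility: within a
cycle, events resolve in a fixed order —

1. the scheduled procedure of the occupied state, with its cost, setting
   draw and clock resets;
2. operative death;
3. all-cause death;
4. battery-depletion check;
5. revision-for-other-reasons check;
6. infection check;
7. non-infectious complication check;
8. follow-up (maintenance) cost in procedure-free cycles.

A revision trigger and a battery depletion landing in the same cycle
resolve to a single revision in which the generator is also replaced (both
clocks reset), so procedures are never double-counted. Life years accrue as
0.25 per survived cycle; the death cycle contributes none, and no half-cycle
correction is applied — with quarterly cycles the bias is below the
reporting resolution. Ages advance 0.25 years per cycle and mortality is
looked up at the integer attained age.

## Parameters

All costs are January-2016 USD; all rates are probabilities per year unless
stated. The reference values, per device population:

* **Run controls.** Horizon 60 quarters; 20,000 patients per run; annual
  discount rate 0.03 (0 and 0.06 as scenarios); one master seed per run.
* **Population.** Entry age truncated-normal (mean 74.6, SD 6.1, support
  [65, 100], discretised to a quarter-year grid); Charlson band mix
  24/56/20% (ICD) and 25/58/17% (CRT-D) for bands 0–2, 3–4, 5+.
* **Settings.** Inpatient share of primary implants 56% (ICD) / 58%
  (CRT-D); of revisions 32–51% by Charlson band; battery changes are always
  outpatient.
* **Operative mortality.** Primary 1.7%, revision 3.4%, generator change
  0.2% per procedure.
* **Event rates** (first year after the keyed procedure, by Charlson band,
  low→high): infection 2–4% after primary implant, 3–7% after generator
  change, 1–3% after revision; complication 4–7% / 2–3% / 6–8%;
  revision-for-other-reasons 0–2%. Annual rates are converted to per-cycle
  probabilities by `annual_to_quarterly()` so that four independent
  quarterly draws reproduce the annual risk exactly.
* **Costs.** Primary implant (inpatient: institutional $48,390–$52,243,
  professional $1,168–$1,517; outpatient: $29,472–$32,077 / $992–$1,333),
  revision (inpatient $33,352–$49,522 / $649–$939; outpatient
  $14,582–$21,199 / $583–$747), battery change (outpatient combined
  $24,054–$25,289), follow-up cycle ($80–$164), complication ($896–$1,150,
  beta), infection ($23,817–$40,841, beta).
* **Battery longevity.** Median quarters to depletion 30/52 (ICD
  legacy/extended) and 22/40 (CRT-D), Weibull shape 5 by default.

### From printed ranges to cells

The published inputs are ranges "depending on device and Charlson band".
Each range is assigned linearly across the three Charlson bands (low band →
low end), on the argument that sicker patients have more events and higher
costs; the device dimension of a range is collapsed, so device differences
enter through battery longevity, case mix, setting mix and mortality — not
through different cell values drawn from the same printed range. For
sampling spread, the printed range is read as a central 95% interval of the
within-cell lognormal: with the median pinned to the cell value, the
least-squares fit on the log bounds has the closed form
`sdlog = log(high/low)/(2 * qnorm(0.975))`. Whether the printed interval is
a 95% interval, an IQR or a min–max is not stated; the `coverage` argument
of `fit_lognormal_from_range()` exposes the choice. The beta rows are read
as *cost* distributions (a beta rescaled to the printed range with mean at
the cell value, concentration 4); reading them as event-probability
distributions instead is configurable but not the default.

### Battery-depletion law

`calibrate_battery_hazard(median, shape)` discretises a Weibull time to
depletion whose continuous survival crosses 0.5 exactly at the target
median. Depletion mass before quarter 2 is removed (a battery change
requires the implant cycle plus at least one maintenance cycle) and the
hazard is forced to 1 at twice the median, which bounds the tunnel depth of
the oracle. Shape 5 makes most replacements of a ~5-year battery fall
between roughly 4 and 6 years; very large shapes give an effectively
deterministic lifetime (used in tests). Depletion times are drawn by
inverse CDF from per-generator uniforms, so a shared quantile draw maps to
a weakly later depletion under a longer-lived law — the mechanism behind
the paired-scenario dominance property.

### Mortality and its calibration

Background mortality is Gompertz in attained age:
quarterly probability `1 - exp(-0.25 * a * m_dev * m_cci * exp(b*(age-65)))`
with Charlson multipliers fixed at 0.75 / 1.0 / 1.6. The level `a * m_dev`
is calibrated per device — deterministically, through the expected-value
oracle, no simulation noise — so that mean discounted life years under the
reference legacy scenario equal the target cohort values (6.53 ICD, 5.50
CRT-D at 3%). The slope `b` is chosen from a small grid (0.02–0.12/yr) to
bring the implied SD of discounted life years closest to the target SDs
(4.64 / 4.29); the grid deliberately excludes 0 so the model keeps genuine
age dependence. The selected slope is 0.02/yr with base rates 0.0713 (ICD)
and 0.0987 (CRT-D) per year at age 65. Even at the flattest admissible
slope the achievable SDs (≈4.25 / 4.03) fall short of the targets: with the
stated Charlson multipliers and entry-age spread there is simply not enough
heterogeneity in the population to produce them, and we chose not to
inflate the multipliers beyond their stated values to manufacture variance.

## Design decisions that were genuinely open

**Infections feed the revision state (default on).** In claims, a
device-related infection is only identifiable when a generator removal,
system/lead revision or pocket revision is performed on the same claim
record — an identified infection *is* a revision procedure. The model
mirrors this: a detected infection sends the patient to state D in the next
cycle, where the revision cost and operative mortality apply. This choice
also makes the revision outcome track the infection outcome nearly one for
one, which is exactly the pattern the reference cohort shows. Setting
`infection_triggers_revision = FALSE` decouples them, leaving
revision-for-other-reasons as the only path into D.

**Revision-for-other-reasons is a first-year hazard.** The input is
stratified by time since the last procedure, like the infection and
complication rates; we apply it during the four cycles after the most
recent procedure. An always-on annual hazard of the same magnitude would
roughly double the lifetime revision count and sever the link between
repeat procedures and revisions.

**A (non-battery) revision does not reset the generator clock** by default:
depletion is keyed to time since the last generator change, and a lead or
pocket revision does not necessarily replace the generator. Configurable.

**Case-mix sensitivity shifts** move 15 percentage points of mass from the
lowest occupied band one band up (sicker) or from the middle band down
(healthier); "20% more outpatient" means +20 percentage points (56% → 76%
outpatient for ICD primaries), not a 20% relative increase. Note an honest
consequence of the monotone range-to-band assignment: a sicker shift raises
per-band costs and event rates at the same time as it raises mortality, and
at the 15-point magnitude the two nearly cancel — deterministically the
sicker ICD cohort costs ~0.6% *more* than the base cohort while living
0.14 fewer discounted years. Only a much larger shift (where the mortality
term dominates) produces the "sicker costs less, dies earlier" pattern;
the tests therefore assert the life-year direction and a narrow cost band,
not a cost decline.

## The expected-value oracle

The same process, made Markov by tunnel expansion: states are (phase,
generator age 1..cap, post-procedure window 1–3 × last-procedure type, or
window ≥ 4), per Charlson band and entry-age atom. The survivors' kernel is
a sparse matrix built once per band; per cycle the occupancy vector is
scaled by (1 − operative) × (1 − all-cause) and propagated, while expected
counts, costs and life years accumulate. Expected costs use distribution
*means* (for a lognormal cell `exp(meanlog + sdlog^2/2)`, not the
configured median) because expectation is linear. The engine and oracle
share the same discrete entry-age grid and mortality lookup, so agreement
is limited only by Monte Carlo error; the test suite requires all
cohort-mean outputs to fall within 3 standard errors at n = 20,000 for the
reference set and four randomised parameter sets. The oracle also yields
the death-cycle distribution, which is what the mortality calibration
root-finds on. SDs of costs are engine-only outputs.

## The synthetic-claims workbench

`generate_claims()` produces beneficiary and claim tables shaped like a
Medicare 5% Limited Data Set extract: longitudinal institutional and
professional lines with CPT/ICD-9-style codes, service dates, settings,
paid amounts stated at their historical price level, plus a ground-truth
table. It emulates: cohort-entry violations (age < 65, out-of-state, HMO,
late enrollment, a study procedure in the 2003 clean period), comorbidity
coding with repeated codes per condition, generator changes driven by the
battery law, first-year infections coded as diagnosis-plus-revision on one
record, stray infection diagnoses *without* procedures (negative controls),
complications, and quarterly monitoring claims. It does not emulate:
coding noise and miscoding, partial-year enrollment gaps, upgrades,
ICD-10-era codes, drug (Part D) costs, or correlated comorbidity structure
— so a passing round trip certifies the derivation *rules*, not robustness
to real claims messiness. The code dictionary ships as editable YAML with
the documented core codes (33249, 33225, 996.61, the monitoring CPTs) and
representative stand-ins for unpublished supplementary lists.

The derivation pipeline applies the cohort rules, computes the Charlson
score (each condition counted once), attributes infections (diagnosis and
revision procedure on the same record, within four quarters of the most
recent device procedure), inflates costs month-by-month to January 2016 by
a supplied price-index series, aggregates index-anchored patient-quarters
excluding zero-cost quarters, and emits a model configuration. Tests
require exact recovery of cohort membership, device type and Charlson
scores, and statistical recovery (binomial CI, 5% on cost medians) of the
generated rates and costs at n = 2,000.

## Problem sizes and runtime

Reference and acceptance runs use the full 20,000 patients per scenario
(about 15 s each on one CPU); the oracle evaluates in 1–2 s. Unit tests use
50–4,000 patients, chosen so the whole suite runs in a few minutes while
every assertion retains comfortable statistical margin.

## Known limitations

* **The legacy battery inputs are internally inconsistent at the source.**
  The depletion law is specified by its own median (30 quarters for legacy
  ICD), while the published cohort results for the legacy arm imply a much
  lower unconditional replacement incidence than any such law can produce
  once survival is calibrated to the published life years: claims-derived
  quarterly replacement rates "averaged over all patients" are deflated by
  cohort mortality, whereas a registry-derived device median is not. We
  keep the device-level median as the defining invariant (it is the only
  interpretation under which legacy and extended arms are comparable), and
  as a consequence the model reports more legacy-arm battery changes — and
  larger legacy-vs-extended differences — than the published cohort does.
  The extended arm, whose inputs were device-level to begin with, agrees
  closely. Users who wish to reproduce the deflated behaviour can supply
  their own per-quarter hazards.
* Discounted life-year SDs are bounded by the modelled heterogeneity (see
  calibration above).
* No device upgrades, lead-level events, quality-of-life weights, or
  societal/indirect costs; no probabilistic sensitivity analysis over
  parameter uncertainty (costs are sampled per event, but rate parameters
  are fixed per run).
* Infections accrue their cost once at detection; multi-quarter infection
  episodes are not modelled.
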