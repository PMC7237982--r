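---
title: "Methods: scoring, cohort construction and evaluation in ewsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, cohort construction and evaluation in ewsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ewsbench benchmarks five points-based early-warning systems — NEWS, MEWS,
Between the Flags (BTF), qSOFA and SIRS — on longitudinal non-ICU inpatient
data. This vignette documents the scoring model, the cohort rules, the
evaluation statistics, the synthetic-cohort generator, and the numerical and
design choices a user should know about.

## The scoring model

Each system is a declarative band table shipped as a CSV under
`inst/extdata/scores/` with columns `channel`, `criterion`, `lower`,
`lower_open`, `upper`, `points`. Nothing about the point values is hard-coded:
`builtin_definition()` loads and validates the tables, and users can supply
their own with `load_score_definition()`.

**Band boundary convention.** A value belongs to the band with the *greatest
satisfied lower bound*: `value >= lower` for a closed bound, `value > lower`
when `lower_open` is set. With closed bounds only, this reproduces half-open
`[lower, upper)` bands. Open lower bounds exist to express published strict
inequalities exactly: the SIRS tachycardia criterion is "heart rate **> 90**",
so 90 beats/min scores zero and 90.5 scores one; the qSOFA hypotension
criterion is "systolic BP **<= 100**", so 100 mm Hg scores one and 100.5
scores zero. A pure half-open convention on an integer grid cannot represent
both at once; the mixed convention can, and the test suite sweeps every stored
boundary and its neighbours to pin the semantics down.

**Criterion groups.** SIRS awards at most one point for "respiratory rate > 20
*or* PaCO2 < 32 mm Hg" and one for "WBC > 12 or < 4 *or* band forms > 10%".
The `criterion` column groups channels that share a criterion;
`sum_of_points` aggregation sums the per-criterion maximum. For NEWS, MEWS
and qSOFA each channel is its own criterion, so the grouping is invisible.
BTF is a single-parameter system: any red-zone band firing yields 1
(`any_trigger`), otherwise 0.

**Transcription sources.** NEWS follows the Royal College of Physicians 2012
chart (including the supplemental-oxygen 2-point item read from a boolean 0/1
channel); MEWS the Subbe 2001 variant (no urine output, AVPU scored 0–3);
qSOFA and SIRS the Sepsis-3 and 1992 consensus criteria; BTF the New South
Wales adult red-zone criteria (respiratory rate < 5 or > 30, SpO2 < 90%,
heart rate < 40 or > 140, systolic BP < 90, consciousness P or U). Published
BTF charts vary slightly across years and states; the data-file format makes
any correction a one-line CSV edit rather than a code change.

**Channels and units.** Values are numeric everywhere: temperature in
Celsius (readers convert Fahrenheit on request), AVPU consciousness coded
0 = Alert, 1 = Voice, 2 = Pain, 3 = Unresponsive (a reader option maps
GCS < 15 to "not alert" for qSOFA-style use), supplemental oxygen 0/1. Each
channel has configurable plausibility bounds used by `validate_cohort()`.

## Event-driven recalculation

`compute_trajectory()` starts at the first documented vital sign with every
channel imputed to its *normal default* — a value chosen to score zero points
in all five systems (an enforced invariant) — then recalculates the score at
every observation time, carrying each channel's last value forward (LOCF)
until replaced or the interval ends. Specifics:

* Observations outside the time-at-risk interval, on channels a score does
  not read, or charted during an ICU location interval are ignored.
* Same-minute observations of different channels are applied as one batch
  with a single recalculation, so no spurious intermediate score appears.
* Same-minute duplicates of one channel keep the last row of the canonical
  (encounter, time, channel, value) sort, making the result independent of
  input row order.
* LOCF has no expiry by default (the carry-forward model used in large
  EHR validation studies); a `staleness_hours` cap is available but off.

The trajectory is piecewise constant; `max_score()` is the analysis quantity
(with ties in time resolved to the earliest attainment), `first_crossing()`
yields alert lead times in hours, and `censor_final_hour()` implements the
sensitivity analysis that discards data charted in the hour before the
outcome. The engine is verified against a brute-force oracle that rescans the
full history at every event time.

## Cohort construction and labels

Inclusion requires age >= 18 and at least one vital sign charted in the ED or
a non-ICU ward. Exclusions are evaluated in a fixed order so the recorded
reason is deterministic: age, labor-and-delivery stay, direct ICU admission
(first inpatient unit is the ICU; an ICU transfer out of the ED after ward
admission counts as an outcome, not an exclusion), death in the ED, discharge
from the ED, no qualifying vital sign.

The time-at-risk interval runs from the first qualifying vital sign (ED time
counts as at-risk time) to the earliest of first ward/ED-to-ICU transfer,
death, or discharge; only this first interval is analysed even if the patient
returns to the ward. Outcomes are hospital death and the combined outcome of
ICU transfer or death. Suspected infection follows the Sepsis-3 dyad: a
culture order and an antibiotic order paired within 72 h (antibiotic after
culture) or 24 h (culture after antibiotic), onset at the first dyad element,
with simultaneous orders qualifying; only an onset inside the time-at-risk
interval labels the hospitalization. No minimum antibiotic duration is
required. The patient-deduplication sensitivity analysis keeps each patient's
chronologically first encounter.

## Evaluation

Discrimination uses the tie-corrected concordance AUC of the maximum score,
computed from midranks and verified against an all-pairs oracle. The default
95% CI is DeLong's closed form (deterministic); a seeded stratified bootstrap
is available, and the two agree closely on moderate samples. CIs are not
clustered by hospital. The full grid is 5 scores x 2 outcomes x 3 subgroups
(all, suspected infection, no suspected infection); empty or single-class
cells are reported as unavailable rather than erroring, and no
multiple-testing adjustment is applied — CIs are reported, not pairwise
tests.

Efficiency curves are step functions over the achievable integer thresholds:
sensitivity against the fraction of the cohort flagged (both non-decreasing
as the threshold drops, with no interpolation). Operating points report
sensitivity, specificity and fraction screened at the conventional cut
points (SIRS >= 2, qSOFA >= 2, NEWS >= 6, NEWS >= 8), and
`workload_comparison()` converts deltas between two operating points into
absolute counts (additional outcome events detected, fewer patients
screened).

## The synthetic-cohort generator

No real EHR extract ships with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every stage
is testable and planted effects are recoverable.

* **Outcome model.** Latent severity `z ~ N(0,1)` per encounter; the combined
  outcome follows a logistic link with hospital-stratum offsets and slope
  1.2; death among outcome cases follows a second logistic with slope 1.2,
  concentrating deaths at high severity. Intercepts are calibrated by
  numerical integration so the marginal rates hit the targets (defaults: 2%
  mortality, 12% ICU transfer or death, 33% suspected infection).
* **Signal.** Deterioration enters per channel as a standardized shift scaled
  by `signal_profile`: a persistent baseline component proportional to `z`
  plus a linear ramp over the final 24 h before the outcome. Setting an
  effect size to zero removes that channel's signal entirely — including the
  infection-physiology bump (fever, tachycardia, leukocytosis around dyad
  onset) — so the all-zero profile is a genuine null. Non-infected
  ICU-transfer-only cases have their ramp attenuated (x0.4), mimicking
  low-acuity transfers; this is what reproduces the weaker combined-outcome
  discrimination in the non-infected subgroup. A log-normal per-patient
  amplitude keeps discrimination in the realistic 0.7–0.95 AUC range rather
  than near-perfect.
* **Outcome timing.** The outcome ends the interval at a time drawn from the
  same log-normal stay-length distribution as uneventful discharges. This is
  deliberate: the maximum of repeated noisy readings grows with the number
  of readings, so if outcome intervals were systematically shorter the
  interval length alone would carry (negative) outcome information and the
  zero-signal null would be biased off 0.5.
* **Charting cadence and missingness.** Vitals every ~4 h with ±1 h jitter
  and <1% missingness; labs daily with high missingness (defaults: WBC 25%,
  band forms 87%, PaCO2 90% — band-form missingness is documented at 87% in
  large EHR cohorts; the other lab rates are the package's own plausible
  choices). Infected encounters emit a qualifying dyad with probability
  0.98, uninfected 0.02, plus occasional unpaired order noise.
* **Exercising the cohort builder.** 5% of encounters deliberately violate an
  inclusion rule (minors, direct ICU admissions, ED discharges,
  labor-and-delivery stays, ED deaths).

Everything is driven by one integer seed and is byte-reproducible. The
ground-truth table records severity, planted outcome and time, infection arm
and ramp amplitude for recovery tests.

**What the generator does not emulate:** treatment effects and alarm-driven
interventions, physiologic autocorrelation beyond LOCF-style persistence,
site-specific case mix, documentation artifacts (unit typos, device error
codes), and competing discharge risks. Passing tests therefore demonstrate
correctness of the pipeline's mechanics and the recoverability of planted
structure — not clinical performance on real wards.

## Problem sizes and numerical choices

The test suite uses cohorts of 400–2000 encounters and 10–20 seeds per
structural claim (rank recovery and ordering checks run 20 seeds at
n = 1500–2000), sizes at which binomial noise on a 2% mortality rate still
leaves the orderings stable. The acceptance script analyses one 4000-encounter
cohort. Null checks on the AUC use the exchangeability standard error of the
Mann–Whitney statistic rather than the DeLong SE, which degenerates when one
class is entirely tied (as happens for the 0/1 BTF trigger). Timestamps are
timezone-naive minutes stored as UTC; lead times are real-valued hours.

## Known limitations

* Published chart variants differ across sources for MEWS and BTF; the
  shipped tables follow the definitions named above and are trivially
  editable.
* The antibiotic dyad element is an order timestamp; administration-time
  semantics are left to the data preparer.
* Discrimination is evaluated on the maximum score over the whole interval,
  not over a fixed prediction horizon (e.g. death within 24 h).
* DeLong CIs ignore within-hospital clustering.
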