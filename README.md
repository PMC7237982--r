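# ewsbench

Benchmarking points-based early-warning scores on non-ICU inpatient cohorts.

Hospitals screen ward and emergency-department patients for impending
deterioration with simple points-based risk scores computed from routine
vitals and labs. Several competing systems are in wide use — the National
Early Warning Score (NEWS), the Modified Early Warning Score (MEWS), the
Between the Flags red-zone criteria (BTF), and the infection-targeted qSOFA
and SIRS criteria — and choosing among them means trading off
discrimination (can the score rank who will die or need the ICU?) against
alerting workload (how many patients cross the threshold and must be
screened?). ewsbench is for biostatisticians and clinical-informatics teams
who want that comparison as a tested, reproducible pipeline they can run on
their own long-format EHR extracts or on calibrated synthetic cohorts.

## What it computes

* **Scores.** All five systems as declarative band tables (CSV, one per
  score, editable): a value lands in the band with the greatest satisfied
  lower bound, `points(v) = sum over criteria of max(band points)`, with BTF
  aggregated as a 0/1 any-trigger. Scores are recalculated event-by-event
  over a patient's *time-at-risk interval* — first documented ED/ward vital
  sign until the first of ICU transfer, death or discharge — starting from
  an imputed-normal state and carrying each channel's last value forward
  (LOCF). The analysis quantity is the maximum score in the interval.
* **Labels.** Hospital death; the combined outcome of ICU transfer or death;
  and Sepsis-3 suspected infection from culture/antibiotic order dyads
  (antibiotic within 72 h after a culture, or culture within 24 h after an
  antibiotic; onset at the first dyad element, counted only inside the
  time-at-risk interval).
* **Evaluation.** Concordance AUC of the maximum score,
  AUC = P(score_case > score_control) + 0.5 P(tie), with DeLong or
  bootstrap 95% CIs, over 5 scores x 2 outcomes x 3 infection subgroups;
  screening efficiency curves (fraction of cohort flagged vs sensitivity at
  every integer threshold); operating points at SIRS>=2, qSOFA>=2, NEWS>=6,
  NEWS>=8; workload deltas in absolute patient counts; alert lead times; and
  three sensitivity analyses (complete-case, final-hour censoring, one
  hospitalization per patient).
* **Synthetic cohorts.** A seeded generator with a latent-severity logistic
  outcome model, calibrated marginal rates (2% mortality, 12% ICU transfer
  or death, 33% suspected infection by default), a 24 h pre-outcome
  deterioration ramp in the channels the scores read, realistic charting
  cadence and lab missingness, planted rule violations, and a ground-truth
  table for recovery tests.

## Worked example

```r
library(ewsbench)

cfg <- generator_config(n_encounters = 1000, seed = 42)
gen <- generate_cohort(cfg)
gen$cohort
#> <ews_cohort> 1000 encounters, 145668 observations, 1778 location intervals, 642 orders

included  <- include_encounters(gen$cohort)
intervals <- build_time_at_risk(gen$cohort, included)
labels    <- flag_cohort(gen$cohort, intervals)
cohort_summary(included, labels)$prevalence
#>   n_included mortality icu_or_death suspected_infection
#> 1        950    0.0316        0.139               0.311

res <- evaluate_all(gen$cohort, intervals, labels, sensitivity = FALSE)
subset(res$discrimination, subgroup == "all" & outcome == "died",
       c(score, auc, ci_low, ci_high))
#>   score   auc ci_low ci_high
#> 1  NEWS 0.913  0.867   0.958
#> 2  MEWS 0.854  0.775   0.934
#> 3   BTF 0.679  0.588   0.770
#> 4 qSOFA 0.818  0.741   0.896
#> 5  SIRS 0.797  0.714   0.879
```

Of 1000 generated encounters, 950 pass the inclusion rules (the generator
plants minors, direct-ICU admissions, ED discharges and similar violations
on purpose); 3.2% died and 31% met the dyad criteria in this draw. NEWS
shows the highest mortality discrimination, the single-parameter BTF the
lowest — the qualitative pattern this kind of comparison exhibits on real
multi-hospital cohorts. Operating points make the workload trade-off
concrete:

```r
subset(res$operating_points, outcome == "died" &
         ((score == "NEWS" & threshold == 6) | (score == "SIRS" & threshold == 2)))
#>   score threshold sensitivity specificity fraction_screened outcome
#> 1  NEWS         6       0.633       0.938             0.080    died
#> 2  SIRS         2       0.733       0.766             0.249    died
```

Here NEWS>=6 flags 8.0% of the cohort against 24.9% for SIRS>=2 — 161 fewer
patients to screen (`res$workload`) at a 10-point sensitivity cost in this
small draw. Single scores also trace back to the band tables:

```r
total_score(builtin_definition("qSOFA"),
            c(respiratory_rate = 24, systolic_bp = 95, consciousness = 1))
#> [1] 3
```

`ews_run(events_or_cohort, "results/")` executes the whole pipeline
(validation, cohort rules, dyads, scoring, evaluation, lead times) and
writes tidy CSV/JSON plus a run log with a config hash;
`ews_simulate(cfg, "events.csv")` writes a synthetic cohort in the
documented long-format events schema (CSV or Parquet). A thin command-line
wrapper lives at `inst/cli/ewsbench.R`.

## Score definition files

Each score is a CSV under `inst/extdata/scores/` with columns `channel,
criterion, lower, lower_open, upper, points`. Bands for a channel chain
(`upper` equals the next `lower`); a closed lower bound means
`[lower, upper)`, an open one expresses published strict inequalities such
as SIRS heart rate > 90. The `criterion` column groups channels that share a
criterion (SIRS: respiratory rate OR PaCO2; WBC OR band forms). Custom
scores load through `load_score_definition()`.

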