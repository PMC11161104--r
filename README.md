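# emadhere

Medication-adherence analysis for oral anticancer therapies monitored with
electronic monitors (EM) — smart pill bottles whose cap records the
timestamp of every opening, used as a proxy for drug intake.

The package is aimed at adherence researchers and trial statisticians who
need to go from raw EM opening logs and prescription records to the three
quantities of the adherence taxonomy:

* **Implementation** — the daily probability of correct intake among
  patients still under observation. Day *t* scores 1 when, for every
  monitor of the patient, observed openings (plus confirmed pocket-dose
  credits) reach the expected openings; days inside oncologist-prescribed
  transient interruptions expect 0 openings.
* **Persistence** — time to premature treatment cessation (adverse events
  or patient decision = event; other cessation or study exit = censored),
  estimated by Kaplan–Meier.
* **Adherence** — the composite: correct intake among *all* initially
  included patients, A(t) = I(t) × S(t).

Longitudinal implementation is modelled with generalized estimating
equations on the daily 0/1 intake:

```
logit P(Y_it = 1) = β₀ + β₁ t + β₂ t² + β₃ t³ + γ · TI_i(t)
```

with an AR-1 working correlation, robust (sandwich) covariance clustered by
patient, and TI_i(t) the days patient *i* has spent in the intervention arm
up to day *t* (0 for controls; time in control is implicit, TC = t − TI).
Estimates are reported at 6 months for a representative patient randomized
to the intervention at day 21 versus a representative control patient, with
the delta-method 95% CI of their difference.

The day-level database is built the way adherence trials clean EM data:
openings are assigned to days running 03:00–02:59 local time, truncated to
each monitor's period of actual use, corrected for patient-reported pocket
doses when the pharmacy pill count confirms them, reduced by reported
curiosity checks, and masked over nonmonitored periods (outcome missing).
Prescribed regimens — including dose changes, cyclic schedules such as
21 days on / 7 days off, and transient interruptions — are expanded into
per-day expected openings under both the prescribed and the manufacturer's
on-label convention, so the cost of ignoring routine-care regimen
adaptations can be quantified.

A calibrated synthetic-cohort generator (`simulate_cohort()`) emulates the
full data-generating process (two arms, dosing-day Bernoulli intake with
patient random intercepts, discontinuation/censoring hazards, transient
interruptions, pocket doses, curiosity checks, nonmonitored periods, pill
counts, BMQ and EORTC QLQ-C30 questionnaire responses), so every stage is
testable without access to patient data. Questionnaire scoring (reverse-sum
BMQ subscales; 0–100 linear transformations for the QLQ-C30) and Welch
group comparisons are included.

## Worked example

```r
library(emadhere)
library(dplyr)

ch  <- simulate_cohort(cohort_config(), seed = 1)      # 120 patients, 360 days
tab <- build_adherence_table(ch$events, ch$prescriptions, ch$reports,
                             ch$pill_counts, ch$patients)
out <- daily_outcome(tab, "prescribed")

fit <- fit_implementation_gee(out)                     # logit GEE, AR-1, cubic time
predict_representative(fit, day = 180, randomization_day = 21)
#> # A tibble: 1 x 8
#>     day p_intervention p_control  delta conf_low conf_high     se ci_method
#>   <dbl>          <dbl>     <dbl>  <dbl>    <dbl>     <dbl>  <dbl> <chr>
#> 1   180          0.983     0.950 0.0325  0.00929    0.0557 0.0118 delta

rec <- persistence_records(ch$patients, from = "randomization")
km  <- km_persistence(filter(rec, arm == "intervention")[c("patient_id", "time", "status")])
km$estimate[km$day == 180]
#> [1] 0.9074978
```

The fitted implementation at 6 months is 98.3% for the representative
intervention patient versus 95.0% for the control patient — a difference of
3.3 percentage points (95% CI 0.9–5.6) — and Kaplan–Meier persistence at
6 months post-randomization in the intervention arm is 90.7%, so composite
adherence is about 0.983 × 0.907 ≈ 89%. `run_pipeline(cohort_config(),
"out/")` runs the same analysis end to end and writes the adherence table,
curves, prediction tables (including the per-subgroup analysis and the
prescribed-vs-on-label comparison), questionnaire scores and figures, plus
a reproducibility manifest.

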