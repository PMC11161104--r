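---
title: "Methods: dosing histories, GEE implementation models and the adherence taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosing histories, GEE implementation models and the adherence taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emadhere)
```

# The measurement problem

Oral targeted anticancer agents (protein kinase inhibitors, PKIs) are
self-managed at home, and electronic monitors (EM) — pill bottles whose cap
records the timestamp of every opening — are the reference instrument for
reconstructing the dosing history. `emadhere` implements the analysis of a
two-arm randomized adherence trial on such data: a day-level dosing-history
database is built from the raw opening log and the prescription record, and
the three phases of adherence are then quantified separately:

* **Implementation** — on each day, the proportion of patients whose intake
  was correct among patients still under observation;
* **Persistence** — the time from study start to premature treatment
  cessation;
* **Adherence** (composite) — the proportion with correct intake among *all*
  patients initially included, which equals the product of the
  implementation and persistence probabilities.

The daily intake outcome is binary: day *t* scores 1 when, for every
monitor the patient carries, the observed openings (plus any confirmed
pocket-dose credit) reach at least the expected openings, and 0 otherwise.

# Database construction

**Day boundary.** A monitoring day runs from 03:00 to 02:59 local time:
an opening at 01:30 on calendar date D belongs to day D − 1. The rule is
applied on the local wall clock, which keeps the assignment well defined
across daylight-saving transitions (the 02:00–03:00 changeover hour never
contains a boundary). `em_day()` implements this rule and every counting
function uses it.

**Truncation.** Events are kept only inside each monitor's window of actual
use; out-of-window events are flagged in a QC report, never silently
dropped.

**Expected openings.** `build_schedule()` expands dated prescription
segments into a per-day expectation under two conventions. Under the
*prescribed* convention, oncologist-ordered transient interruptions (for
toxicity, administrative reasons or validated patient requests) set the
expectation to 0 — taking nothing is then optimal implementation. Under the
*on-label* convention the expectation is the manufacturer's recommended
regimen, so the same days typically score 0. The gap between the two
conventions measures how much implementation would be underestimated if
routine-care regimen adaptations were ignored. Off-weeks of cyclic regimens
(e.g. 21 days on / 7 days off) have expectation 0 under *both* conventions
and are therefore never counted as interruptions. Interruption reason codes
are carried through for reporting but do not affect computation, since all
three reasons set the expectation to 0 identically.

**Pocket doses.** A pocket dose is a dose taken out of the monitor in
advance and swallowed later, on a day with no recorded opening. Credits are
inserted only when the pharmacy pill count for the refill period shows at
least that many pills left the bottle beyond the recorded openings, one
credit per deficit day inside the reported window, earliest deficit first,
never exceeding the reported count. The chronological tie-break is a design
choice (the source data do not dictate one); it is deterministic and
auditable.

**Curiosity checks** (openings without intake) are subtracted from the
day's count, floor 0, symmetrically to pocket-dose credits. Whether such
openings should be subtracted or ignored is genuinely open; the policy is a
parameter (`curiosity_policy = "subtract"` or `"ignore"`), with subtraction
as the default because the reports are collected for exactly this purpose.

**Nonmonitored periods** (e.g. hospitalizations) make the outcome missing:
those patient-days leave every denominator, and masking never alters counts
on other days.

# The implementation model

Daily intake is modelled with generalized estimating equations: logit link,
polynomial time effect, first-order autoregressive working correlation, and
robust (sandwich) covariance with the patient as the cluster. GEE was chosen
over a random-effects model because the estimand is the population-averaged
(marginal) probability of correct intake — the quantity the empirical
curves estimate.

**Exposure covariate.** The intervention enters as a time-dependent
exposure: TI(*t*), the number of days spent in the intervention arm up to
day *t*, accruing from each patient's own randomization day and identically
0 for control and never-randomized patients (the latter contribute to the
baseline trajectory "as control" until they drop out, and their
randomization date equals the first visit when randomization happened at
inclusion). Time spent in control satisfies TC(*t*) = *t* − TI(*t*) for
every patient, so TC is perfectly collinear with the model's linear time
term and is left implicit: the TI coefficient is the per-day log-odds
effect of a day under the intervention relative to a day under control, and
representative-patient predictions are unchanged by this
reparameterization.

**Polynomial degree.** Default 3 (captures the early rise after the first
feedback interview and the late drift); the degree is a parameter and is
recorded in the model card. The time axis is rescaled internally by its
maximum before the powers are formed, which makes predictions invariant to
affine rescaling of the day axis and keeps the information matrix well
conditioned.

**Link.** Logit: the outcome is binary and predictions are reported on the
probability scale; no other link is considered.

**The fitter.** The package ships its own GEE routine (`gee_binary()`).
Fisher scoring solves the estimating equations; the AR-1 working
correlation is estimated from lag-one products of Pearson residuals; and
the inverse working correlation enters through the tridiagonal closed form
of an AR-1 inverse, so each iteration is O(N) in the number of patient-days
and no per-cluster matrix is ever formed. Missing days are dropped and
adjacent remaining observations of a cluster are treated as lag-one
neighbours (the usual order-based convention). The tests cross-check the
routine two independent ways: with an independence working correlation the
coefficients must equal `glm()` maximum likelihood and the robust
covariance must equal the clustered HC0 sandwich from the sandwich package;
and for AR-1 a dense-matrix reference implementation of the same equations
must agree to 6 decimals. An all-correct (or all-incorrect) outcome admits
no finite estimate; the fitter raises a dedicated degenerate-case error and
`run_pipeline()` then reports the constant implementation without fitting.

**Representative patients.** Estimates are reported at day 180 for a
patient who switched to the intervention after a 21-day baseline
(TI = 159) and a patient who stayed in control (TI = 0), with the
difference on the probability scale. The 95% CI of the difference uses the
delta method on the two linear predictors with the robust covariance; a
seeded bootstrap over patients (default 500 resamples) is available as an
alternative because the analytic choice is not dictated by the source
material.

**Subgroups.** Covariables enter one at a time, continuous ones
dichotomized at the cohort median (or a prespecified cut: 60 years, 60 days
since PKI initiation, 2 years since metastatic diagnosis). Each stratum is
refitted separately — paired per-stratum estimates match how such tables
are reported — rather than through interaction terms; strata with fewer
than two patients are marked inestimable.

# Persistence and adherence

Discontinuation for adverse events or patient personal/unilateral reasons
is the persistence event; cessation for other clinical reasons (progression,
asymptomatic toxicity) and study exit without discontinuation are censoring
times. The product-limit estimate and its Greenwood-based bounds come from
`survival::survfit()`.

The adherence analysis runs on the randomization clock over 340 days
(roughly 12 months minus the 21-day baseline): the baseline period is
excluded, days after a discontinuation event count as incorrect intake
through day 340, and days after a censoring time are missing. Two adherence
estimates are computed because the empirical definition ("correct intake
among all initially included") and the product formulation I(t) × S(t)
disagree when censoring exists: the product form is primary, the empirical
variant (discontinued patients kept in the denominator as 0, censored
patients excluded after censoring) is returned alongside.

# The synthetic cohort and its calibration

No patient-level data are distributable, so the package ships a generator
(`simulate_cohort()`) whose defaults are the study conditions: 120 patients,
1:1 allocation, 21-day baseline (with 35% of patients randomized at the
inclusion visit itself), 360-day horizon.

**Intake.** Daily intake is Bernoulli from a logistic trajectory with a
patient-level normal random intercept (SD 1.5 on the log-odds scale), which
induces the within-patient autocorrelation the AR-1 working correlation
targets. The config stores three *marginal implementation* anchors —
day 0 = 95.5%, day 180 control = 95.03%, day 180 intervention = 98.10% —
and the generator converts them exactly rather than by stochastic
calibration: the anchors define a linear marginal log-odds trajectory in
*t* and TI(*t*); the share of patient-days whose prescribed expectation is
0 (interruptions, cyclic off-weeks — days that score 1 regardless of
intake) is removed analytically via a renewal-process approximation to get
the marginal probability of taking the drug on a dosing day; and the
conditional intercept is obtained by solving
E[logit⁻¹(η + σZ)] = p with Gauss–Hermite quadrature. A law-of-large-numbers
test at n = 5000 checks that the latent patient-level probabilities average
to the configured marginal.

**Interruptions.** Episodes arrive per monitor with a constant daily hazard
of 0.006 after day 42 and log-normal durations (median 7 days,
IQR ≈ 5–12). These values were chosen so the simulated descriptives match
the trial's: ~56% of patients with at least one interruption longer than
2 days, a median of 1 episode per monitor, median duration 7 days. This
descriptive calibration implies that roughly 4–5% of at-risk patient-days
around month 6 fall inside an interruption, which bounds the achievable
dual-convention gap at about 6 percentage points; the trial's printed
whole-sample on-label estimate implies a somewhat larger interruption
burden than its own descriptive statistics do, and the generator follows
the descriptives.

**Discontinuation.** Events and censoring are competing daily geometric
hazards per arm; event hazards are set from the 6-month persistence targets
(91.5% / 89.3%) and censoring hazards reproduce the observed attrition
(about a quarter of intervention and half of control patients completing
12 months). Dropout is independent of the intake process (no informative
missingness) — a deliberate simplification.

**Deviations.** Pocket-dose episodes (rate 0.3 per patient, 1–2 days),
curiosity checks (0.2), and nonmonitored periods (0.25, 3–10 days) are
injected and reported exactly; pill counts are generated consistent with
consumption so that genuine pocket reports are confirmed. Opening
timestamps are uniform in a 07:00–22:00 intake window with 3% of openings
placed between 00:00 and 03:00 to exercise the day-boundary rule; the
within-day placement is a placeholder, as no empirical opening-time
distribution was available to emulate.

**What the generator does not emulate.** Informative dropout, seasonal or
weekday intake patterns, learning effects in monitor handling, partial
intakes on multi-opening regimens, unreported deviations, and any
pharmacokinetic layer. Tests passing on this cohort therefore validate the
pipeline's arithmetic and the estimators' statistical behaviour under the
assumed structure, not robustness to those real-data features.

# Numerical choices and problem sizes

* Fisher scoring runs to a 1e-8 coefficient tolerance (cap 100 iterations);
  the AR-1 parameter is clamped to (−0.99, 0.99); non-convergence and
  singular information are errors with diagnostics, never silent.
* Wilson score intervals for empirical proportions (well-behaved near 1,
  where implementation lives).
* Segment dates are inclusive on both ends; schedule gaps and overlaps are
  hard errors listing the offending monitor-days.
* The test suite's heavy cases are sized to finish comfortably on one CPU:
  the round-trip recovery uses 20 cohorts of 120 patients × 360 days; the
  coverage property uses 200 replicates of 40 patients × 60 days; the
  brute-force cleaning oracle runs on cohorts of ≤ 5 patients × ≤ 30 days.
  These sizes are the package's chosen trade-off between Monte-Carlo error
  and runtime.

# Known limitations

* The GEE fitter supports the working correlations the analysis needs
  (independence, exchangeable, AR-1) with a scalar correlation parameter;
  unstructured or user-supplied correlation matrices are out of scope.
* The AR-1 lag convention is order-based: gaps from missing days are
  treated as lag one. This matches common practice but understates the
  decay across long gaps.
* Pill-count reconciliation assumes a constant tablets-per-opening within a
  refill period.
* The bootstrap CI refits the GEE per resample and is correspondingly slow;
  it is an option, not the default.
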