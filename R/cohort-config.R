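# Configuration and calibration of the synthetic two-arm cohort.
#
# The generator is calibrated on the *outcome* scale: the config stores the
# marginal probability of correct intake (prescribed convention) at three
# anchor points — day 0 (both arms), day 180 in control, and day 180 for a
# patient with 159 days of intervention exposure — and the generator converts
# them deterministically into the conditional (random-intercept) log-odds it
# simulates from. The conversion has two steps:
#   1. remove the share of patient-days on which the prescribed expectation
#      is 0 (transient interruptions, cyclic off-weeks), where the outcome is
#      correct by definition, to get the marginal probability of *taking* the
#      drug on a dosing day; and
#   2. solve E_b[ logit^-1(eta + b) ] = p for eta with b ~ N(0, sigma^2)
#      (Gauss-Hermite quadrature + root finding), so that the population
#      average of the patient-level intake probabilities matches the target.

# Probabilists' Gauss-Hermite rule via the Golub-Welsch eigen decomposition
# of the Jacobi matrix; nodes/weights for E[f(Z)], Z ~ N(0,1).
gauss_hermite <- function(n = 25) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = ev$values, weights = ev$vectors[1, ]^2)
}

# Marginal probability of a logit-normal: E[plogis(eta + sigma Z)].
logitnorm_mean <- function(eta, sigma, gh = gauss_hermite()) {
  vapply(eta, function(e) sum(gh$weights * plogis(e + sigma * gh$nodes)),
         numeric(1))
}

# Solve for the conditional intercept eta giving marginal probability p.
# Returns a fast interpolator (marginal logit -> conditional logit) so the
# generator can convert whole day grids at once.
conditional_logit_fun <- function(sigma) {
  if (sigma == 0) return(function(lm) lm)
  gh <- gauss_hermite()
  grid <- seq(-12, 12, length.out = 241)
  eta <- vapply(grid, function(lm) {
    p <- plogis(lm)
    uniroot(function(e) logitnorm_mean(e, sigma, gh) - p,
            lower = lm - 1, upper = lm + 8 * sigma + 1, extendInt = "yes",
            tol = 1e-10)$root
  }, numeric(1))
  stats::approxfun(grid, eta, rule = 2)
}

#' Configuration of the synthetic two-arm cohort
#'
#' Returns the full parameter set of the synthetic-cohort generator. The
#' defaults are the calibrated study conditions: a ~120-patient, 1:1 cohort
#' monitored for 360 days with a 21-day baseline, marginal day-180
#' implementation of 98.10% (intervention) and 95.03% (control), persistence
#' event hazards giving 91.5% / 89.3% at 6 months, and prescribed transient
#' interruptions with ~56% patient prevalence and a median duration of 7
#' days (IQR ~ 4-12, log-normal). Any element can be overridden through the
#' arguments; [noiseless_config()] gives the degenerate perfect-adherence
#' scenario used for pipeline smoke tests.
#'
#' @param n_patients number of patients.
#' @param allocation proportion allocated to the intervention arm.
#' @param baseline_days EM-monitored baseline before randomization (days).
#' @param horizon_days monitoring horizon (days); must be >= baseline.
#' @param randomize_at_inclusion_prob share of patients whose randomization
#'   date is the inclusion visit itself (day 0) rather than the end of
#'   baseline.
#' @param intake list: `impl_day0`, `impl_day180_control`,
#'   `impl_day180_intervention` (marginal implementation anchors on the
#'   prescribed convention) and `sigma_patient` (SD of the patient random
#'   intercept on the log-odds scale).
#' @param interruption list: `onset_day` (no prescribed interruptions before
#'   this day), `hazard` (per-day probability an interruption starts, per
#'   monitor), `duration_meanlog`, `duration_sdlog` (log-normal duration,
#'   rounded to whole days, minimum 1).
#' @param discontinuation list of per-day hazards by arm:
#'   `event_hazard` (premature cessation counted as a persistence event) and
#'   `censor_hazard` (other cessation / study exit, censored), each a named
#'   vector `c(intervention=, control=)`.
#' @param deviations list: `pocket_rate` (expected pocket-dose episodes per
#'   patient), `pocket_max_days`, `curiosity_rate`, `nonmonitored_rate`,
#'   `nonmonitored_min`, `nonmonitored_max` (days).
#' @param regimen list: `cyclic_prob` (share of patients on a 21/7 cyclic
#'   regimen), `cycle_on`, `cycle_off`, `multi_monitor_prob` (share with a
#'   second monitor, e.g. association regimens), `two_daily_prob` (share of
#'   monitors with 2 expected openings/day), `dose_change_prob` (share of
#'   regular monitors whose prescription record is split by a dose change).
#' @param timing list: `window_start`, `window_end` (hours of the usual
#'   intake window), `early_fraction` (share of openings falling between
#'   00:00 and 03:00, exercising the day-boundary rule), `tz`.
#' @param questionnaires per-scale mean/SD used to draw item responses;
#'   see the default for the expected structure.
#' @param covariates baseline covariate distribution (proportions and
#'   location/scale parameters).
#' @param effect_modifiers optional named list of per-level multipliers of
#'   the intervention-exposure effect, e.g.
#'   `list(gender = c(male = 1.5, female = 0.5))`.
#' @param seed default random seed used by [simulate_cohort()].
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 120,
                          allocation = 0.5,
                          baseline_days = 21,
                          horizon_days = 360,
                          randomize_at_inclusion_prob = 0.35,
                          intake = list(),
                          interruption = list(),
                          discontinuation = list(),
                          deviations = list(),
                          regimen = list(),
                          timing = list(),
                          questionnaires = list(),
                          covariates = list(),
                          effect_modifiers = NULL,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    allocation = allocation,
    baseline_days = baseline_days,
    horizon_days = horizon_days,
    randomize_at_inclusion_prob = randomize_at_inclusion_prob,
    intake = modifyList(list(
      impl_day0 = 0.955,
      impl_day180_control = 0.9503,
      impl_day180_intervention = 0.9810,
      sigma_patient = 1.5
    ), intake),
    interruption = modifyList(list(
      onset_day = 42,
      hazard = 0.006,
      duration_meanlog = log(7),
      duration_sdlog = 0.814
    ), interruption),
    discontinuation = modifyList(list(
      event_hazard = c(intervention = -log(0.915) / 180,
                       control = -log(0.893) / 180),
      censor_hazard = c(intervention = 0.0030, control = 0.0015)
    ), discontinuation),
    deviations = modifyList(list(
      pocket_rate = 0.3,
      pocket_max_days = 2,
      curiosity_rate = 0.2,
      nonmonitored_rate = 0.25,
      nonmonitored_min = 3,
      nonmonitored_max = 10
    ), deviations),
    regimen = modifyList(list(
      cyclic_prob = 0.3,
      cycle_on = 21,
      cycle_off = 7,
      multi_monitor_prob = 0.1,
      two_daily_prob = 0.2,
      dose_change_prob = 0.2
    ), regimen),
    timing = modifyList(list(
      window_start = 7,
      window_end = 22,
      early_fraction = 0.03,
      tz = "Europe/Zurich"
    ), timing),
    questionnaires = modifyList(list(
      bmq = list(
        specific_necessity = c(mean = 17, sd = 4),
        specific_concerns = c(mean = 15, sd = 4),
        general_overprescribing = c(mean = 12, sd = 3),
        general_prejudices = c(mean = 11, sd = 3)
      ),
      qlq = list(functional = c(mean = 80, sd = 15),
                 symptom = c(mean = 20, sd = 15),
                 global = c(mean = 60, sd = 20)),
      nonresponse_prob = 0.15
    ), questionnaires),
    covariates = modifyList(list(
      p_male = 0.41,
      age_mean = 61, age_sd = 11,
      p_metastasis = 0.81,
      metastasis_years_meanlog = log(1.7), metastasis_years_sdlog = 0.9,
      pki_days_meanlog = log(60), pki_days_sdlog = 1.1,
      p_adherence_tool = 0.25
    ), covariates),
    effect_modifiers = effect_modifiers,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Degenerate noiseless scenario
#'
#' All intake probabilities 1, no interruptions, no discontinuation or
#' censoring hazards, no deviations: every patient-day has openings equal to
#' the prescribed expectation, downstream implementation is exactly 100% on
#' every day and Kaplan-Meier persistence is exactly 1.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
noiseless_config <- function(...) {
  cohort_config(
    intake = list(impl_day0 = 1, impl_day180_control = 1,
                  impl_day180_intervention = 1, sigma_patient = 0),
    interruption = list(hazard = 0),
    discontinuation = list(event_hazard = c(intervention = 0, control = 0),
                           censor_hazard = c(intervention = 0, control = 0)),
    deviations = list(pocket_rate = 0, curiosity_rate = 0,
                      nonmonitored_rate = 0),
    ...
  )
}

validate_cohort_config <- function(cfg) {
  check_pos(cfg$n_patients, "n_patients", strict = TRUE)
  check_prob(cfg$allocation, "allocation")
  check_pos(cfg$baseline_days, "baseline_days")
  check_pos(cfg$horizon_days, "horizon_days", strict = TRUE)
  if (cfg$horizon_days < cfg$baseline_days) {
    stop_config("`horizon_days` must be at least `baseline_days`.")
  }
  check_prob(cfg$randomize_at_inclusion_prob, "randomize_at_inclusion_prob")
  with(cfg$intake, {
    check_prob(impl_day0, "intake$impl_day0")
    check_prob(impl_day180_control, "intake$impl_day180_control")
    check_prob(impl_day180_intervention, "intake$impl_day180_intervention")
    check_pos(sigma_patient, "intake$sigma_patient")
  })
  check_prob(cfg$interruption$hazard, "interruption$hazard")
  check_pos(cfg$interruption$onset_day, "interruption$onset_day")
  check_prob(cfg$discontinuation$event_hazard, "discontinuation$event_hazard")
  check_prob(cfg$discontinuation$censor_hazard, "discontinuation$censor_hazard")
  for (f in c("pocket_rate", "curiosity_rate", "nonmonitored_rate")) {
    check_pos(cfg$deviations[[f]], paste0("deviations$", f))
  }
  if (cfg$deviations$nonmonitored_min < 1) {
    stop_config("`deviations$nonmonitored_min` must be at least 1 day.")
  }
  check_prob(cfg$regimen$cyclic_prob, "regimen$cyclic_prob")
  check_prob(cfg$regimen$multi_monitor_prob, "regimen$multi_monitor_prob")
  check_prob(cfg$timing$early_fraction, "timing$early_fraction")
  invisible(cfg)
}

#' Read a cohort configuration from a YAML file
#'
#' The YAML mirrors the argument structure of [cohort_config()]; absent keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- purrr::map(raw, function(x) {
    if (is.list(x) && all(purrr::map_lgl(x, is.numeric)) &&
          !is.null(names(x)) && all(purrr::map_int(x, length) == 1)) {
      # named scalar lists from YAML -> named numeric vectors where needed
      x
    } else x
  })
  do.call(cohort_config, raw)
}

# The marginal implementation trajectory on the log-odds scale:
# logit F(t) = m0 + m1 t + m2 TI(t). Anchors: day 0 both arms, day 180
# control, day 180 with 159 exposure days (randomized at day 21).
trajectory_params <- function(cfg) {
  i <- cfg$intake
  l0 <- qlogis(min(i$impl_day0, 1 - 1e-12))
  lc <- qlogis(min(i$impl_day180_control, 1 - 1e-12))
  li <- qlogis(min(i$impl_day180_intervention, 1 - 1e-12))
  list(
    m0 = l0,
    m1 = (lc - l0) / 180,
    m2 = (li - lc) / (180 - cfg$baseline_days),
    perfect = i$impl_day0 >= 1 && i$impl_day180_control >= 1 &&
      i$impl_day180_intervention >= 1
  )
}

# Expected fraction of patient-days with a prescribed expectation of 0,
# used to convert implementation targets into intake targets:
# pi_off from cyclic off-weeks (time-constant), pi_int(t) from transient
# interruptions (0 before onset, ramping to the renewal steady state).
zero_expectation_fraction <- function(cfg, day) {
  mean_dur <- exp(cfg$interruption$duration_meanlog +
                    cfg$interruption$duration_sdlog^2 / 2)
  pi_ss <- cfg$interruption$hazard * mean_dur /
    (1 + cfg$interruption$hazard * mean_dur)
  ramp <- pmin(1, pmax(0, (day - cfg$interruption$onset_day) / mean_dur))
  pi_int <- pi_ss * ramp
  pi_off <- cfg$regimen$cyclic_prob *
    cfg$regimen$cycle_off / (cfg$regimen$cycle_on + cfg$regimen$cycle_off)
  pmin(0.95, pi_int + pi_off * (1 - pi_int))
}
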