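# The synthetic cohort generator: determinism, conservation, degenerate
# scenarios and calibration of the latent intake process.

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(allocation = 1.5), "allocation",
               class = "emadhere_config_error")
  expect_error(cohort_config(interruption = list(hazard = -0.1)),
               "hazard", class = "emadhere_config_error")
  expect_error(cohort_config(horizon_days = 10, baseline_days = 21),
               "horizon", class = "emadhere_config_error")
  expect_error(cohort_config(deviations = list(nonmonitored_min = 0)),
               "nonmonitored_min", class = "emadhere_config_error")
})

test_that("the same config and seed give identical output", {
  cfg <- cohort_config(n_patients = 15)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  for (nm in c("patients", "events", "prescriptions", "reports",
               "pill_counts", "questionnaires")) {
    expect_identical(as.data.frame(a[[nm]]), as.data.frame(b[[nm]]),
                     label = nm)
  }
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(as.data.frame(a$events), as.data.frame(c$events)))
})

test_that("written cohorts are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, seed = 9), d1)
  write_cohort(simulate_cohort(cfg, seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the noiseless scenario gives perfect implementation and persistence", {
  ch <- simulate_cohort(noiseless_config(n_patients = 10, horizon_days = 60),
                        seed = 2)
  tab <- build_adherence_table(ch$events, ch$prescriptions, ch$reports,
                               ch$pill_counts, ch$patients)
  # every patient-day has openings equal to the prescribed expectation
  expect_true(all(tab$observed_openings == tab$expected_prescribed))
  out <- daily_outcome(tab, "prescribed")
  impl <- empirical_implementation(out)
  expect_true(all(impl$estimate == 1))
  # no discontinuations: Kaplan-Meier persistence is exactly 1
  rec <- persistence_records(ch$patients, from = "randomization")
  expect_true(all(rec$status == "censored"))
  expect_true(all(km_persistence(rec[c("patient_id", "time", "status")])$estimate == 1))
})

test_that("every patient has at least one monitor and events stay within monitored windows", {
  ch <- simulate_cohort(cohort_config(n_patients = 25), seed = 4)
  expect_setequal(unique(ch$prescriptions$patient_id), ch$patients$patient_id)
  windows <- dplyr::summarise(
    dplyr::group_by(ch$prescriptions, patient_id, em_id),
    start_date = min(start_date), end_date = max(end_date), .groups = "drop"
  )
  kept <- truncate_events(ch$events, windows)
  expect_equal(nrow(attr(kept, "flagged")), 0)
  # discontinued patients have no events after their last monitored day
  last_event <- dplyr::summarise(
    dplyr::group_by(kept, patient_id), last = max(day), .groups = "drop"
  )
  joined <- dplyr::inner_join(last_event, ch$patients, by = "patient_id")
  expect_true(all(as.integer(joined$last - joined$inclusion_date) <
                    joined$exit_day))
})

test_that("injected deviations are reported exactly (conservation)", {
  ch <- simulate_cohort(cohort_config(n_patients = 40), seed = 8)
  truth <- ch$truth
  rep_pocket <- ch$reports[ch$reports$report_type == "pocket_dose", ]
  expect_equal(nrow(rep_pocket), nrow(truth$pocket_episodes))
  expect_equal(sum(rep_pocket$count), sum(truth$pocket_episodes$count))
  rep_nm <- ch$reports[ch$reports$report_type == "nonmonitored", ]
  # one report row per monitor of the patient
  expect_equal(
    nrow(rep_nm),
    sum(truth$nonmonitored_episodes$patient_id %in%
          truth$patients$patient_id[truth$patients$n_monitors == 2]) +
      nrow(truth$nonmonitored_episodes)
  )
  rep_cur <- ch$reports[ch$reports$report_type == "curiosity", ]
  expect_equal(nrow(rep_cur), nrow(truth$curiosity_checks))
})

test_that("with constant intake probability the empirical implementation matches the binomial target", {
  # flat marginal: all anchors at 0.9, no interruptions, no cycles, no
  # dropout, no deviations -> every day is Bernoulli(0.9) across patients
  cfg <- cohort_config(
    n_patients = 600, horizon_days = 60,
    intake = list(impl_day0 = 0.9, impl_day180_control = 0.9,
                  impl_day180_intervention = 0.9, sigma_patient = 1),
    interruption = list(hazard = 0),
    regimen = list(cyclic_prob = 0, multi_monitor_prob = 0,
                   dose_change_prob = 0),
    discontinuation = list(event_hazard = c(intervention = 0, control = 0),
                           censor_hazard = c(intervention = 0, control = 0)),
    deviations = list(pocket_rate = 0, curiosity_rate = 0,
                      nonmonitored_rate = 0)
  )
  ch <- simulate_cohort(cfg, seed = 31)
  tab <- build_adherence_table(ch$events, ch$prescriptions, ch$reports,
                               ch$pill_counts, ch$patients)
  impl <- empirical_implementation(daily_outcome(tab, "prescribed"))
  # 99% binomial band around 0.9 at n = 600
  band <- 2.58 * sqrt(0.9 * 0.1 / 600)
  checked <- impl$estimate[impl$day %in% c(10, 30, 50)]
  expect_true(all(abs(checked - 0.9) <= band + 1e-9))
})

test_that("arm-level latent intake probabilities converge to the configured marginal", {
  # law-of-large-numbers check on the latent layer (baseline days carry no
  # exposure effect, so both arms share the marginal trajectory there)
  cfg <- cohort_config(
    n_patients = 5000, horizon_days = 30, baseline_days = 21,
    discontinuation = list(event_hazard = c(intervention = 0, control = 0),
                           censor_hazard = c(intervention = 0, control = 0)),
    deviations = list(pocket_rate = 0, curiosity_rate = 0,
                      nonmonitored_rate = 0)
  )
  ch <- simulate_cohort(cfg, seed = 17)
  lat <- ch$truth$latent_mean_by_day
  tp <- ch$truth$calibration
  for (d in c(5, 15)) {
    target_impl <- plogis(tp$m0 + tp$m1 * d)
    pi_tot <- emadhere:::zero_expectation_fraction(cfg, d)
    target_intake <- (target_impl - pi_tot) / (1 - pi_tot)
    expect_equal(lat$mean_p_latent[lat$day == d], target_intake,
                 tolerance = 0.01)
  }
})

test_that("simulated transient interruptions match the calibrated descriptives", {
  ch <- simulate_cohort(cohort_config(n_patients = 300), seed = 19)
  sch <- build_schedule(ch$prescriptions)
  ti <- transient_interruptions(sch)
  prevalence <- length(unique(ti$patient_id)) / nrow(ch$patients)
  expect_gt(prevalence, 0.45)
  expect_lt(prevalence, 0.67)
  expect_equal(median(ti$duration), 7, tolerance = 1)
})
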