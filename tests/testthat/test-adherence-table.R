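# Pocket-dose crediting, nonmonitored masking, pill-count reconciliation and
# the assembled adherence table.

pocket_fixture <- function() {
  # 10 monitored days at 1/day; openings on days 1-4 and 8-10; days 5-7 are
  # zero-opening days (the patient pocketed doses)
  dates <- as.Date("2020-01-01") + 0:9
  events <- daily_events(start = "2020-01-01", days = 4)
  events <- dplyr::bind_rows(events, daily_events(start = "2020-01-08", days = 3))
  prescriptions <- seg(start = "2020-01-01", end = "2020-01-10")
  list(events = events, prescriptions = prescriptions, dates = dates)
}

pocket_report <- function(count, from = "2020-01-04", to = "2020-01-08") {
  tibble::tibble(
    patient_id = "P1", em_id = "P1-EM1", report_type = "pocket_dose",
    start_date = as.Date(from), end_date = as.Date(to), count = count
  )
}

pill_count <- function(dispensed, returned) {
  tibble::tibble(
    patient_id = "P1", em_id = "P1-EM1",
    period_start = as.Date("2020-01-01"), period_end = as.Date("2020-01-10"),
    dispensed = dispensed, returned = returned, tablets_per_opening = 1L
  )
}

test_that("pocket doses are credited greedily to the earliest deficit days when confirmed", {
  fx <- pocket_fixture()
  # 7 openings recorded, 9 pills consumed -> pill count supports 2 credits
  tab <- build_adherence_table(fx$events, fx$prescriptions,
                               reports = pocket_report(2),
                               pill_counts = pill_count(10, 1))
  credited <- tab$date[tab$pocket_dose_credit == 1L]
  # hand-trace of the greedy rule: the window 4..8 contains zero days 5,6,7;
  # the first two get one credit each
  expect_equal(credited, as.Date(c("2020-01-05", "2020-01-06")))
  expect_equal(sum(tab$pocket_dose_credit), 2L)
})

test_that("a pocket report without pill-count surplus yields no credit and a warning", {
  fx <- pocket_fixture()
  expect_warning(
    tab <- build_adherence_table(fx$events, fx$prescriptions,
                                 reports = pocket_report(1),
                                 pill_counts = pill_count(10, 3)),
    class = "emadhere_pocket_warning"
  )
  expect_equal(sum(tab$pocket_dose_credit), 0L)

  # no pill count at all: never confirmed
  expect_warning(
    tab2 <- build_adherence_table(fx$events, fx$prescriptions,
                                  reports = pocket_report(1)),
    class = "emadhere_pocket_warning"
  )
  expect_equal(sum(tab2$pocket_dose_credit), 0L)
})

test_that("credits never exceed the reported count even with more deficit days", {
  fx <- pocket_fixture()
  tab <- build_adherence_table(fx$events, fx$prescriptions,
                               reports = pocket_report(1, "2020-01-05", "2020-01-07"),
                               pill_counts = pill_count(10, 1))
  expect_equal(sum(tab$pocket_dose_credit), 1L)
  expect_equal(tab$date[tab$pocket_dose_credit == 1L], as.Date("2020-01-05"))
})

test_that("without reports all credits are zero and all days are monitored", {
  fx <- pocket_fixture()
  tab <- build_adherence_table(fx$events, fx$prescriptions)
  expect_true(all(tab$pocket_dose_credit == 0L))
  expect_true(all(tab$monitored))
})

test_that("nonmonitored periods mask exactly the reported days and nothing else", {
  fx <- pocket_fixture()
  nm <- tibble::tibble(
    patient_id = "P1", em_id = "P1-EM1", report_type = "nonmonitored",
    start_date = as.Date("2020-01-03"), end_date = as.Date("2020-01-07"),
    count = NA_integer_
  )
  tab <- build_adherence_table(fx$events, fx$prescriptions, reports = nm)
  expect_equal(sum(!tab$monitored), 5)
  expect_equal(tab$date[!tab$monitored], as.Date("2020-01-03") + 0:4)
  # masking does not alter counts
  base <- build_adherence_table(fx$events, fx$prescriptions)
  expect_equal(tab$observed_openings, base$observed_openings)

  # a period outside the window warns
  off <- nm
  off$start_date <- as.Date("2021-01-01")
  off$end_date <- as.Date("2021-01-05")
  expect_warning(mask_nonmonitored(base, off), class = "emadhere_mask_warning")
})

test_that("masking with an empty report set is the identity", {
  fx <- pocket_fixture()
  base <- build_adherence_table(fx$events, fx$prescriptions)
  expect_identical(mask_nonmonitored(base, NULL), base)
})

test_that("curiosity checks are subtracted under the default policy only", {
  fx <- pocket_fixture()
  cur <- tibble::tibble(
    patient_id = "P1", em_id = "P1-EM1", report_type = "curiosity",
    start_date = as.Date("2020-01-02"), end_date = as.Date("2020-01-02"),
    count = 1L
  )
  tab_sub <- build_adherence_table(fx$events, fx$prescriptions, reports = cur)
  tab_ign <- build_adherence_table(fx$events, fx$prescriptions, reports = cur,
                                   curiosity_policy = "ignore")
  d2 <- tab_sub$date == as.Date("2020-01-02")
  expect_equal(tab_sub$observed_openings[d2], 0L)
  expect_equal(tab_ign$observed_openings[d2], 1L)
})

test_that("pill-count percentages follow the arithmetic and discrepancies are flagged", {
  # 28 expected pills; dispensed 30, returned 2 -> 100%; returned 9 -> 75%
  prescriptions <- seg(start = "2020-01-01", end = "2020-01-28")
  events <- daily_events(start = "2020-01-01", days = 28)
  tab <- build_adherence_table(events, prescriptions)
  pc <- tibble::tibble(
    patient_id = "P1", em_id = "P1-EM1",
    period_start = as.Date("2020-01-01"), period_end = as.Date("2020-01-28"),
    dispensed = 30L, returned = c(2L, 9L), tablets_per_opening = 1L
  )
  rec <- reconcile_pill_count(tab, pc)
  expect_equal(rec$percentage, c(100, 75))
  # 28 openings recorded: consuming 28 agrees, consuming 21 is off by 7
  expect_equal(rec$discrepancy, c(FALSE, TRUE))
  expect_error(reconcile_pill_count(tab, dplyr::mutate(pc, returned = 40L)),
               class = "emadhere_data_error")
})

test_that("the cleaning pipeline is deterministic", {
  fx <- pocket_fixture()
  a <- build_adherence_table(fx$events, fx$prescriptions,
                             reports = pocket_report(2),
                             pill_counts = pill_count(10, 1))
  b <- build_adherence_table(fx$events, fx$prescriptions,
                             reports = pocket_report(2),
                             pill_counts = pill_count(10, 1))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("event conservation holds end to end on a simulated cohort", {
  ch <- simulate_cohort(cohort_config(n_patients = 12), seed = 3)
  tab <- suppressWarnings(build_adherence_table(
    ch$events, ch$prescriptions, ch$reports, ch$pill_counts, ch$patients
  ))
  qc <- attr(tab, "qc")
  # every retained event lands in exactly one day count (before curiosity
  # subtraction); curiosity-subtracted openings are accounted in the QC
  expect_equal(sum(tab$observed_openings) + qc$n_curiosity_subtracted,
               qc$n_events_retained)
  expect_equal(qc$n_events_retained + qc$n_events_flagged, nrow(ch$events))
  # credits never exceed reported pocket doses
  reported <- sum(ch$reports$count[ch$reports$report_type == "pocket_dose"])
  expect_lte(sum(tab$pocket_dose_credit), reported)
})
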