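# Implementation, persistence and adherence curves.

make_outcomes <- function(values, day = 0L) {
  tibble::tibble(
    patient_id = paste0("P", seq_along(values)),
    day_index = day, value = values, convention = "prescribed"
  )
}

test_that("empirical implementation is the proportion correct among observed", {
  cur <- empirical_implementation(make_outcomes(c(1L, 1L, 1L, 0L)))
  expect_equal(cur$estimate, 0.75)
  expect_equal(cur$n, 4L)
  # missing outcomes leave the denominator
  cur2 <- empirical_implementation(make_outcomes(c(1L, 1L, NA, 0L)))
  expect_equal(cur2$estimate, 2 / 3)
  expect_equal(cur2$n, 3L)
  # all correct -> constant 1
  cur3 <- empirical_implementation(
    dplyr::bind_rows(make_outcomes(rep(1L, 5), 0L),
                     make_outcomes(rep(1L, 5), 1L))
  )
  expect_true(all(cur3$estimate == 1))
})

test_that("product-limit persistence matches hand computation", {
  # no events -> S = 1 everywhere
  rec0 <- tibble::tibble(patient_id = paste0("P", 1:5),
                         time = c(10, 20, 30, 40, 50), status = "censored")
  s0 <- km_persistence(rec0)
  expect_true(all(s0$estimate == 1))

  # 1 event at day 10 among 10 at risk -> S(10) = 0.9
  rec1 <- tibble::tibble(
    patient_id = paste0("P", 1:10),
    time = c(10, rep(50, 9)),
    status = c("event", rep("censored", 9))
  )
  s1 <- km_persistence(rec1)
  expect_equal(s1$estimate[s1$day == 10], 0.9)
  expect_equal(s1$estimate[s1$day == 9], 1)

  # staggered censoring, hand-computed product-limit table:
  # times: 5(event,6 at risk) -> 5/6; 8(censor); 12(event,4 at risk) -> 5/6*3/4
  # 15(censor); 20(event,2 at risk) -> 5/6*3/4*1/2; 25(censor)
  rec2 <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    time = c(5, 8, 12, 15, 20, 25),
    status = c("event", "censored", "event", "censored", "event", "censored")
  )
  s2 <- km_persistence(rec2)
  expect_equal(s2$estimate[s2$day == 5], 5 / 6)
  expect_equal(s2$estimate[s2$day == 12], 5 / 6 * 3 / 4)
  expect_equal(s2$estimate[s2$day == 20], 5 / 6 * 3 / 4 * 1 / 2, tolerance = 1e-12)
  expect_true(all(diff(s2$estimate) <= 1e-12))
  expect_equal(s2$estimate[s2$day == 0], 1)
})

test_that("without censoring the product-limit estimate equals the empirical survival function", {
  set.seed(99)
  for (rep in 1:5) {
    times <- sample(1:30, 12, replace = TRUE)
    rec <- tibble::tibble(patient_id = paste0("P", 1:12),
                          time = times, status = "event")
    km <- km_persistence(rec)
    emp <- vapply(km$day, function(d) mean(times > d), numeric(1))
    expect_equal(km$estimate, emp, tolerance = 1e-12)
  }
})

test_that("negative persistence times are a data error", {
  expect_error(
    km_persistence(tibble::tibble(patient_id = "P1", time = -1, status = "event")),
    class = "emadhere_data_error"
  )
})

test_that("adherence is the product of implementation and persistence and is bounded by both", {
  outcomes <- dplyr::bind_rows(lapply(0:20, function(d) {
    make_outcomes(rep(c(1L, 1L, 1L, 1L, 0L), 4), day = d)
  }))
  rec <- tibble::tibble(
    patient_id = paste0("P", 1:20),
    time = c(10, rep(30, 19)),
    status = c("event", rep("censored", 19))
  )
  adh <- empirical_adherence(outcomes, rec)
  impl <- empirical_implementation(outcomes)
  km <- km_persistence(rec, day_grid = impl$day)
  joined <- dplyr::inner_join(
    tibble::as_tibble(adh$product)[, c("day", "estimate")],
    dplyr::inner_join(tibble::as_tibble(impl)[, c("day", "estimate")],
                      tibble::as_tibble(km)[, c("day", "estimate")],
                      by = "day", suffix = c("_i", "_s")),
    by = "day"
  )
  expect_equal(joined$estimate, joined$estimate_i * joined$estimate_s)
  expect_true(all(joined$estimate <= joined$estimate_i + 1e-12))
  expect_true(all(joined$estimate <= joined$estimate_s + 1e-12))
  # spot value: I = 0.8, S(15) = 0.95 -> A = 0.76
  expect_equal(joined$estimate[joined$day == 15], 0.8 * 0.95)
  # empirical variant: the discontinued patient (P1, event at day 10) counts
  # as 0 after day 10 while staying in the denominator of 20; P1's own
  # outcome pattern contributes 1s before. On day 15: 15 correct followers
  # of the 4-in-5 pattern, P1 forced to 0 -> 15/20
  emp <- adh$empirical
  expect_equal(emp$estimate[emp$day == 15], 15 / 20)
  expect_equal(emp$n[emp$day == 15], 20L)
})

test_that("with no discontinuations the adherence curve equals the implementation curve", {
  outcomes <- dplyr::bind_rows(lapply(0:10, function(d) {
    make_outcomes(rep(c(1L, 0L), 5), day = d)
  }))
  rec <- tibble::tibble(patient_id = paste0("P", 1:10),
                        time = 30, status = "censored")
  adh <- empirical_adherence(outcomes, rec)
  impl <- empirical_implementation(outcomes)
  expect_equal(adh$product$estimate, impl$estimate)
  expect_equal(adh$empirical$estimate, impl$estimate)
})

test_that("mismatched cohorts are rejected", {
  outcomes <- make_outcomes(c(1L, 0L))
  rec <- tibble::tibble(patient_id = c("P1", "P2", "P99"),
                        time = 10, status = "censored")
  expect_error(empirical_adherence(outcomes, rec),
               class = "emadhere_data_error")
})
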