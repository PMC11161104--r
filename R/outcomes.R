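#' Daily binary intake outcome
#'
#' Medication intake on day *t* is correct (1) when, for **every** electronic
#' monitor assigned to the patient that day, the observed openings plus any
#' pocket-dose credit reach at least the expected openings under the chosen
#' convention; incorrect (0) otherwise; and missing when any of the patient's
#' monitors is in a nonmonitored period that day.
#'
#' Under the `"prescribed"` convention, days inside an oncologist-prescribed
#' transient interruption have an expectation of 0, so taking nothing is
#' optimal implementation. Under the `"onlabel"` convention the expectation
#' is the manufacturer's recommended regimen, so the same days typically
#' score 0 — the comparison quantifies how much implementation would be
#' underestimated if prescribed interruptions were ignored.
#'
#' @param table an adherence table from [build_adherence_table()].
#' @param convention `"prescribed"` (default) or `"onlabel"`.
#' @return a tibble with one row per patient-day: `patient_id`, `date`,
#'   `day_index`, `value` (1/0/`NA`), `convention`, plus any per-patient
#'   covariables present in `table` (constant within patient).
#' @export
daily_outcome <- function(table, convention = c("prescribed", "onlabel")) {
  convention <- arg_match(convention)
  expected_col <- if (convention == "prescribed") "expected_prescribed" else "expected_onlabel"

  per_monitor_cols <- c(
    "em_id", "observed_openings", "pocket_dose_credit",
    "expected_prescribed", "expected_onlabel", "segment_type", "monitored"
  )
  covar_cols <- setdiff(names(table), c(per_monitor_cols, "patient_id", "date", "day_index"))

  table %>%
    group_by(.data$patient_id, .data$date, .data$day_index) %>%
    summarise(
      value = if_else(
        any(!.data$monitored),
        NA_integer_,
        as.integer(all(.data$observed_openings + .data$pocket_dose_credit >=
                         .data[[expected_col]]))
      ),
      across(all_of(covar_cols), first),
      .groups = "drop"
    ) %>%
    mutate(convention = convention) %>%
    arrange(.data$patient_id, .data$date)
}
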