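#' Expand a prescription history into a day-level expected-openings schedule
#'
#' Prescription records arrive as dated regimen segments per electronic
#' monitor: regular dosing, the on/off phases of cyclic regimens (e.g. 21
#' days on / 7 days off), and oncologist-prescribed transient interruptions.
#' `build_schedule()` turns them into one row per (patient, monitor, calendar
#' day) carrying the number of expected monitor openings under two
#' conventions:
#'
#' * `expected_prescribed` — the oncologist's regimen in force that day.
#'   During a prescribed transient interruption the expectation is 0 (taking
#'   nothing is optimal implementation of the prescription).
#' * `expected_onlabel` — the manufacturer's recommended regimen in force
#'   during the segment, used as the comparator convention. Off-weeks of a
#'   cyclic regimen have an on-label expectation of 0 as well, because the
#'   label itself prescribes the pause.
#'
#' @param segments a data frame with one row per regimen segment and columns
#'   `patient_id`, `em_id`, `start_date`, `end_date` (inclusive calendar
#'   dates), `expected_openings_per_day`, `segment_type` (one of `"regular"`,
#'   `"cycle_on"`, `"cycle_off"`, `"interruption"`) and
#'   `label_openings_per_day`. An optional `reason` column (for
#'   interruptions) is carried through.
#' @return a tibble with columns `patient_id`, `em_id`, `date`,
#'   `expected_prescribed`, `expected_onlabel`, `segment_type` (and `reason`
#'   if supplied), one row per monitored day of each monitor.
#' @details Segment dates are inclusive on both ends. Segments of one monitor
#'   must tile its span: overlaps raise a schedule-conflict error listing the
#'   offending days and gaps raise a coverage error, because a day under
#'   monitoring must have a defined expectation. Rebuilding from the same
#'   segments (in any row order) gives an identical schedule.
#' @seealso [transient_interruptions()]
#' @export
build_schedule <- function(segments) {
  required <- c(
    "patient_id", "em_id", "start_date", "end_date",
    "expected_openings_per_day", "segment_type", "label_openings_per_day"
  )
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols)) {
    stop_data(glue::glue(
      "prescription segments lack column(s): {toString(missing_cols)}"
    ))
  }
  segments <- as_tibble(segments) %>%
    mutate(
      start_date = lubridate::as_date(.data$start_date),
      end_date = lubridate::as_date(.data$end_date)
    ) %>%
    arrange(.data$patient_id, .data$em_id, .data$start_date)

  if (any(segments$end_date < segments$start_date)) {
    stop_data("prescription segment with end_date before start_date")
  }
  if (any(segments$expected_openings_per_day < 0 |
            segments$label_openings_per_day < 0)) {
    stop_data("expected openings per day must be non-negative")
  }
  bad_int <- segments$segment_type == "interruption" &
    segments$expected_openings_per_day != 0
  if (any(bad_int)) {
    stop_data("interruption segments must have expected_openings_per_day = 0")
  }
  types <- c("regular", "cycle_on", "cycle_off", "interruption")
  if (!all(segments$segment_type %in% types)) {
    stop_data(glue::glue(
      "segment_type must be one of {toString(types)}"
    ))
  }

  keep <- intersect(c("reason"), names(segments))
  days <- segments %>%
    mutate(.seg = row_number(), n_days = as.integer(.data$end_date - .data$start_date) + 1L) %>%
    tidyr::uncount(.data$n_days, .id = ".offset") %>%
    mutate(
      date = .data$start_date + .data$.offset - 1L,
      expected_prescribed = as.integer(.data$expected_openings_per_day),
      expected_onlabel = as.integer(.data$label_openings_per_day)
    ) %>%
    select(
      "patient_id", "em_id", "date",
      "expected_prescribed", "expected_onlabel", "segment_type",
      all_of(keep)
    )

  dup <- days %>%
    dplyr::count(.data$patient_id, .data$em_id, .data$date) %>%
    filter(.data$n > 1L)
  if (nrow(dup)) {
    show <- head(dup, 5)
    stop_data(glue::glue(
      "overlapping prescription segments: monitor {show$em_id[1]} is covered ",
      "more than once on {nrow(dup)} day(s), e.g. {toString(head(show$date, 5))}"
    ))
  }

  gaps <- days %>%
    group_by(.data$patient_id, .data$em_id) %>%
    summarise(
      span = as.integer(max(.data$date) - min(.data$date)) + 1L,
      covered = dplyr::n(), .groups = "drop"
    ) %>%
    filter(.data$span != .data$covered)
  if (nrow(gaps)) {
    stop_data(glue::glue(
      "prescription history has coverage gaps for monitor(s) ",
      "{toString(head(gaps$em_id, 5))}: every day between the first and last ",
      "segment must have a defined expectation"
    ))
  }

  days %>% arrange(.data$patient_id, .data$em_id, .data$date)
}

#' Find prescribed transient interruptions in a schedule
#'
#' A transient interruption is a maximal run of consecutive days on which the
#' oncologist's prescribed expectation is 0 while the manufacturer's label
#' still expects dosing. Off-weeks of cyclic regimens are excluded because
#' the label expectation is 0 there too. Following the trial's descriptive
#' definition, only runs strictly longer than `min_run - 1` days (i.e. "more
#' than 2 days in a row" with the default) are reported.
#'
#' @param schedule a day-level schedule from [build_schedule()].
#' @param min_run minimal run length, in days, for a run to count (default 3,
#'   i.e. runs of more than 2 consecutive days).
#' @return a tibble with one row per interruption window: `patient_id`,
#'   `em_id`, `start_date`, `end_date`, `duration` (days).
#' @export
transient_interruptions <- function(schedule, min_run = 3) {
  stopifnot(min_run >= 1)
  runs <- schedule %>%
    arrange(.data$patient_id, .data$em_id, .data$date) %>%
    group_by(.data$patient_id, .data$em_id) %>%
    mutate(
      interrupted = .data$expected_prescribed == 0L & .data$expected_onlabel > 0L,
      new_run = .data$interrupted &
        (row_number() == 1L | !lag(.data$interrupted, default = FALSE) |
           .data$date != lag(.data$date, default = lubridate::as_date(NA)) + 1L),
      run_id = cumsum(.data$new_run)
    ) %>%
    filter(.data$interrupted) %>%
    ungroup()
  if (!nrow(runs)) {
    return(tibble(patient_id = character(), em_id = character(),
                  start_date = as.Date(character()),
                  end_date = as.Date(character()), duration = integer()))
  }
  runs %>%
    group_by(.data$patient_id, .data$em_id, .data$run_id) %>%
    summarise(
      start_date = min(.data$date),
      end_date = max(.data$date),
      duration = dplyr::n(),
      .groups = "drop"
    ) %>%
    filter(.data$duration >= min_run) %>%
    select(-"run_id") %>%
    arrange(.data$patient_id, .data$em_id, .data$start_date)
}
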