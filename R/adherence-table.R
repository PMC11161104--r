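# The day-level adherence table: the pipeline's central artifact.
# One row per (patient, monitor, day) with observed vs expected openings,
# pocket-dose credits, the monitored flag and patient covariables.

#' Insert pocket-dose credits confirmed by pill counts
#'
#' A pocket dose is a dose removed from the monitor in advance and taken
#' later, on a day with no recorded opening. When a patient reports pocket
#' doses and the pill count for the refill period confirms that at least that
#' many pills left the bottle beyond the recorded openings, the reported
#' number of non-openings is corrected by crediting one opening per deficit
#' day inside the reported window, earliest deficit first, up to the reported
#' count. Unconfirmed reports yield no credit and a warning.
#'
#' @param table a day-level table with columns `patient_id`, `em_id`, `date`,
#'   `observed_openings`, `expected_prescribed`.
#' @param reports patient reports; rows with `report_type == "pocket_dose"`
#'   are used (`patient_id`, `em_id`, `start_date`, `end_date`, `count`).
#' @param pill_counts per refill period: `patient_id`, `em_id`,
#'   `period_start`, `period_end`, `dispensed`, `returned` and optionally
#'   `tablets_per_opening` (default 1). A report is confirmed by the
#'   period(s) overlapping its window.
#' @return `table` with a `pocket_dose_credit` column (0 where no credit).
#' @export
apply_pocket_doses <- function(table, reports = NULL, pill_counts = NULL) {
  table <- as_tibble(table) %>%
    mutate(pocket_dose_credit = 0L) %>%
    arrange(.data$patient_id, .data$em_id, .data$date)
  pockets <- if (is.null(reports)) tibble() else
    filter(as_tibble(reports), .data$report_type == "pocket_dose")
  if (!nrow(pockets)) return(table)

  if (!is.null(pill_counts)) {
    pill_counts <- as_tibble(pill_counts)
    if (!"tablets_per_opening" %in% names(pill_counts)) {
      pill_counts$tablets_per_opening <- 1L
    }
  }

  for (k in seq_len(nrow(pockets))) {
    rep_k <- pockets[k, ]
    rows <- which(
      table$patient_id == rep_k$patient_id &
        table$em_id == rep_k$em_id &
        table$date >= rep_k$start_date &
        table$date <= rep_k$end_date
    )
    deficit <- rows[table$observed_openings[rows] + table$pocket_dose_credit[rows] <
                      table$expected_prescribed[rows]]
    if (!length(deficit)) next

    allowed <- 0L
    if (!is.null(pill_counts)) {
      periods <- pill_counts %>%
        filter(
          .data$patient_id == rep_k$patient_id,
          .data$em_id == rep_k$em_id,
          .data$period_start <= rep_k$end_date,
          .data$period_end >= rep_k$start_date
        )
      if (nrow(periods)) {
        # Pills that left the bottle beyond what the recorded openings explain,
        # expressed in openings.
        for (j in seq_len(nrow(periods))) {
          per <- periods[j, ]
          in_per <- table$patient_id == per$patient_id &
            table$em_id == per$em_id &
            table$date >= per$period_start & table$date <= per$period_end
          openings <- sum(table$observed_openings[in_per])
          consumed <- (per$dispensed - per$returned) / per$tablets_per_opening
          allowed <- allowed + max(0L, as.integer(floor(consumed)) - openings)
        }
      }
    }
    credit <- min(rep_k$count, length(deficit), allowed)
    if (credit < rep_k$count) {
      why <- if (credit == 0) "not confirmed by pill count, no credit inserted"
             else paste("only", credit, "credit(s) supported by the pill count")
      warn(glue::glue(
        "pocket-dose report for {rep_k$patient_id}/{rep_k$em_id} ",
        "({rep_k$start_date}..{rep_k$end_date}, count {rep_k$count}): {why}"
      ), class = "emadhere_pocket_warning")
    }
    if (credit > 0) {
      take <- deficit[seq_len(credit)]  # chronological: earliest deficit first
      table$pocket_dose_credit[take] <- table$pocket_dose_credit[take] + 1L
    }
  }
  table
}

#' Mask nonmonitored periods
#'
#' During periods when the monitor was not used (e.g. hospitalisations),
#' collected in the case report forms, the implementation outcome is missing:
#' the affected days are flagged `monitored = FALSE` and excluded from every
#' outcome denominator downstream. Counts on other days are untouched.
#'
#' @param table a day-level table with `patient_id`, `em_id`, `date`.
#' @param reports patient reports; rows with `report_type == "nonmonitored"`
#'   are used.
#' @return `table` with a logical `monitored` column.
#' @export
mask_nonmonitored <- function(table, reports = NULL) {
  table <- as_tibble(table)
  if (!"monitored" %in% names(table)) table$monitored <- TRUE
  nm <- if (is.null(reports)) tibble() else
    filter(as_tibble(reports), .data$report_type == "nonmonitored")
  if (!nrow(nm)) return(table)
  for (k in seq_len(nrow(nm))) {
    rep_k <- nm[k, ]
    rows <- table$patient_id == rep_k$patient_id &
      table$em_id == rep_k$em_id &
      table$date >= rep_k$start_date & table$date <= rep_k$end_date
    if (!any(rows)) {
      warn(glue::glue(
        "nonmonitored period {rep_k$start_date}..{rep_k$end_date} for ",
        "{rep_k$patient_id}/{rep_k$em_id} lies outside the monitored window"
      ), class = "emadhere_mask_warning")
      next
    }
    table$monitored[rows] <- FALSE
  }
  table
}

#' Reconcile recorded openings against a pharmacy pill count
#'
#' Pharmacy technicians count pills at each refill to compute an aggregated
#' percentage of medication intake since the last refill, and the count is
#' used to cross-check the electronic record (important with multiple tablets
#' per intake). The percentage is (dispensed - returned) / expected pills
#' over the period x 100; a discrepancy is flagged when the pills consumed
#' disagree with (openings + credits) x tablets-per-opening by more than
#' `tolerance` tablets.
#'
#' @param table an adherence table covering the periods (needs
#'   `observed_openings`, `pocket_dose_credit`, `expected_prescribed`).
#' @param pill_counts per refill period: `patient_id`, `em_id`,
#'   `period_start`, `period_end`, `dispensed`, `returned`, optionally
#'   `tablets_per_opening` (default 1).
#' @param tolerance allowed absolute disagreement, in tablets (default 2).
#' @return a tibble, one row per period, with `percentage` and `discrepancy`.
#' @export
reconcile_pill_count <- function(table, pill_counts, tolerance = 2) {
  pill_counts <- as_tibble(pill_counts)
  if (!"tablets_per_opening" %in% names(pill_counts)) {
    pill_counts$tablets_per_opening <- 1L
  }
  if (any(pill_counts$returned < 0) ||
        any(pill_counts$returned > pill_counts$dispensed)) {
    stop_data("pill count with returned < 0 or returned > dispensed")
  }
  if (!"pocket_dose_credit" %in% names(table)) table$pocket_dose_credit <- 0L

  purrr::map_dfr(seq_len(nrow(pill_counts)), function(j) {
    per <- pill_counts[j, ]
    days <- table %>%
      filter(
        .data$patient_id == per$patient_id, .data$em_id == per$em_id,
        .data$date >= per$period_start, .data$date <= per$period_end
      )
    expected_pills <- sum(days$expected_prescribed) * per$tablets_per_opening
    consumed <- per$dispensed - per$returned
    accounted <- sum(days$observed_openings + days$pocket_dose_credit) *
      per$tablets_per_opening
    tibble(
      patient_id = per$patient_id, em_id = per$em_id,
      period_start = per$period_start, period_end = per$period_end,
      percentage = if (expected_pills > 0) 100 * consumed / expected_pills else NA_real_,
      discrepancy = abs(consumed - accounted) > tolerance
    )
  })
}

#' Build the day-level adherence table from raw inputs
#'
#' Runs the full database-construction procedure: expand the prescription
#' history into the expected-openings schedule, truncate the event log to
#' each monitor's window with the 03:00 day boundary, count daily openings,
#' optionally subtract reported curiosity checks (openings without intake),
#' insert pill-count-confirmed pocket-dose credits, mask nonmonitored
#' periods, and join patient covariables. Deterministic: the same inputs give
#' an identical table.
#'
#' @param events raw EM opening log (`patient_id`, `em_id`, `timestamp`).
#' @param prescriptions prescription segments (see [build_schedule()]).
#' @param reports patient reports (`report_type` of `"pocket_dose"`,
#'   `"nonmonitored"` or `"curiosity"`), or `NULL`.
#' @param pill_counts refill pill counts, or `NULL` (pocket-dose reports then
#'   cannot be confirmed and yield no credit).
#' @param patients one row per patient with `patient_id`, `inclusion_date`
#'   and any covariables to carry (arm, randomization day, age, gender, ...);
#'   or `NULL`, in which case `day_index` counts from each patient's first
#'   scheduled day.
#' @param curiosity_policy `"subtract"` (default) removes reported
#'   curiosity-check openings from the day's count (floor 0); `"ignore"`
#'   leaves counts untouched.
#' @param tz local civil timezone for day assignment.
#' @return a tibble with one row per (patient, monitor, day): columns
#'   `patient_id`, `em_id`, `date`, `day_index`, `observed_openings`,
#'   `pocket_dose_credit`, `expected_prescribed`, `expected_onlabel`,
#'   `segment_type`, `monitored`, plus any covariables from `patients`.
#'   QC counts (flagged events, credits) in `attr(, "qc")`.
#' @export
build_adherence_table <- function(events, prescriptions, reports = NULL,
                                  pill_counts = NULL, patients = NULL,
                                  curiosity_policy = c("subtract", "ignore"),
                                  tz = "Europe/Zurich") {
  curiosity_policy <- arg_match(curiosity_policy)
  schedule <- build_schedule(prescriptions)
  windows <- schedule %>%
    group_by(.data$patient_id, .data$em_id) %>%
    summarise(
      start_date = min(.data$date), end_date = max(.data$date),
      .groups = "drop"
    )

  retained <- truncate_events(events, windows, tz = tz)
  flagged <- attr(retained, "flagged")
  counts <- count_daily_openings(retained, tz = tz)

  table <- schedule %>%
    left_join(counts, by = c("patient_id", "em_id", "date" = "day")) %>%
    mutate(observed_openings = dplyr::coalesce(.data$observed_openings, 0L))

  n_curiosity <- 0L
  if (curiosity_policy == "subtract" && !is.null(reports)) {
    cur <- filter(as_tibble(reports), .data$report_type == "curiosity")
    if (nrow(cur)) {
      cur_days <- cur %>%
        mutate(n_days = as.integer(.data$end_date - .data$start_date) + 1L) %>%
        tidyr::uncount(.data$n_days, .id = ".off") %>%
        mutate(date = .data$start_date + .data$.off - 1L) %>%
        group_by(.data$patient_id, .data$em_id, .data$date) %>%
        summarise(curiosity = sum(.data$count), .groups = "drop")
      table <- table %>%
        left_join(cur_days, by = c("patient_id", "em_id", "date")) %>%
        mutate(
          curiosity = dplyr::coalesce(.data$curiosity, 0L),
          observed_openings = pmax(0L, .data$observed_openings - .data$curiosity)
        ) %>%
        select(-"curiosity")
      n_curiosity <- sum(cur_days$curiosity)
    }
  }

  table <- apply_pocket_doses(table, reports, pill_counts)
  table <- mask_nonmonitored(table, reports)

  if (!is.null(patients)) {
    patients <- as_tibble(patients)
    table <- table %>%
      left_join(patients, by = "patient_id") %>%
      mutate(day_index = as.integer(.data$date - .data$inclusion_date))
  } else {
    table <- table %>%
      group_by(.data$patient_id) %>%
      mutate(day_index = as.integer(.data$date - min(.data$date))) %>%
      ungroup()
  }

  out <- table %>% arrange(.data$patient_id, .data$em_id, .data$date)
  attr(out, "qc") <- list(
    n_events_retained = nrow(retained),
    n_events_flagged = nrow(flagged),
    flagged_events = flagged,
    n_curiosity_subtracted = n_curiosity,
    n_pocket_credits = sum(out$pocket_dose_credit),
    n_days_nonmonitored = sum(!out$monitored)
  )
  out
}
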