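#' Truncate an EM event log to the monitored window of each monitor
#'
#' Openings recorded outside the actual start and end dates of electronic
#' monitor use (e.g. test openings at the pharmacy before hand-out, or
#' openings after the bottle was returned) must not enter the dosing-history
#' database. Events are first assigned to a monitoring day with the 03:00
#' boundary rule ([em_day()]), then kept only if that day lies inside the
#' monitor's window. Out-of-window events are flagged, not silently dropped:
#' they are returned in the `"flagged"` attribute and counted in the QC
#' summary.
#'
#' @param events a data frame with columns `patient_id`, `em_id`,
#'   `timestamp` (POSIXct, or ISO-8601 strings parseable by
#'   [lubridate::ymd_hms()]).
#' @param windows one row per monitor: `patient_id`, `em_id`, `start_date`,
#'   `end_date` (inclusive monitoring-day dates).
#' @param tz local civil timezone used for day assignment.
#' @return the retained events as a tibble with an added `day` column; the
#'   discarded rows are attached as `attr(, "flagged")`.
#' @export
truncate_events <- function(events, windows, tz = "Europe/Zurich") {
  events <- as_tibble(events)
  if (!inherits(events$timestamp, "POSIXct")) {
    parsed <- lubridate::ymd_hms(events$timestamp, tz = tz, quiet = TRUE)
    if (any(is.na(parsed) & !is.na(events$timestamp))) {
      stop_data("unparseable timestamps in the event log")
    }
    events$timestamp <- parsed
  }
  orphans <- events %>%
    dplyr::anti_join(windows, by = c("patient_id", "em_id")) %>%
    distinct(.data$patient_id, .data$em_id)
  if (nrow(orphans)) {
    stop_data(glue::glue(
      "monitor(s) with events but no monitoring window: ",
      "{toString(head(paste(orphans$patient_id, orphans$em_id, sep = '/'), 5))}"
    ))
  }

  events <- events %>%
    mutate(day = em_day(.data$timestamp, tz = tz)) %>%
    left_join(
      windows %>% select("patient_id", "em_id", "start_date", "end_date"),
      by = c("patient_id", "em_id")
    ) %>%
    mutate(in_window = .data$day >= .data$start_date & .data$day <= .data$end_date)

  flagged <- events %>% filter(!.data$in_window) %>%
    select("patient_id", "em_id", "timestamp", "day")
  retained <- events %>% filter(.data$in_window) %>%
    select("patient_id", "em_id", "timestamp", "day")
  attr(retained, "flagged") <- flagged
  retained
}

#' Count daily EM openings with the 03:00 day boundary
#'
#' @param events a (truncated) event log; if it lacks a `day` column the
#'   03:00-boundary day is computed from `timestamp`.
#' @param tz local civil timezone used for day assignment.
#' @return a tibble (`patient_id`, `em_id`, `day`, `observed_openings`) with
#'   one row per monitor-day that has at least one opening. Days with no
#'   openings are implicit zeros; the adherence-table builder fills them in
#'   against the schedule grid. The counts sum to the number of input events.
#' @export
count_daily_openings <- function(events, tz = "Europe/Zurich") {
  events <- as_tibble(events)
  if (!"day" %in% names(events)) {
    events <- events %>% mutate(day = em_day(.data$timestamp, tz = tz))
  }
  events %>%
    group_by(.data$patient_id, .data$em_id, .data$day) %>%
    summarise(observed_openings = dplyr::n(), .groups = "drop") %>%
    arrange(.data$patient_id, .data$em_id, .data$day)
}
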