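# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk.

TZ <- "Europe/Zurich"

seg <- function(patient = "P1", em = "P1-EM1", start, end, expected = 1L,
                type = "regular", label = expected, reason = NA_character_) {
  tibble::tibble(
    patient_id = patient, em_id = em,
    start_date = as.Date(start), end_date = as.Date(end),
    expected_openings_per_day = as.integer(expected),
    segment_type = type,
    label_openings_per_day = as.integer(label),
    reason = reason
  )
}

ts_local <- function(x) as.POSIXct(x, tz = TZ)

ev <- function(patient = "P1", em = "P1-EM1", when) {
  tibble::tibble(patient_id = patient, em_id = em,
                 timestamp = ts_local(when))
}

# One regular monitor with one opening per day over [start, end] and an event
# at `hour` on every day; convenient base for pipeline tests.
daily_events <- function(patient = "P1", em = "P1-EM1",
                         start, days, hour = "09:00:00") {
  dates <- as.Date(start) + seq_len(days) - 1
  tibble::tibble(
    patient_id = patient, em_id = em,
    timestamp = ts_local(paste(dates, hour))
  )
}

# Direct simulation of correlated binary panels from a random-intercept
# logistic model; marginal logit is m0 + m2 * TI(t). Used for the GEE
# cross-checks and the coverage property.
sim_panel <- function(n = 40, days = 100, m0 = 2, m2 = 0, sigma = 1,
                      rand_day = 10) {
  conv <- emadhere:::conditional_logit_fun(sigma)
  arm <- rep(c("intervention", "control"), length.out = n)
  b <- rnorm(n, 0, sigma)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- 0:(days - 1)
    ti <- if (arm[i] == "intervention") pmax(0, t - rand_day) else 0 * t
    eta <- conv(m0 + m2 * ti) + b[i]
    data.frame(
      patient_id = sprintf("P%03d", i), day_index = t,
      value = as.integer(runif(days) < plogis(eta)),
      arm = arm[i], randomization_day = rand_day
    )
  }))
  tibble::as_tibble(df)
}

# A brute-force day-by-day reference implementation of the cleaning stage
# (naive loops, no vectorisation), used as the oracle for small cohorts.
naive_adherence_table <- function(events, prescriptions, reports = NULL,
                                  pill_counts = NULL,
                                  curiosity_policy = "subtract", tz = TZ) {
  day_of <- function(t) {
    # the 03:00 rule on the local wall clock
    stamp <- format(t, tz = tz, format = "%Y-%m-%d %H")
    d <- as.Date(substr(stamp, 1, 10))
    h <- as.integer(substr(stamp, 12, 13))
    d - (h < 3)
  }
  monitors <- unique(prescriptions[c("patient_id", "em_id")])
  rows <- list()
  for (m in seq_len(nrow(monitors))) {
    pid <- monitors$patient_id[m]
    em <- monitors$em_id[m]
    segs <- prescriptions[prescriptions$patient_id == pid &
                            prescriptions$em_id == em, ]
    w_start <- min(segs$start_date)
    w_end <- max(segs$end_date)
    for (d in as.list(seq(w_start, w_end, by = "day"))) {
      hit <- segs[segs$start_date <= d & segs$end_date >= d, ]
      stopifnot(nrow(hit) == 1)
      obs <- 0L
      if (nrow(events)) {
        for (i in seq_len(nrow(events))) {
          if (events$patient_id[i] == pid && events$em_id[i] == em &&
                day_of(events$timestamp[i]) == d) {
            obs <- obs + 1L
          }
        }
      }
      if (curiosity_policy == "subtract" && !is.null(reports)) {
        cr <- reports[reports$report_type == "curiosity" &
                        reports$patient_id == pid & reports$em_id == em, ]
        for (i in seq_len(nrow(cr))) {
          if (cr$start_date[i] <= d && cr$end_date[i] >= d) {
            obs <- max(0L, obs - cr$count[i])
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, em_id = em, date = d,
        expected_prescribed = hit$expected_openings_per_day,
        expected_onlabel = hit$label_openings_per_day,
        segment_type = hit$segment_type,
        observed_openings = obs, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$patient_id, tab$em_id, tab$date), ]
  tab$pocket_dose_credit <- 0L
  if (!is.null(reports)) {
    pk <- reports[reports$report_type == "pocket_dose", ]
    for (i in seq_len(nrow(pk))) {
      allowed <- 0L
      if (!is.null(pill_counts)) {
        pc <- pill_counts[pill_counts$patient_id == pk$patient_id[i] &
                            pill_counts$em_id == pk$em_id[i] &
                            pill_counts$period_start <= pk$end_date[i] &
                            pill_counts$period_end >= pk$start_date[i], ]
        for (j in seq_len(nrow(pc))) {
          openings <- 0L
          for (r in seq_len(nrow(tab))) {
            if (tab$patient_id[r] == pc$patient_id[j] &&
                  tab$em_id[r] == pc$em_id[j] &&
                  tab$date[r] >= pc$period_start[j] &&
                  tab$date[r] <= pc$period_end[j]) {
              openings <- openings + tab$observed_openings[r]
            }
          }
          tpo <- if ("tablets_per_opening" %in% names(pc)) pc$tablets_per_opening[j] else 1L
          allowed <- allowed +
            max(0L, floor((pc$dispensed[j] - pc$returned[j]) / tpo) - openings)
        }
      }
      credited <- 0L
      for (r in seq_len(nrow(tab))) {
        if (credited >= min(pk$count[i], allowed)) break
        if (tab$patient_id[r] == pk$patient_id[i] &&
              tab$em_id[r] == pk$em_id[i] &&
              tab$date[r] >= pk$start_date[i] &&
              tab$date[r] <= pk$end_date[i] &&
              tab$observed_openings[r] + tab$pocket_dose_credit[r] <
                tab$expected_prescribed[r]) {
          tab$pocket_dose_credit[r] <- tab$pocket_dose_credit[r] + 1L
          credited <- credited + 1L
        }
      }
    }
  }
  tab$monitored <- TRUE
  if (!is.null(reports)) {
    nm <- reports[reports$report_type == "nonmonitored", ]
    for (i in seq_len(nrow(nm))) {
      for (r in seq_len(nrow(tab))) {
        if (tab$patient_id[r] == nm$patient_id[i] &&
              tab$em_id[r] == nm$em_id[i] &&
              tab$date[r] >= nm$start_date[i] &&
              tab$date[r] <= nm$end_date[i]) {
          tab$monitored[r] <- FALSE
        }
      }
    }
  }
  tibble::as_tibble(tab)
}
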