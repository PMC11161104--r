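# Synthetic two-arm cohort generator. Produces raw EM event logs,
# prescription histories, patient reports, pill counts, questionnaire
# responses and baseline covariates with the statistical structure the
# analysis assumes, plus a ground-truth object the pipeline never consumes.

#' Simulate a synthetic electronic-monitoring cohort
#'
#' Generates a complete two-arm cohort under a [cohort_config()]: daily
#' intake is a Bernoulli draw from a logistic trajectory with a
#' patient-level random intercept (which induces within-patient
#' autocorrelation); discontinuation and censoring are competing daily
#' hazards per arm; oncologist-prescribed transient interruptions arrive
#' per monitor with log-normal durations; a configurable share of patients
#' is on a cyclic (21/7) regimen or carries a second monitor; pocket doses,
#' curiosity checks and nonmonitored periods are injected and reported
#' exactly; pill counts are consistent with consumption. With the same
#' config and seed the output is identical.
#'
#' @param config a [cohort_config()].
#' @param seed random seed (default: `config$seed`).
#' @return a list of tibbles — `patients`, `events`, `prescriptions`,
#'   `reports`, `pill_counts`, `questionnaires` — and `truth`, the latent
#'   ground truth (never consumed by the analysis pipeline).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  cfg <- config
  validate_cohort_config(cfg)
  set.seed(seed)
  n <- as.integer(cfg$n_patients)
  tz <- cfg$timing$tz

  ## ---- patients ------------------------------------------------------
  n_int <- round(n * cfg$allocation)
  arm_assigned <- sample(c(rep("intervention", n_int),
                           rep("control", n - n_int)))
  rand_day_planned <- ifelse(
    runif(n) < cfg$randomize_at_inclusion_prob, 0L, as.integer(cfg$baseline_days)
  )
  b <- rnorm(n, 0, cfg$intake$sigma_patient)

  cv <- cfg$covariates
  gender <- ifelse(runif(n) < cv$p_male, "male", "female")
  age <- pmin(pmax(round(rnorm(n, cv$age_mean, cv$age_sd)), 25), 90)
  metastasis <- runif(n) < cv$p_metastasis
  years_since_metastasis <- ifelse(
    metastasis,
    round(rlnorm(n, cv$metastasis_years_meanlog, cv$metastasis_years_sdlog), 1),
    NA_real_
  )
  days_since_pki_initiation <- pmax(
    1L, round(rlnorm(n, cv$pki_days_meanlog, cv$pki_days_sdlog))
  )
  adherence_tool <- runif(n) < cv$p_adherence_tool

  modifier <- rep(1, n)
  if (!is.null(cfg$effect_modifiers)) {
    covs <- list(gender = gender, metastasis = metastasis,
                 adherence_tool = adherence_tool)
    for (nm in names(cfg$effect_modifiers)) {
      lv <- as.character(covs[[nm]])
      mult <- cfg$effect_modifiers[[nm]][lv]
      mult[is.na(mult)] <- 1
      modifier <- modifier * as.numeric(mult)
    }
  }

  draw_geom <- function(h) {
    out <- rep(Inf, n)
    pos <- h > 0
    if (any(pos)) out[pos] <- rgeom(sum(pos), h[pos]) + 1
    out
  }
  ev_h <- cfg$discontinuation$event_hazard[arm_assigned]
  cs_h <- cfg$discontinuation$censor_hazard[arm_assigned]
  event_day <- draw_geom(ev_h)
  censor_day <- draw_geom(cs_h)
  exit_day <- pmin(event_day, censor_day, cfg$horizon_days)
  exit_type <- dplyr::case_when(
    exit_day == cfg$horizon_days & event_day > exit_day & censor_day > exit_day ~ "completed",
    event_day <= censor_day ~ sample(
      c("discontinuation_adverse_event", "discontinuation_personal"),
      n, replace = TRUE, prob = c(0.6, 0.4)
    ),
    TRUE ~ sample(c("cessation_clinical", "study_exit"),
                  n, replace = TRUE, prob = c(0.8, 0.2))
  )
  exit_day <- as.integer(exit_day)
  randomized <- exit_day > rand_day_planned
  randomization_day <- ifelse(randomized, rand_day_planned, NA_integer_)
  arm <- ifelse(randomized, arm_assigned, NA_character_)
  inclusion_date <- as.Date("2019-01-01") + sample.int(540, n, replace = TRUE)

  patient_id <- sprintf("P%04d", seq_len(n))
  patients <- tibble(
    patient_id, inclusion_date,
    arm, randomized, randomization_day = as.integer(randomization_day),
    gender, age, metastasis, years_since_metastasis,
    days_since_pki_initiation, adherence_tool,
    exit_day, exit_type
  )

  ## ---- monitors ------------------------------------------------------
  n_mon <- 1L + (runif(n) < cfg$regimen$multi_monitor_prob)
  cyclic <- runif(n) < cfg$regimen$cyclic_prob
  monitors <- tibble(
    patient_id = rep(patient_id, n_mon),
    em_index = unlist(lapply(n_mon, seq_len)),
    exit_day = rep(exit_day, n_mon),
    inclusion_date = rep(inclusion_date, n_mon),
    cyclic = rep(cyclic, n_mon) & unlist(lapply(n_mon, seq_len)) == 1L
  ) %>%
    mutate(
      em_id = paste0(.data$patient_id, "-EM", .data$em_index),
      base_openings = 1L + (runif(dplyr::n()) < cfg$regimen$two_daily_prob),
      dose_change = !.data$cyclic &
        runif(dplyr::n()) < cfg$regimen$dose_change_prob &
        .data$exit_day > 60L,
      change_day = ifelse(
        .data$dose_change,
        30L + floor(runif(dplyr::n()) * pmax(1, .data$exit_day - 60L)),
        NA_integer_
      )
    )

  ## ---- interruption episodes (per monitor) ---------------------------
  irp <- cfg$interruption
  interruptions <- purrr::map_dfr(seq_len(nrow(monitors)), function(i) {
    m <- monitors[i, ]
    if (irp$hazard <= 0 || m$exit_day <= irp$onset_day) return(NULL)
    days <- seq.int(irp$onset_day, m$exit_day - 1L)
    starts <- days[runif(length(days)) < irp$hazard]
    if (!length(starts)) return(NULL)
    durs <- pmax(1L, round(rlnorm(length(starts), irp$duration_meanlog,
                                  irp$duration_sdlog)))
    keep_start <- integer(0)
    keep_end <- integer(0)
    busy_until <- -1L
    for (j in seq_along(starts)) {
      if (starts[j] > busy_until) {
        e <- min(starts[j] + durs[j] - 1L, m$exit_day - 1L)
        keep_start <- c(keep_start, starts[j])
        keep_end <- c(keep_end, e)
        busy_until <- e + 1L  # at least one dosing day between episodes
      }
    }
    tibble(patient_id = m$patient_id, em_id = m$em_id,
           start_day = keep_start, end_day = keep_end)
  })
  if (nrow(interruptions)) {
    interruptions <- interruptions %>%
      mutate(duration = .data$end_day - .data$start_day + 1L)
  } else {
    interruptions <- tibble(patient_id = character(), em_id = character(),
                            start_day = integer(), end_day = integer(),
                            duration = integer())
  }

  ## ---- monitor-day grid ----------------------------------------------
  grid <- monitors %>%
    mutate(n_days = .data$exit_day) %>%
    tidyr::uncount(.data$n_days, .id = ".d") %>%
    mutate(day = .data$.d - 1L) %>%
    select("patient_id", "em_id", "inclusion_date", "cyclic",
           "base_openings", "dose_change", "change_day", "day")

  cyc_len <- cfg$regimen$cycle_on + cfg$regimen$cycle_off
  grid <- grid %>%
    mutate(
      openings_t = ifelse(
        !is.na(.data$change_day) & .data$day >= .data$change_day,
        ifelse(.data$base_openings == 1L, 2L, 1L), .data$base_openings
      ),
      off = .data$cyclic & (.data$day %% cyc_len) >= cfg$regimen$cycle_on
    )

  if (nrow(interruptions)) {
    int_days <- interruptions %>%
      mutate(n_days = .data$duration) %>%
      tidyr::uncount(.data$n_days, .id = ".d") %>%
      mutate(day = .data$start_day + .data$.d - 1L, interrupted = TRUE) %>%
      select("em_id", "day", "interrupted")
    grid <- grid %>%
      left_join(int_days, by = c("em_id", "day")) %>%
      mutate(interrupted = dplyr::coalesce(.data$interrupted, FALSE))
  } else {
    grid$interrupted <- FALSE
  }

  grid <- grid %>%
    mutate(
      expected_prescribed = dplyr::case_when(
        .data$off ~ 0L, .data$interrupted ~ 0L, TRUE ~ .data$openings_t
      ),
      expected_onlabel = if_else(.data$off, 0L, .data$openings_t),
      segment_type = dplyr::case_when(
        .data$off ~ "cycle_off",
        .data$interrupted ~ "interruption",
        .data$cyclic ~ "cycle_on",
        TRUE ~ "regular"
      )
    )

  ## ---- daily intake (patient level) ----------------------------------
  tp <- trajectory_params(cfg)
  pd <- tibble(
    patient_id = rep(patient_id, exit_day),
    day = unlist(lapply(exit_day, function(k) seq_len(k) - 1L))
  ) %>%
    left_join(
      tibble(patient_id, arm, randomization_day = patients$randomization_day,
             b, modifier),
      by = "patient_id"
    )
  ti <- exposure_days(pd$day, pd$arm, pd$randomization_day)
  if (tp$perfect) {
    pd$intake <- TRUE
    pd$p_latent <- 1
  } else {
    lF <- tp$m0 + tp$m1 * pd$day + tp$m2 * pd$modifier * ti
    pi_tot <- zero_expectation_fraction(cfg, pd$day)
    p_marg <- pmin(1 - 1e-9, pmax(1e-9, (plogis(lF) - pi_tot) / (1 - pi_tot)))
    cond <- conditional_logit_fun(cfg$intake$sigma_patient)
    eta <- cond(qlogis(p_marg))
    pd$p_latent <- plogis(eta + pd$b)
    pd$intake <- runif(nrow(pd)) < pd$p_latent
  }

  ## ---- nonmonitored periods (patient level) --------------------------
  dv <- cfg$deviations
  nonmonitored <- purrr::map_dfr(seq_len(n), function(i) {
    k <- rpois(1, dv$nonmonitored_rate)
    if (k == 0 || exit_day[i] < dv$nonmonitored_min + 2) return(NULL)
    out <- NULL
    taken <- rep(FALSE, exit_day[i])
    for (j in seq_len(k)) {
      dur <- sample(dv$nonmonitored_min:dv$nonmonitored_max, 1)
      if (exit_day[i] - dur < 2) next
      s <- sample.int(exit_day[i] - dur, 1)  # start day >= 1
      idx <- s:(s + dur - 1L)
      if (any(taken[idx + 1L])) next
      taken[idx + 1L] <- TRUE
      out <- bind_rows(out, tibble(
        patient_id = patient_id[i], start_day = s, end_day = s + dur - 1L
      ))
    }
    out
  })
  if (is.null(nonmonitored) || !nrow(nonmonitored)) {
    nonmonitored <- tibble(patient_id = character(),
                           start_day = integer(), end_day = integer())
  }
  nm_days <- nonmonitored %>%
    mutate(n_days = .data$end_day - .data$start_day + 1L) %>%
    tidyr::uncount(.data$n_days, .id = ".d") %>%
    mutate(day = .data$start_day + .data$.d - 1L, nonmon = TRUE) %>%
    select("patient_id", "day", "nonmon")
  pd <- pd %>%
    left_join(nm_days, by = c("patient_id", "day")) %>%
    mutate(nonmon = dplyr::coalesce(.data$nonmon, FALSE))

  ## ---- merge monitor grid with patient-day intake --------------------
  grid <- grid %>%
    left_join(pd %>% select("patient_id", "day", "intake", "nonmon"),
              by = c("patient_id", "day"))

  ## ---- pocket-dose episodes (first monitor) --------------------------
  first_em <- monitors %>% filter(.data$em_index == 1L) %>%
    select("patient_id", "em_id")
  g1 <- grid %>%
    semi_join(first_em, by = c("patient_id", "em_id")) %>%
    arrange(.data$patient_id, .data$day)
  pocket <- purrr::map_dfr(seq_len(n), function(i) {
    k <- rpois(1, dv$pocket_rate)
    if (k == 0) return(NULL)
    pid <- patient_id[i]
    gi <- g1 %>% filter(.data$patient_id == .env$pid)
    ok <- gi$intake & gi$expected_prescribed > 0L & !gi$nonmon & gi$day >= 1L
    out <- NULL
    used <- rep(FALSE, nrow(gi))
    for (j in seq_len(k)) {
      len <- sample.int(dv$pocket_max_days, 1)
      cand <- which(ok & !used)
      cand <- cand[cand + len - 1L <= nrow(gi)]
      cand <- cand[vapply(cand, function(s) {
        all(ok[s:(s + len - 1L)]) && !any(used[s:(s + len - 1L)]) &&
          !used[max(1L, s - 1L)]
      }, logical(1))]
      if (!length(cand)) next
      s <- sample(cand, 1)
      used[s:(s + len - 1L)] <- TRUE
      out <- bind_rows(out, tibble(
        patient_id = patient_id[i], em_id = gi$em_id[1],
        start_day = gi$day[s], end_day = gi$day[s + len - 1L], count = len
      ))
    }
    out
  })
  if (is.null(pocket) || !nrow(pocket)) {
    pocket <- tibble(patient_id = character(), em_id = character(),
                     start_day = integer(), end_day = integer(),
                     count = integer())
  }
  pk_days <- pocket %>%
    mutate(n_days = .data$count) %>%
    tidyr::uncount(.data$n_days, .id = ".d") %>%
    mutate(day = .data$start_day + .data$.d - 1L, pocket_day = TRUE) %>%
    select("em_id", "day", "pocket_day")
  grid <- grid %>%
    left_join(pk_days, by = c("em_id", "day")) %>%
    mutate(pocket_day = dplyr::coalesce(.data$pocket_day, FALSE))

  ## ---- curiosity checks (first monitor) ------------------------------
  curiosity <- purrr::map_dfr(seq_len(n), function(i) {
    k <- rpois(1, dv$curiosity_rate)
    if (k == 0) return(NULL)
    pid <- patient_id[i]
    gi <- g1 %>% filter(.data$patient_id == .env$pid, !.data$nonmon)
    if (!nrow(gi)) return(NULL)
    rows <- sample.int(nrow(gi), min(k, nrow(gi)))
    tibble(patient_id = patient_id[i], em_id = gi$em_id[1],
           day = gi$day[rows], count = 1L)
  })
  if (is.null(curiosity) || !nrow(curiosity)) {
    curiosity <- tibble(patient_id = character(), em_id = character(),
                        day = integer(), count = integer())
  }

  ## ---- events --------------------------------------------------------
  grid <- grid %>%
    left_join(curiosity %>% select("em_id", "day", curiosity = "count"),
              by = c("em_id", "day")) %>%
    mutate(
      curiosity = dplyr::coalesce(.data$curiosity, 0L),
      n_open = if_else(
        !.data$nonmon & .data$intake & .data$expected_prescribed > 0L &
          !.data$pocket_day,
        .data$expected_prescribed, 0L
      ) + if_else(.data$nonmon, 0L, .data$curiosity)
    )

  ev <- grid %>%
    filter(.data$n_open > 0L) %>%
    select("patient_id", "em_id", "inclusion_date", "day", "n_open") %>%
    tidyr::uncount(.data$n_open)
  early <- runif(nrow(ev)) < cfg$timing$early_fraction
  hour <- ifelse(
    early,
    runif(nrow(ev), 0, 3) + 24,
    runif(nrow(ev), cfg$timing$window_start, cfg$timing$window_end)
  )
  midnight <- lubridate::force_tz(
    lubridate::as_datetime(ev$inclusion_date + ev$day), tzone = tz
  )
  events <- ev %>%
    mutate(timestamp = midnight + lubridate::dseconds(round(hour * 3600))) %>%
    select("patient_id", "em_id", "timestamp") %>%
    arrange(.data$patient_id, .data$em_id, .data$timestamp)

  ## ---- prescriptions (run-length compression of the day grid) --------
  prescriptions <- grid %>%
    arrange(.data$patient_id, .data$em_id, .data$day) %>%
    group_by(.data$patient_id, .data$em_id) %>%
    mutate(
      chg = .data$day == min(.data$day) |
        .data$expected_prescribed != lag(.data$expected_prescribed) |
        .data$expected_onlabel != lag(.data$expected_onlabel) |
        .data$segment_type != lag(.data$segment_type),
      seg = cumsum(.data$chg)
    ) %>%
    group_by(.data$patient_id, .data$em_id, .data$seg) %>%
    summarise(
      start_date = min(.data$inclusion_date + .data$day),
      end_date = max(.data$inclusion_date + .data$day),
      expected_openings_per_day = .data$expected_prescribed[1],
      segment_type = .data$segment_type[1],
      label_openings_per_day = .data$expected_onlabel[1],
      .groups = "drop"
    ) %>%
    mutate(reason = if_else(
      .data$segment_type == "interruption",
      sample(c("clinical", "administrative", "patient_request"),
             dplyr::n(), replace = TRUE, prob = c(0.7, 0.15, 0.15)),
      NA_character_
    )) %>%
    select(-"seg")

  ## ---- reports -------------------------------------------------------
  incl <- setNames(inclusion_date, patient_id)
  reports <- bind_rows(
    pocket %>% mutate(report_type = "pocket_dose"),
    nonmonitored %>%
      left_join(first_em, by = "patient_id") %>%
      mutate(report_type = "nonmonitored", count = NA_integer_),
    curiosity %>% mutate(report_type = "curiosity",
                         start_day = .data$day, end_day = .data$day) %>%
      select(-"day")
  ) %>%
    mutate(
      start_date = incl[.data$patient_id] + .data$start_day,
      end_date = incl[.data$patient_id] + .data$end_day
    ) %>%
    select("patient_id", "em_id", "report_type", "start_date", "end_date",
           "count")
  # nonmonitored periods silence every monitor of the patient
  multi <- monitors %>% filter(.data$em_index == 2L) %>%
    select("patient_id", em2 = "em_id")
  nm2 <- reports %>%
    filter(.data$report_type == "nonmonitored") %>%
    inner_join(multi, by = "patient_id") %>%
    mutate(em_id = .data$em2) %>%
    select(-"em2")
  reports <- bind_rows(reports, nm2) %>%
    arrange(.data$patient_id, .data$start_date)

  ## ---- pill counts ---------------------------------------------------
  pill_counts <- grid %>%
    mutate(period = .data$day %/% 28L) %>%
    group_by(.data$patient_id, .data$em_id, .data$period) %>%
    summarise(
      period_start = min(.data$inclusion_date + .data$day),
      period_end = max(.data$inclusion_date + .data$day),
      dispensed = sum(.data$expected_prescribed) + 2L,
      consumed = sum(.data$expected_prescribed *
                       as.integer(.data$intake & !.data$nonmon)),
      .groups = "drop"
    ) %>%
    mutate(returned = .data$dispensed - .data$consumed,
           tablets_per_opening = 1L) %>%
    select("patient_id", "em_id", "period_start", "period_end",
           "dispensed", "returned", "tablets_per_opening")

  ## ---- questionnaires ------------------------------------------------
  questionnaires <- simulate_questionnaires(cfg, patients)

  truth <- list(
    patients = patients %>%
      mutate(arm_assigned = arm_assigned, b = b, modifier = modifier,
             cyclic = cyclic, n_monitors = n_mon),
    interruptions = interruptions,
    pocket_episodes = pocket,
    nonmonitored_episodes = nonmonitored,
    curiosity_checks = curiosity,
    calibration = list(
      m0 = tp$m0, m1 = tp$m1, m2 = tp$m2,
      sigma_patient = cfg$intake$sigma_patient,
      perfect = tp$perfect
    ),
    latent_mean_by_day = pd %>%
      group_by(.data$day) %>%
      summarise(mean_p_latent = mean(.data$p_latent), .groups = "drop"),
    seed = seed
  )

  list(
    patients = patients,
    events = events,
    prescriptions = prescriptions,
    reports = reports,
    pill_counts = pill_counts,
    questionnaires = questionnaires,
    truth = truth
  )
}

simulate_questionnaires <- function(cfg, patients) {
  qcfg <- cfg$questionnaires
  bmq <- bmq_items()
  qlq <- qlq_c30_items()
  n <- nrow(patients)
  waves <- purrr::map_dfr(c(0, 6, 12), function(w) {
    present <- switch(as.character(w),
      "0" = rep(TRUE, n),
      "6" = patients$exit_day > 180,
      "12" = patients$exit_day >= cfg$horizon_days
    )
    responds <- present &
      (w == 0 | runif(n) >= qcfg$nonresponse_prob)
    tibble(patient_id = patients$patient_id[responds], wave = w)
  })
  if (!nrow(waves)) {
    return(tibble(patient_id = character(), wave = numeric(),
                  instrument = character(), item_id = character(),
                  response = integer()))
  }

  bmq_rows <- purrr::map_dfr(unique(bmq$scale), function(sc) {
    it <- bmq$item_id[bmq$scale == sc]
    k <- length(it)
    pars <- qcfg$bmq[[sc]]
    scored <- matrix(
      pmin(5L, pmax(1L, round(rnorm(nrow(waves) * k, pars["mean"] / k,
                                    pars["sd"] / sqrt(k))))),
      nrow = nrow(waves)
    )
    tibble(
      patient_id = rep(waves$patient_id, k),
      wave = rep(waves$wave, k),
      instrument = "BMQ",
      item_id = rep(it, each = nrow(waves)),
      response = as.integer(6L - as.vector(scored))
    )
  })

  qlq_scales <- qlq %>% distinct(.data$scale, .data$scale_type)
  qlq_rows <- purrr::map_dfr(seq_len(nrow(qlq_scales)), function(j) {
    sc <- qlq_scales$scale[j]
    type <- qlq_scales$scale_type[j]
    it <- qlq$item_id[qlq$scale == sc]
    pars <- qcfg$qlq[[type]]
    target <- pmin(100, pmax(0, rnorm(nrow(waves), pars["mean"], pars["sd"])))
    rs <- switch(type,
      functional = 1 + 3 * (1 - target / 100),
      symptom = 1 + 3 * target / 100,
      global = 1 + 6 * target / 100
    )
    rmax <- if (type == "global") 7L else 4L
    resp <- matrix(
      pmin(rmax, pmax(1L, round(rnorm(nrow(waves) * length(it),
                                      rep(rs, length(it)), 0.5)))),
      nrow = nrow(waves)
    )
    tibble(
      patient_id = rep(waves$patient_id, length(it)),
      wave = rep(waves$wave, length(it)),
      instrument = "QLQC30",
      item_id = rep(it, each = nrow(waves)),
      response = as.integer(as.vector(resp))
    )
  })
  bind_rows(bmq_rows, qlq_rows) %>%
    arrange(.data$patient_id, .data$wave, .data$instrument, .data$item_id)
}

#' Derive persistence records from the patient table
#'
#' Maps each patient's study exit to the persistence outcome: a premature
#' treatment cessation for adverse events or personal/unilateral reasons is
#' an event; cessation for other clinical reasons, study exit without
#' discontinuation, or completing the monitoring period are censoring times.
#'
#' @param patients the patient table (needs `exit_day`, `exit_type`, and
#'   `randomization_day` for the randomization clock).
#' @param from `"randomization"` (default; never-randomized patients are
#'   excluded) or `"inclusion"`.
#' @return a tibble: `patient_id`, `time` (days), `status`
#'   (`"event"`/`"censored"`), `reason`, `arm`.
#' @export
persistence_records <- function(patients, from = c("randomization", "inclusion")) {
  from <- arg_match(from)
  df <- as_tibble(patients)
  if (from == "randomization") {
    df <- df %>% filter(!is.na(.data$randomization_day))
    df$time <- df$exit_day - df$randomization_day
  } else {
    df$time <- df$exit_day
  }
  df %>%
    mutate(
      status = if_else(startsWith(.data$exit_type, "discontinuation"),
                       "event", "censored"),
      reason = .data$exit_type
    ) %>%
    select("patient_id", "time", "status", "reason", dplyr::any_of("arm"))
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `patients.csv`, `events.csv` (ISO-8601 timestamps with offset),
#' `prescriptions.csv`, `reports.csv`, `pill_counts.csv`,
#' `questionnaires.csv` and `truth.json` into a directory.
#'
#' @param cohort a list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  ev <- cohort$events %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S%z"))
  w(cohort$patients, "patients.csv")
  w(ev, "events.csv")
  w(cohort$prescriptions, "prescriptions.csv")
  w(cohort$reports, "reports.csv")
  w(cohort$pill_counts, "pill_counts.csv")
  w(cohort$questionnaires, "questionnaires.csv")
  truth <- cohort$truth
  truth$patients <- as.data.frame(truth$patients)
  truth$latent_mean_by_day <- as.data.frame(truth$latent_mean_by_day)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA, Date = "ISO8601")
  invisible(dir)
}
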