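# Implementation and adherence models: cubic-time GEE with a time-dependent
# intervention-exposure covariate, representative-patient predictions at 6
# months, and the one-covariable-at-a-time subgroup analysis.

# Build the model frame used by both models. Time is rescaled internally by
# its maximum so that predictions are invariant to affine rescaling of the
# day axis supplied by the caller.
gee_frame <- function(df, time, degree, group_effect) {
  t_raw <- df[[time]]
  s <- max(t_raw, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) s <- 1
  ts <- t_raw / s
  X <- cbind(1, outer(ts, seq_len(degree), `^`))
  colnames(X) <- c("(Intercept)", paste0("time^", seq_len(degree)))
  if (group_effect) {
    X <- cbind(X, time_in_intervention = df$.ti / s)
  }
  list(X = X, time_scale = s)
}

# Time spent in the intervention arm up to day t (inclusion clock): accrues
# from each patient's own randomization day, and is 0 for control and
# never-randomized patients.
exposure_days <- function(day, arm, randomization_day) {
  ti <- ifelse(
    !is.na(arm) & arm == "intervention" & !is.na(randomization_day),
    pmax(0, day - randomization_day),
    0
  )
  as.numeric(ti)
}

#' Fit the longitudinal implementation GEE
#'
#' Describes daily medication intake (0/1) from inclusion over the
#' monitoring window with a GEE: logit link, polynomial time effect
#' (default degree 3) and an autoregressive working correlation. The
#' intervention is a time-dependent exposure: the covariate is the time
#' spent in the intervention arm up to day *t*, which accrues from each
#' patient's randomization day and stays 0 for control and never-randomized
#' patients. Time spent in control is implicit (it equals *t* minus time in
#' intervention for every patient, so including both alongside a linear time
#' term would be collinear); the exposure coefficient is therefore the
#' per-day log-odds effect of a day in intervention relative to a day in
#' control.
#'
#' @param outcomes a daily-outcome tibble from [daily_outcome()], carrying
#'   `arm` and `randomization_day` covariables. Missing (nonmonitored) days
#'   are dropped.
#' @param degree degree of the time polynomial (default 3).
#' @param corstr working correlation (default `"ar1"`).
#' @param time the day-clock column (default `"day_index"`).
#' @param group_effect set `FALSE` to fit the whole-sample model with no
#'   group variable (used for the prescribed-vs-on-label comparison).
#' @param window_days restrict to days `<= window_days` (default 365).
#' @return an `em_gee` fit, augmented with the model card entries needed for
#'   prediction (`time_scale`, `degree`, `clock`, the analysis data).
#' @export
fit_implementation_gee <- function(outcomes, degree = 3, corstr = "ar1",
                                   time = "day_index", group_effect = TRUE,
                                   window_days = 365) {
  df <- outcomes %>%
    filter(!is.na(.data$value), .data[[time]] <= window_days) %>%
    arrange(.data$patient_id, .data[[time]])
  if (dplyr::n_distinct(df$patient_id) < 2) {
    stop_data("need at least 2 patients with observed days to fit the GEE")
  }
  if (group_effect) {
    if (!all(c("arm", "randomization_day") %in% names(df))) {
      stop_data("outcomes must carry `arm` and `randomization_day` covariables")
    }
    df$.ti <- exposure_days(df[[time]], df$arm, df$randomization_day)
  }
  fr <- gee_frame(df, time, degree, group_effect)
  fit <- gee_binary(fr$X, df$value, df$patient_id, corstr = corstr)
  fit$time_scale <- fr$time_scale
  fit$degree <- degree
  fit$group_effect <- group_effect
  fit$time <- time
  fit$data <- df
  fit
}

rep_design <- function(fit, day, ti_days) {
  s <- fit$time_scale
  x <- c(1, (day / s)^seq_len(fit$degree))
  if (fit$group_effect) x <- c(x, ti_days / s)
  x
}

#' Representative-patient predictions and the between-group difference
#'
#' Converts a fitted implementation (or adherence) GEE into the probability
#' of correct intake at a given day for two representative patients: one who
#' switched to the intervention at `randomization_day` (time in intervention
#' = `day - randomization_day`) and one who stayed in control (time in
#' intervention = 0). The difference is reported on the probability scale
#' with a 95% CI, by the delta method on the two linear predictors using the
#' robust covariance, or by a seeded bootstrap over patients.
#'
#' @param fit an `em_gee` from [fit_implementation_gee()] /
#'   [fit_adherence_gee()].
#' @param day prediction day (default 180, i.e. 6 months).
#' @param randomization_day day the representative intervention patient
#'   entered the intervention (default 21, the baseline length; use 0 on the
#'   randomization clock).
#' @param level confidence level.
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param B bootstrap resamples (default 500).
#' @param seed seed for the bootstrap resampling.
#' @return a one-row tibble: `day`, `p_intervention`, `p_control`, `delta`,
#'   `conf_low`, `conf_high` (CI of the difference), `se`, `ci_method`.
#' @export
predict_representative <- function(fit, day = 180, randomization_day = 21,
                                   level = 0.95, ci_method = c("delta", "bootstrap"),
                                   B = 500, seed = NULL) {
  ci_method <- arg_match(ci_method)
  if (!fit$group_effect) {
    stop_data("fit has no group effect; use predict_day() for the whole-sample model")
  }
  max_day <- fit$time_scale
  if (day > max_day) {
    warn(glue::glue("day {day} lies beyond the observed range ({max_day}): extrapolating"),
         class = "emadhere_extrapolation_warning")
  }
  x_int <- rep_design(fit, day, ti_days = day - randomization_day)
  x_ctl <- rep_design(fit, day, ti_days = 0)
  beta <- fit$coefficients
  p_int <- plogis(sum(x_int * beta))
  p_ctl <- plogis(sum(x_ctl * beta))
  delta <- p_int - p_ctl
  z <- qnorm(1 - (1 - level) / 2)

  if (ci_method == "delta") {
    grad <- p_int * (1 - p_int) * x_int - p_ctl * (1 - p_ctl) * x_ctl
    se <- sqrt(drop(t(grad) %*% fit$vcov_robust %*% grad))
    lo <- delta - z * se
    hi <- delta + z * se
  } else {
    if (is.null(fit$data)) stop_data("bootstrap CI needs the analysis data in the fit")
    if (!is.null(seed)) set.seed(seed)
    ids <- unique(fit$data$patient_id)
    boot <- purrr::map_dbl(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      dfb <- purrr::map_dfr(seq_along(take), function(i) {
        fit$data %>% filter(.data$patient_id == take[i]) %>%
          mutate(patient_id = paste0("b", i))
      })
      fb <- tryCatch({
        fr <- gee_frame(dfb, fit$time, fit$degree, TRUE)
        f <- gee_binary(fr$X, dfb$value, dfb$patient_id, corstr = fit$corstr)
        f$time_scale <- fr$time_scale
        f$degree <- fit$degree
        f$group_effect <- TRUE
        plogis(sum(rep_design(f, day, day - randomization_day) * f$coefficients)) -
          plogis(sum(rep_design(f, day, 0) * f$coefficients))
      }, error = function(e) NA_real_)
      fb
    })
    boot <- boot[is.finite(boot)]
    se <- sd(boot)
    qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  tibble(
    day = day, p_intervention = p_int, p_control = p_ctl,
    delta = delta, conf_low = lo, conf_high = hi, se = se,
    ci_method = ci_method
  )
}

#' Whole-sample prediction from a no-group GEE
#'
#' For the prescribed-vs-on-label comparison the model is fitted on the
#' whole sample without group variables; this returns the fitted probability
#' at a given day with a delta-method CI from the robust covariance.
#'
#' @param fit an `em_gee` fitted with `group_effect = FALSE`.
#' @param day prediction day.
#' @param level confidence level.
#' @return a one-row tibble: `day`, `estimate`, `conf_low`, `conf_high`.
#' @export
predict_day <- function(fit, day = 180, level = 0.95) {
  x <- rep_design(fit, day, ti_days = 0)
  p <- plogis(sum(x * fit$coefficients))
  grad <- p * (1 - p) * x
  se <- sqrt(drop(t(grad) %*% fit$vcov_robust %*% grad))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    day = day, estimate = p,
    conf_low = plogis(qlogis(p) - z * se / (p * (1 - p))),
    conf_high = plogis(qlogis(p) + z * se / (p * (1 - p)))
  )
}

#' One-covariable-at-a-time subgroup analysis
#'
#' Refits the implementation GEE separately in each stratum of a single
#' covariable (the exploratory analysis behind the per-subgroup estimate
#' table). Continuous covariables are dichotomized at the cohort median
#' (strata labelled `<= m` / `> m`); categorical covariables use their
#' levels. Strata with fewer than 2 patients, or where the fit is degenerate,
#' are marked inestimable.
#'
#' @param outcomes daily outcomes with the covariable joined per patient.
#' @param covariable name of the covariable column.
#' @param cut optional dichotomization cut for a continuous covariable
#'   (default: cohort median across patients).
#' @param day,randomization_day prediction day and representative
#'   randomization day, as in [predict_representative()].
#' @param ... passed to [fit_implementation_gee()].
#' @return a tibble with one row per stratum: `covariable`, `stratum`,
#'   `n_patients`, the representative predictions and difference, and an
#'   `estimable` flag.
#' @export
subgroup_analysis <- function(outcomes, covariable, cut = NULL, day = 180,
                              randomization_day = 21, ...) {
  if (!covariable %in% names(outcomes)) {
    stop_data(glue::glue("covariable `{covariable}` not found in the outcomes"))
  }
  per_patient <- outcomes %>%
    distinct(.data$patient_id, cov_value = .data[[covariable]])
  x <- per_patient$cov_value
  if (is.numeric(x)) {
    if (is.null(cut)) cut <- median(x, na.rm = TRUE)
    stratum <- ifelse(x <= cut, paste0("<= ", cut), paste0("> ", cut))
  } else {
    stratum <- as.character(x)
  }
  per_patient$stratum <- stratum
  strata <- sort(unique(stratum[!is.na(stratum)]))

  purrr::map_dfr(strata, function(st) {
    ids <- per_patient$patient_id[!is.na(per_patient$stratum) &
                                    per_patient$stratum == st]
    sub <- outcomes %>% filter(.data$patient_id %in% ids)
    base <- tibble(
      covariable = covariable, stratum = st, n_patients = length(ids)
    )
    if (length(ids) < 2) {
      return(base %>% mutate(estimable = FALSE))
    }
    res <- tryCatch({
      fit <- fit_implementation_gee(sub, ...)
      pred <- predict_representative(fit, day = day,
                                     randomization_day = randomization_day)
      dplyr::bind_cols(base, pred %>% select(-"ci_method")) %>%
        mutate(estimable = TRUE)
    }, error = function(e) base %>% mutate(estimable = FALSE))
    res
  })
}

#' Fit the adherence GEE on the randomization clock
#'
#' Adherence combines implementation and persistence: the clock starts at
#' each patient's randomization day (the baseline period is excluded), runs
#' over a fixed window (default 340 days), days after a discontinuation
#' event are counted as incorrect intake (0), and days after a censoring
#' time are missing. The same GEE structure as the implementation model is
#' then fitted on this outcome.
#'
#' @param outcomes daily outcomes (inclusion clock) with `arm` and
#'   `randomization_day` covariables.
#' @param records persistence records (`patient_id`, `time` measured from
#'   randomization, `status`).
#' @param window_days randomization-clock window (default 340).
#' @param degree,corstr model settings as in [fit_implementation_gee()].
#' @return an `em_gee` fit on the randomization clock; predict with
#'   [predict_representative()] using `randomization_day = 0`.
#' @export
fit_adherence_gee <- function(outcomes, records, window_days = 340,
                              degree = 3, corstr = "ar1") {
  rc <- randomization_clock(outcomes, window_days = window_days)
  records <- as_tibble(records)
  status <- records$status
  if (!is.numeric(status)) status <- as.integer(status == "event")
  rec <- records
  rec$.status <- as.integer(status)
  rec <- rec %>% select("patient_id", "time", ".status")

  rc <- rc %>% left_join(rec, by = "patient_id")
  # beyond a censoring time the outcome is missing
  rc <- rc %>%
    filter(!(.data$.status == 0L & .data$day_rand > .data$time))
  # after a discontinuation event the outcome is 0 through the window;
  # extend the grid where monitoring stopped at the event
  ev <- rc %>%
    filter(.data$.status == 1L) %>%
    distinct(.data$patient_id, .data$time, .data$arm, .data$randomization_day)
  if (nrow(ev)) {
    pad <- ev %>%
      mutate(n_days = pmax(0L, as.integer(window_days - floor(.data$time)))) %>%
      filter(.data$n_days > 0L) %>%
      tidyr::uncount(.data$n_days, .id = ".off") %>%
      mutate(day_rand = as.integer(floor(.data$time)) + .data$.off,
             value = 0L) %>%
      select("patient_id", "day_rand", "value", "arm", "randomization_day") %>%
      dplyr::anti_join(rc, by = c("patient_id", "day_rand"))
    rc <- bind_rows(
      rc %>% mutate(value = if_else(.data$.status == 1L & .data$day_rand > .data$time,
                                    0L, .data$value)),
      pad
    )
  }
  # on the randomization clock, time in intervention accrues from day 0
  rc <- rc %>%
    mutate(randomization_day = 0) %>%
    arrange(.data$patient_id, .data$day_rand)
  fit_implementation_gee(
    rc, degree = degree, corstr = corstr, time = "day_rand",
    window_days = window_days
  )
}
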