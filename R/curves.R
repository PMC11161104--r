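# Outcome curves: empirical implementation, Kaplan-Meier persistence and
# composite adherence. All three are returned as "adherence_curve" tibbles:
# one row per day with the point estimate, pointwise 95% bounds and the
# denominator (patients at risk / under observation).

new_curve <- function(df, curve, convention = NA_character_) {
  out <- df %>% mutate(curve = curve, convention = convention) %>%
    select("curve", "convention", "day", "estimate", "lo", "hi", "n")
  class(out) <- c("adherence_curve", class(out))
  out
}

#' Empirical implementation curve
#'
#' On each day, the proportion of patients with correct intake among the
#' patients still under observation with a non-missing outcome that day
#' (nonmonitored days are excluded from the denominator). Pointwise 95%
#' bounds are Wilson score intervals.
#'
#' @param outcomes a daily-outcome tibble from [daily_outcome()].
#' @param time column name holding the day clock (default `"day_index"`,
#'   days since inclusion).
#' @return an `adherence_curve` tibble: `curve`, `convention`, `day`,
#'   `estimate`, `lo`, `hi`, `n` (denominator). Days with denominator 0 are
#'   undefined points and omitted.
#' @export
empirical_implementation <- function(outcomes, time = "day_index") {
  conv <- unique(outcomes$convention)
  conv <- if (length(conv) == 1) conv else NA_character_
  df <- outcomes %>%
    filter(!is.na(.data$value)) %>%
    group_by(day = .data[[time]]) %>%
    summarise(x = sum(.data$value), n = dplyr::n(), .groups = "drop") %>%
    mutate(estimate = .data$x / .data$n)
  ci <- wilson_ci(df$x, df$n)
  df <- df %>% mutate(lo = ci$lo, hi = ci$hi) %>% select(-"x")
  new_curve(df, curve = "implementation", convention = conv)
}

#' Kaplan-Meier persistence curve
#'
#' Persistence is the time from the start of observation to premature
#' treatment cessation. A discontinuation for adverse events or for patient
#' personal/unilateral reasons is an event; cessation for other clinical
#' reasons (progression, asymptomatic toxicity) or study exit without
#' discontinuation is a censoring time. The product-limit estimate with
#' Greenwood-based 95% bounds is computed by [survival::survfit()].
#'
#' @param records one row per patient: `patient_id`, `time` (days), `status`
#'   (`"event"`/`"censored"`, or 1/0).
#' @param day_grid optional integer vector of days at which to evaluate the
#'   curve; default: days 0..max(time).
#' @return an `adherence_curve` tibble (curve `"persistence"`).
#' @export
km_persistence <- function(records, day_grid = NULL) {
  records <- as_tibble(records)
  if (any(records$time < 0)) stop_data("negative persistence times")
  status <- records$status
  if (!is.numeric(status)) status <- as.integer(status == "event")
  fit <- survival::survfit(
    survival::Surv(records$time, status) ~ 1, conf.type = "log"
  )
  if (is.null(day_grid)) day_grid <- 0:max(records$time)
  sm <- summary(fit, times = day_grid, extend = TRUE)
  df <- tibble(
    day = sm$time, estimate = sm$surv,
    lo = dplyr::coalesce(sm$lower, sm$surv),
    hi = dplyr::coalesce(sm$upper, sm$surv),
    n = sm$n.risk
  )
  new_curve(df, curve = "persistence")
}

#' Composite adherence curve
#'
#' Adherence on day *t* is the proportion of patients with correct intake
#' among **all** patients initially included, i.e. also counting those who
#' already discontinued. The primary estimate is the product form
#' A(t) = I(t) x S(t), implementation times Kaplan-Meier persistence; a
#' secondary purely empirical variant counts discontinued patients as 0 and
#' keeps them in the denominator, excluding censored patients after their
#' censoring day. Both are returned.
#'
#' Product-form bounds combine the two pointwise variances on the log scale
#' (first-order delta method, treating I and S as independent).
#'
#' @param outcomes daily outcomes on the same clock as `records` (for the
#'   randomization-clock analysis, supply outcomes re-indexed from each
#'   patient's randomization day).
#' @param records persistence records for the same cohort (see
#'   [km_persistence()]).
#' @param time column of `outcomes` holding the day clock.
#' @return a list with `product` and `empirical`, both `adherence_curve`
#'   tibbles (curve `"adherence"`).
#' @export
empirical_adherence <- function(outcomes, records, time = "day_index") {
  extra <- setdiff(unique(records$patient_id), unique(outcomes$patient_id))
  if (length(extra)) {
    stop_data("persistence records refer to patients absent from the outcomes")
  }
  impl <- empirical_implementation(outcomes, time = time)
  km <- km_persistence(records, day_grid = sort(unique(impl$day)))

  prod_df <- impl %>%
    as_tibble() %>%
    select("day", i = "estimate", i_lo = "lo", i_hi = "hi", "n") %>%
    inner_join(
      km %>% as_tibble() %>% select("day", s = "estimate", s_lo = "lo", s_hi = "hi"),
      by = "day"
    ) %>%
    mutate(
      estimate = .data$i * .data$s,
      # combine relative half-widths on the log scale
      rel = sqrt(
        (log(pmax(.data$i_hi, 1e-12)) - log(pmax(.data$i_lo, 1e-12)))^2 +
          (log(pmax(.data$s_hi, 1e-12)) - log(pmax(.data$s_lo, 1e-12)))^2
      ) / 2,
      lo = pmax(0, .data$estimate * exp(-.data$rel)),
      hi = pmin(1, .data$estimate * exp(.data$rel))
    ) %>%
    select("day", "estimate", "lo", "hi", "n")

  status <- records$status
  if (!is.numeric(status)) status <- as.integer(status == "event")
  rec <- as_tibble(records)
  rec$.status <- as.integer(status)
  emp_df <- outcomes %>%
    left_join(rec %>% select("patient_id", "time", ".status"),
              by = "patient_id", suffix = c("", ".rec")) %>%
    mutate(
      day = .data[[time]],
      v = case_when(
        .data$day > .data$time & .data$.status == 1L ~ 0L,   # discontinued: counted as 0
        .data$day > .data$time & .data$.status == 0L ~ NA_integer_,  # censored: excluded
        TRUE ~ .data$value
      )
    ) %>%
    filter(!is.na(.data$v)) %>%
    group_by(.data$day) %>%
    summarise(x = sum(.data$v), n = dplyr::n(), .groups = "drop") %>%
    mutate(estimate = .data$x / .data$n)
  ci <- wilson_ci(emp_df$x, emp_df$n)
  emp_df <- emp_df %>% mutate(lo = ci$lo, hi = ci$hi) %>% select(-"x")

  conv <- unique(outcomes$convention)
  conv <- if (length(conv) == 1) conv else NA_character_
  list(
    product = new_curve(prod_df, curve = "adherence", convention = conv),
    empirical = new_curve(emp_df, curve = "adherence_empirical", convention = conv)
  )
}

#' Re-index daily outcomes onto the randomization clock
#'
#' The adherence analysis starts the clock at each patient's randomization
#' day and runs over a fixed window (default 340 days, roughly 12 months
#' minus the 21-day baseline). Pre-randomization days are dropped;
#' never-randomized patients contribute nothing.
#'
#' @param outcomes daily outcomes (needs a `randomization_day` covariable).
#' @param window_days length of the randomization-clock window.
#' @return the outcomes with `day_rand = day_index - randomization_day`,
#'   restricted to `0 <= day_rand <= window_days`.
#' @export
randomization_clock <- function(outcomes, window_days = 340) {
  outcomes %>%
    filter(!is.na(.data$randomization_day)) %>%
    mutate(day_rand = .data$day_index - .data$randomization_day) %>%
    filter(.data$day_rand >= 0, .data$day_rand <= window_days)
}

#' @export
autoplot.adherence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Day", y = "Probability",
      title = unique(object$curve)
    ) +
    ggplot2::theme_minimal()
}
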