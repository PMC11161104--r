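# Internal helpers shared across the pipeline.

#' Assign an EM timestamp to a monitoring day
#'
#' The electronic monitor's day runs from 03:00 to 02:59 the next morning, so
#' an opening recorded at, say, 01:30 on calendar date D belongs to the
#' monitoring day D - 1. Timestamps are interpreted in the study's local
#' civil time before the boundary is applied, which also makes daylight-saving
#' transitions (02:00-03:00) safe.
#'
#' @param ts a POSIXct vector (any timezone; converted to `tz`).
#' @param tz local civil timezone of the study site.
#' @return a `Date` vector: the monitoring day each timestamp belongs to.
#' @export
#' @examples
#' em_day(as.POSIXct("2020-05-10 01:30:00", tz = "Europe/Zurich"))
#' # -> "2020-05-09": before 03:00, so the previous monitoring day
em_day <- function(ts, tz = "Europe/Zurich") {
  if (!inherits(ts, "POSIXct")) {
    abort("`ts` must be a POSIXct vector.", class = "emadhere_data_error")
  }
  local <- lubridate::with_tz(ts, tzone = tz)
  # compare local clock time, not a fixed 3-hour offset: on the
  # spring-forward night (02:00 -> 03:00) the monitoring day still starts at
  # 03:00 on the local clock even though it is only 23 hours long
  lubridate::as_date(local) - (lubridate::hour(local) < 3)
}

# Wilson score interval for a binomial proportion; returns a list(lo, hi).
# Used for the pointwise bands of empirical curves.
wilson_ci <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lo = pmax(0, centre - half), hi = pmin(1, centre + half))
}

# Stop with a data-validation error, consistent class for tests.
stop_data <- function(msg) abort(msg, class = "emadhere_data_error")
stop_config <- function(msg) abort(msg, class = "emadhere_config_error")

# Check a scalar probability field of a config, naming the field on failure.
check_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_config(glue::glue("`{field}` must be a probability in [0, 1]."))
  }
  invisible(x)
}

check_pos <- function(x, field, strict = FALSE) {
  bad <- !is.numeric(x) || any(is.na(x)) || any(if (strict) x <= 0 else x < 0)
  if (bad) {
    stop_config(glue::glue(
      "`{field}` must be {if (strict) 'positive' else 'non-negative'}."
    ))
  }
  invisible(x)
}
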