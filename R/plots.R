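# Publication-shaped figures: model trajectories over empirical daily
# proportions, and the dual-convention comparison.

#' Plot the fitted implementation model over the empirical curve
#'
#' Shows the GEE-fitted implementation trajectory for a representative
#' patient randomized to the intervention at day 21 and a representative
#' control patient, over the empirical day-by-day implementation of the
#' whole sample, with the number of patients under observation as a rug of
#' text below.
#'
#' @param fit an `em_gee` from [fit_implementation_gee()].
#' @param outcomes the daily outcomes the model was fitted on.
#' @param randomization_day representative randomization day (default 21).
#' @param prediction_day day marked with a vertical reference line.
#' @return a ggplot object.
#' @export
plot_implementation_fit <- function(fit, outcomes, randomization_day = 21,
                                    prediction_day = 180) {
  emp <- empirical_implementation(outcomes)
  days <- sort(unique(emp$day))
  traj <- purrr::map_dfr(days, function(d) {
    x_int <- rep_design(fit, d, ti_days = max(0, d - randomization_day))
    x_ctl <- rep_design(fit, d, ti_days = 0)
    tibble(
      day = d,
      intervention = plogis(sum(x_int * fit$coefficients)),
      control = plogis(sum(x_ctl * fit$coefficients))
    )
  }) %>%
    tidyr::pivot_longer(c("intervention", "control"),
                        names_to = "arm", values_to = "p")
  ggplot2::ggplot() +
    ggplot2::geom_step(
      data = as_tibble(emp),
      ggplot2::aes(x = .data$day, y = .data$estimate),
      colour = "grey30", linewidth = 0.3
    ) +
    ggplot2::geom_line(
      data = traj,
      ggplot2::aes(x = .data$day, y = .data$p, colour = .data$arm),
      linewidth = 0.9
    ) +
    ggplot2::geom_vline(xintercept = prediction_day, linetype = 3) +
    ggplot2::scale_colour_manual(
      values = c(intervention = "#c0392b", control = "#2980b9")
    ) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "Days since inclusion",
                  y = "Probability of correct intake",
                  colour = NULL,
                  title = "Daily implementation: model over empirical") +
    ggplot2::theme_minimal()
}

#' Plot implementation under both regimen conventions
#'
#' Overlays the empirical implementation curves computed against the
#' oncologist-prescribed regimen (interruptions count as expected = 0) and
#' against the manufacturer's on-label regimen, quantifying how much
#' implementation would be underestimated if prescribed interruptions were
#' ignored.
#'
#' @param curves a curve table containing `curve == "implementation"` rows
#'   for both conventions (e.g. the `curves` element of [run_pipeline()]'s
#'   result).
#' @return a ggplot object.
#' @export
plot_dual_convention <- function(curves) {
  df <- curves %>%
    filter(.data$curve == "implementation",
           .data$convention %in% c("prescribed", "onlabel"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$estimate,
                                   colour = .data$convention)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(prescribed = "black", onlabel = "#c0392b")
    ) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "Days since inclusion",
                  y = "Proportion with correct intake",
                  colour = "Convention",
                  title = "Implementation: prescribed vs on-label regimen") +
    ggplot2::theme_minimal()
}
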