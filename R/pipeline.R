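# End-to-end pipeline: simulate -> clean -> estimate -> model -> score ->
# report, with every stage reading from and writing to plain-text artifacts
# so that tables and figures are regenerated solely from on-disk files.

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the raw CSV files.
#' @param tz timezone for event timestamps.
#' @return a list of tibbles (`patients`, `events`, `prescriptions`,
#'   `reports`, `pill_counts`, `questionnaires`).
#' @export
read_cohort <- function(dir, tz = "Europe/Zurich") {
  rd <- function(name) {
    as_tibble(utils::read.csv(file.path(dir, name), stringsAsFactors = FALSE))
  }
  patients <- rd("patients.csv") %>%
    mutate(inclusion_date = lubridate::as_date(.data$inclusion_date),
           arm = dplyr::na_if(.data$arm, ""))
  events <- rd("events.csv") %>%
    mutate(timestamp = lubridate::with_tz(
      lubridate::ymd_hms(.data$timestamp, tz = "UTC"), tzone = tz
    ))
  prescriptions <- rd("prescriptions.csv") %>%
    mutate(start_date = lubridate::as_date(.data$start_date),
           end_date = lubridate::as_date(.data$end_date))
  reports <- rd("reports.csv") %>%
    mutate(start_date = lubridate::as_date(.data$start_date),
           end_date = lubridate::as_date(.data$end_date))
  pill_counts <- rd("pill_counts.csv") %>%
    mutate(period_start = lubridate::as_date(.data$period_start),
           period_end = lubridate::as_date(.data$period_end))
  questionnaires <- rd("questionnaires.csv")
  list(patients = patients, events = events, prescriptions = prescriptions,
       reports = reports, pill_counts = pill_counts,
       questionnaires = questionnaires)
}

#' Run the full adherence analysis pipeline
#'
#' Orchestrates the whole analysis on a synthetic cohort: generate the raw
#' files, build the adherence table, compute daily outcomes under both
#' conventions, estimate the implementation / persistence / adherence
#' curves, fit the GEE models (group model, whole-sample dual-convention
#' models, adherence model and the one-at-a-time subgroup analysis), score
#' the questionnaires, and write every table plus a reproducibility
#' manifest (seed, package version, config hash) into `out_dir`. Rerunning
#' with the same config and seed reproduces the artifacts bit-identically.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param seed seed (default `config$seed`).
#' @param prediction_day day of the representative predictions (default 180).
#' @param subgroups named list of covariables for the subgroup analysis;
#'   values give the dichotomization cut for continuous covariables (NULL =
#'   categorical or median). Default: the trial's set (age at 60 years, time
#'   since PKI initiation at 60 days, time since metastatic diagnosis at 2
#'   years, gender, metastasis, prior adherence-tool use).
#' @param figures write ggplot figures (PNG) alongside the tables.
#' @return invisibly, a list with the main in-memory results (`curves`,
#'   `predictions`, `fit`, `manifest`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = config$seed,
                         prediction_day = 180,
                         subgroups = list(gender = NULL, age = 60,
                                          days_since_pki_initiation = 60,
                                          metastasis = NULL,
                                          years_since_metastasis = 2,
                                          adherence_tool = NULL),
                         figures = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(glue::glue("pipeline stage `{name}` failed: {conditionMessage(e)}"),
            class = "emadhere_pipeline_error", parent = e)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  raw_dir <- file.path(out_dir, "raw")
  tz <- config$timing$tz

  ## simulate
  cohort <- stage("simulate", {
    ch <- simulate_cohort(config, seed = seed)
    write_cohort(ch, raw_dir)
    ch
  })

  ## clean (from the on-disk raw files)
  table <- stage("clean", {
    raw <- read_cohort(raw_dir, tz = tz)
    tab <- suppressWarnings(build_adherence_table(
      raw$events, raw$prescriptions, raw$reports, raw$pill_counts,
      raw$patients, tz = tz
    ))
    utils::write.csv(tab, file.path(out_dir, "adherence_table.csv"),
                     row.names = FALSE, na = "")
    qc <- attr(tab, "qc")
    qc$flagged_events <- NULL
    jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    tab
  })

  ## estimate
  est <- stage("estimate", {
    out_p <- daily_outcome(table, "prescribed")
    out_l <- daily_outcome(table, "onlabel")
    rec <- persistence_records(cohort$patients, from = "randomization")
    curves <- bind_rows(
      empirical_implementation(out_p),
      empirical_implementation(out_l),
      km_persistence(rec %>% select("patient_id", "time", "status")),
      empirical_adherence(
        randomization_clock(out_p) %>% rename(day_incl = "day_index"),
        rec, time = "day_rand"
      )$product
    )
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(rec, file.path(out_dir, "persistence.csv"),
                     row.names = FALSE, na = "")
    list(out_p = out_p, out_l = out_l, rec = rec, curves = curves)
  })

  ## model
  mod <- stage("model", {
    degenerate <- FALSE
    fit <- tryCatch(
      fit_implementation_gee(est$out_p),
      emadhere_degenerate_error = function(e) {
        degenerate <<- TRUE
        NULL
      }
    )
    if (degenerate) {
      # all outcomes identical: no finite GEE estimate exists; report the
      # constant implementation without fitting
      const <- mean(est$out_p$value, na.rm = TRUE)
      main <- tibble(
        day = prediction_day, p_intervention = const, p_control = const,
        delta = 0, conf_low = 0, conf_high = 0, se = 0,
        ci_method = "degenerate",
        covariable = "randomization_groups", stratum = "all"
      )
      global <- tibble(
        day = prediction_day,
        estimate = c(const, mean(est$out_l$value, na.rm = TRUE)),
        conf_low = NA_real_, conf_high = NA_real_,
        convention = c("prescribed", "onlabel")
      )
      subs <- NULL
      adh <- NULL
    } else {
      main <- predict_representative(fit, day = prediction_day) %>%
        mutate(covariable = "randomization_groups", stratum = "all")
      fit_p <- fit_implementation_gee(est$out_p, group_effect = FALSE)
      fit_l <- fit_implementation_gee(est$out_l, group_effect = FALSE)
      global <- bind_rows(
        predict_day(fit_p, prediction_day) %>%
          mutate(convention = "prescribed"),
        predict_day(fit_l, prediction_day) %>%
          mutate(convention = "onlabel")
      )
      subs <- purrr::imap_dfr(subgroups, function(cut, covariable) {
        subgroup_analysis(est$out_p, covariable, cut = cut,
                          day = prediction_day)
      })
      adh_fit <- tryCatch(
        fit_adherence_gee(est$out_p, est$rec),
        error = function(e) NULL
      )
      adh <- if (!is.null(adh_fit)) {
        predict_representative(adh_fit, day = prediction_day,
                               randomization_day = 0) %>%
          mutate(covariable = "adherence_since_randomization", stratum = "all")
      } else NULL
    }
    predictions <- bind_rows(main, subs, adh)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(global, file.path(out_dir, "global_implementation.csv"),
                     row.names = FALSE, na = "")
    card <- if (degenerate) {
      list(degenerate = TRUE, prediction_day = prediction_day,
           conventions = c("prescribed", "onlabel"))
    } else {
      c(
        glance(fit) %>% as.list(),
        list(degree = fit$degree, prediction_day = prediction_day,
             conventions = c("prescribed", "onlabel"))
      )
    }
    jsonlite::write_json(card, file.path(out_dir, "model_card.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, predictions = predictions, global = global)
  })

  ## score
  stage("score", {
    q <- cohort$questionnaires
    scores <- bind_rows(
      score_bmq(q) %>% mutate(scale_type = NA_character_),
      score_qlq(q)
    )
    grp <- cohort$patients %>%
      filter(!is.na(.data$arm)) %>%
      select("patient_id", group = "arm")
    comparisons <- compare_groups(scores, grp)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(comparisons, file.path(out_dir, "score_comparisons.csv"),
                     row.names = FALSE, na = "")
  })

  ## report
  manifest <- stage("report", {
    if (figures) {
      try_fig <- function(name, plot) {
        tryCatch(
          ggplot2::ggsave(file.path(out_dir, name), plot,
                          width = 7, height = 4.5, dpi = 150),
          error = function(e) warn(glue::glue("figure {name} not written: ",
                                              conditionMessage(e)))
        )
      }
      if (!is.null(mod$fit)) {
        try_fig("implementation_model.png",
                plot_implementation_fit(mod$fit, est$out_p,
                                        prediction_day = prediction_day))
      }
      try_fig("dual_convention.png",
              plot_dual_convention(est$curves))
      try_fig("persistence_km.png",
              autoplot(km_persistence(
                est$rec %>% select("patient_id", "time", "status")
              )))
    }
    manifest <- list(
      package_version = as.character(packageVersion("emadhere")),
      r_version = as.character(getRversion()),
      seed = seed,
      config_hash = rlang::hash(unclass(config)),
      created = "run_pipeline",
      n_patients = config$n_patients,
      horizon_days = config$horizon_days
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  })

  invisible(list(curves = est$curves, predictions = mod$predictions,
                 global = mod$global, fit = mod$fit, manifest = manifest))
}
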