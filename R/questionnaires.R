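# Patient-reported outcome scoring: Beliefs about Medicines Questionnaire
# (BMQ) and the EORTC QLQ-C30 quality-of-life instrument, plus the Welch
# between-group comparison.

#' Default BMQ item map
#'
#' The BMQ has 18 items rated 1 "Strongly agree" to 5 "Strongly disagree",
#' grouped into perceived necessity (5 items), concerns (5), overprescribing
#' (4) and prejudices (4). Subscale scores add the reverse scores
#' (6 - raw) of the items, so higher scores mean stronger beliefs; the
#' admissible ranges are 5-25 for the 5-item scales and 4-20 for the 4-item
#' scales. The exact reverse-scoring direction per item is
#' instrument-defined; the shipped map reverses all items and is editable
#' (`system.file("extdata", "bmq_items.csv", package = "emadhere")`) —
#' verify against the instrument manual before scoring real data.
#'
#' @return a tibble: `scale`, `item_id`, `reverse`, `scale_min`, `scale_max`.
#' @export
bmq_items <- function() {
  path <- system.file("extdata", "bmq_items.csv", package = "emadhere")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default EORTC QLQ-C30 item map
#'
#' The standard scale structure of the 30-item instrument: five functional
#' scales (15 items), nine symptom scales (13 items) and the 2-item global
#' health status. Functional and symptom items are rated 1-4, global items
#' 1-7. Editable copy in
#' `system.file("extdata", "qlq_c30_items.csv", package = "emadhere")`.
#'
#' @return a tibble: `scale`, `scale_type`, `item_id`.
#' @export
qlq_c30_items <- function() {
  path <- system.file("extdata", "qlq_c30_items.csv", package = "emadhere")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Score the Beliefs about Medicines Questionnaire
#'
#' Each subscale is the sum of the reverse scores (6 - raw) of its items.
#' As a sum-based score it does not tolerate missing items: with the default
#' `missing_policy = "strict"`, any missing item makes the subscale missing.
#'
#' @param responses a tibble with `patient_id`, `wave`, `item_id`,
#'   `response` (integers 1-5; `NA` allowed). If an `instrument` column is
#'   present, rows with `instrument == "BMQ"` are used.
#' @param items item map (default [bmq_items()]).
#' @param missing_policy `"strict"` (any missing item voids the subscale) or
#'   `"prorate"` (mean of available items times the item count, needs at
#'   least half the items).
#' @return a tibble: `patient_id`, `wave`, `scale`, `score`, `scale_min`,
#'   `scale_max`.
#' @export
score_bmq <- function(responses, items = bmq_items(),
                      missing_policy = c("strict", "prorate")) {
  missing_policy <- arg_match(missing_policy)
  responses <- as_tibble(responses)
  if ("instrument" %in% names(responses)) {
    responses <- filter(responses, .data$instrument == "BMQ")
  }
  responses <- semi_join(responses, items, by = "item_id")
  bad <- responses %>%
    filter(!is.na(.data$response) & (.data$response < 1 | .data$response > 5))
  if (nrow(bad)) {
    stop_data(glue::glue(
      "BMQ response out of the 1-5 range for item(s) ",
      "{toString(head(unique(bad$item_id), 5))}"
    ))
  }
  responses %>%
    inner_join(items, by = "item_id") %>%
    mutate(scored = if_else(.data$reverse, 6 - .data$response, .data$response)) %>%
    group_by(.data$patient_id, .data$wave, .data$scale,
             .data$scale_min, .data$scale_max) %>%
    summarise(
      n_items = dplyr::n(),
      n_missing = sum(is.na(.data$scored)),
      total = sum(.data$scored),
      prorated = mean(.data$scored, na.rm = TRUE) * dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      score = dplyr::case_when(
        missing_policy == "strict" & .data$n_missing > 0 ~ NA_real_,
        missing_policy == "prorate" & .data$n_missing > .data$n_items / 2 ~ NA_real_,
        missing_policy == "prorate" ~ .data$prorated,
        TRUE ~ .data$total
      )
    ) %>%
    select("patient_id", "wave", "scale", "score", "scale_min", "scale_max")
}

#' Score the EORTC QLQ-C30
#'
#' For each scale, the raw score RS is the mean of the available item
#' responses, linearly transformed to 0-100: functional scales
#' S = (1 - (RS - 1) / 3) x 100, symptom scales S = ((RS - 1) / 3) x 100,
#' global health status S = ((RS - 1) / 6) x 100. High functional and global
#' scores indicate healthy functioning / high quality of life; high symptom
#' scores indicate high symptomatology. The mean-based raw score tolerates
#' missing items (a scale is scored if at least half its items are present,
#' the instrument's usual rule).
#'
#' @param responses a tibble with `patient_id`, `wave`, `item_id`,
#'   `response` (1-4, global items 1-7). If an `instrument` column is
#'   present, rows with `instrument == "QLQC30"` are used.
#' @param items item map (default [qlq_c30_items()]).
#' @return a tibble: `patient_id`, `wave`, `scale`, `scale_type`, `score`,
#'   `scale_min` (0), `scale_max` (100).
#' @export
score_qlq <- function(responses, items = qlq_c30_items()) {
  responses <- as_tibble(responses)
  if ("instrument" %in% names(responses)) {
    responses <- filter(responses, .data$instrument == "QLQC30")
  }
  responses <- semi_join(responses, items, by = "item_id")
  joined <- responses %>% inner_join(items, by = "item_id")
  max_resp <- if_else(joined$scale_type == "global", 7, 4)
  bad <- joined[!is.na(joined$response) &
                  (joined$response < 1 | joined$response > max_resp), ]
  if (nrow(bad)) {
    stop_data(glue::glue(
      "QLQ-C30 response out of range for item(s) ",
      "{toString(head(unique(bad$item_id), 5))}"
    ))
  }
  joined %>%
    group_by(.data$patient_id, .data$wave, .data$scale, .data$scale_type) %>%
    summarise(
      n_items = dplyr::n(),
      n_avail = sum(!is.na(.data$response)),
      rs = mean(.data$response, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      rs = if_else(.data$n_avail * 2 >= .data$n_items & .data$n_avail > 0,
                   .data$rs, NA_real_),
      score = dplyr::case_when(
        .data$scale_type == "functional" ~ (1 - (.data$rs - 1) / 3) * 100,
        .data$scale_type == "symptom" ~ ((.data$rs - 1) / 3) * 100,
        .data$scale_type == "global" ~ ((.data$rs - 1) / 6) * 100
      ),
      scale_min = 0, scale_max = 100
    ) %>%
    select("patient_id", "wave", "scale", "scale_type", "score",
           "scale_min", "scale_max")
}

#' Compare questionnaire scores between groups with Welch's t test
#'
#' Two-sided Welch (unequal-variance) t tests per scale and wave, with
#' Welch-Satterthwaite degrees of freedom. Group sizes, means, SDs and
#' missing counts are reported; a comparison with fewer than 2 non-missing
#' scores in either group is marked inestimable rather than raising an
#' error.
#'
#' @param scores scored scales from [score_bmq()] / [score_qlq()].
#' @param groups per-patient grouping: `patient_id` and `group` (two
#'   levels).
#' @return a tibble with one row per (scale, wave): group summaries,
#'   `statistic`, `df`, `p.value`, `estimable`.
#' @export
compare_groups <- function(scores, groups) {
  groups <- as_tibble(groups)
  lv <- sort(unique(as.character(groups$group)))
  if (length(lv) != 2) stop_data("`groups` must define exactly two groups")
  df <- scores %>% inner_join(groups, by = "patient_id")

  df %>%
    group_by(.data$scale, .data$wave) %>%
    dplyr::group_modify(function(d, key) {
      x <- d$score[d$group == lv[1]]
      y <- d$score[d$group == lv[2]]
      xs <- x[!is.na(x)]
      ys <- y[!is.na(y)]
      base <- tibble(
        group1 = lv[1], group2 = lv[2],
        n1 = length(xs), n2 = length(ys),
        missing1 = sum(is.na(x)), missing2 = sum(is.na(y)),
        mean1 = if (length(xs)) mean(xs) else NA_real_,
        sd1 = if (length(xs) > 1) sd(xs) else NA_real_,
        mean2 = if (length(ys)) mean(ys) else NA_real_,
        sd2 = if (length(ys) > 1) sd(ys) else NA_real_
      )
      if (length(xs) < 2 || length(ys) < 2 ||
            (sd(xs) == 0 && sd(ys) == 0)) {
        if (length(xs) >= 2 && length(ys) >= 2 &&
              isTRUE(all.equal(mean(xs), mean(ys)))) {
          # identical degenerate groups: no evidence of a difference
          return(base %>% mutate(statistic = 0, df = NA_real_, p.value = 1,
                                 estimable = TRUE))
        }
        return(base %>% mutate(statistic = NA_real_, df = NA_real_,
                               p.value = NA_real_, estimable = FALSE))
      }
      tt <- t.test(xs, ys, var.equal = FALSE)
      base %>% mutate(
        statistic = unname(tt$statistic),
        df = unname(tt$parameter),
        p.value = tt$p.value,
        estimable = TRUE
      )
    }) %>%
    ungroup()
}
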