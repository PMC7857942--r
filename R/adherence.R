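# Survey completion and adherence. A survey instance counts as completed
# when at least 75% of its items were answered; adherence at a wave is
# reported two ways, as the proportion of eligible participants completing
# at least one survey and the proportion completing every scheduled survey,
# both over the same fixed post-exclusion denominator.

#' Completion of a single survey instance
#'
#' @param responses Vector of item values for one instance, `NA` = skipped.
#' @param threshold Completion threshold as a fraction of items answered
#'   (default 0.75, inclusive).
#' @return `TRUE` iff `answered / total >= threshold`.
#' @export
#' @examples
#' is_complete(c(1, 2, NA, 3))        # 3/4 = 75%, TRUE
#' is_complete(c(rep(1, 14), rep(NA, 6))) # 14/20, FALSE
is_complete <- function(responses, threshold = 0.75) {
  if (length(responses) == 0) {
    abort("Cannot assess completion of a zero-item instrument.",
          class = "ecohortr_data_error")
  }
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1].", class = "ecohortr_config_error")
  }
  sum(!is.na(responses)) / length(responses) >= threshold
}

#' Per-instance completion status
#'
#' Counts answered items per survey instance against the instrument's item
#' count and applies the completion threshold.
#'
#' @param responses Long item-response tibble (`participant_id`,
#'   `instance_id`, `item_index`, `value`).
#' @param assignments Wave assignments from [assign_waves()] (provides each
#'   instance's `survey_type` and `wave`).
#' @param instruments Instrument table, default [survey_instruments()].
#' @param threshold Completion threshold, default 0.75.
#' @return A tibble `participant_id, instance_id, survey_type, wave,
#'   n_answered, n_items, complete`.
#' @export
completion_status <- function(responses, assignments,
                              instruments = survey_instruments(),
                              threshold = 0.75) {
  answered <- responses |>
    dplyr::summarise(n_answered = sum(!is.na(.data$value)), .by = "instance_id")
  assignments |>
    dplyr::left_join(answered, by = "instance_id") |>
    dplyr::inner_join(dplyr::select(instruments, "survey_type", "n_items"),
                      by = "survey_type") |>
    dplyr::mutate(
      n_answered = dplyr::coalesce(.data$n_answered, 0L),
      complete = .data$n_answered / .data$n_items >= threshold
    ) |>
    dplyr::select("participant_id", "instance_id", "survey_type", "wave",
                  "n_answered", "n_items", "complete")
}

#' Adherence: at least one completed survey per wave
#'
#' Per wave, the numerator is the number of eligible participants with at
#' least one completed survey assigned to that wave; the denominator is the
#' full eligible participant count (constant across waves, and including
#' participants who returned nothing).
#'
#' @param completions Completion table from [completion_status()].
#' @param eligible_participants Eligible participant tibble (column `id`),
#'   from [apply_eligibility()].
#' @return A tibble `wave, n_any, denominator, p_any, pct_any` (percent
#'   rounded half-up to 2 decimals).
#' @export
adherence_any <- function(completions, eligible_participants) {
  denom <- nrow(eligible_participants)
  counts <- completions |>
    dplyr::filter(.data$complete,
                  .data$wave %in% wave_levels(),
                  .data$participant_id %in% eligible_participants$id) |>
    dplyr::distinct(.data$participant_id, .data$wave) |>
    dplyr::count(.data$wave, name = "n_any")
  tibble::tibble(wave = wave_levels()) |>
    dplyr::left_join(counts, by = "wave") |>
    dplyr::mutate(
      n_any = dplyr::coalesce(.data$n_any, 0L),
      denominator = denom,
      p_any = if (denom > 0) .data$n_any / denom else NA_real_,
      pct_any = round_half_up(100 * .data$p_any, 2)
    )
}

#' Adherence: all scheduled surveys completed per wave
#'
#' Per wave, the numerator counts eligible participants who completed every
#' survey type scheduled at that wave; the denominator matches
#' [adherence_any()].
#'
#' @inheritParams adherence_any
#' @param schedule Deployment schedule tibble (`survey_type`, `wave`).
#' @return A tibble `wave, n_all, denominator, p_all, pct_all`.
#' @export
adherence_all <- function(completions, schedule, eligible_participants) {
  missing_waves <- setdiff(wave_levels(), unique(schedule$wave))
  if (length(missing_waves)) {
    abort(sprintf("Schedule lacks waves: %s", paste(missing_waves, collapse = ", ")),
          class = "ecohortr_config_error")
  }
  denom <- nrow(eligible_participants)
  n_sched <- dplyr::count(schedule, .data$wave, name = "n_scheduled")
  counts <- completions |>
    dplyr::filter(.data$complete,
                  .data$participant_id %in% eligible_participants$id) |>
    dplyr::semi_join(schedule, by = c("survey_type", "wave")) |>
    dplyr::distinct(.data$participant_id, .data$wave, .data$survey_type) |>
    dplyr::count(.data$participant_id, .data$wave, name = "n_done") |>
    dplyr::inner_join(n_sched, by = "wave") |>
    dplyr::filter(.data$n_done == .data$n_scheduled) |>
    dplyr::count(.data$wave, name = "n_all")
  tibble::tibble(wave = wave_levels()) |>
    dplyr::left_join(counts, by = "wave") |>
    dplyr::mutate(
      n_all = dplyr::coalesce(.data$n_all, 0L),
      denominator = denom,
      p_all = if (denom > 0) .data$n_all / denom else NA_real_,
      pct_all = round_half_up(100 * .data$p_all, 2)
    )
}

#' Combined adherence table
#'
#' Joins [adherence_any()] and [adherence_all()] into one per-wave table.
#'
#' @inheritParams adherence_all
#' @return A tibble `wave, n_any, n_all, denominator, p_any, p_all,
#'   pct_any, pct_all`.
#' @export
survey_adherence <- function(completions, schedule, eligible_participants) {
  dplyr::inner_join(
    adherence_any(completions, eligible_participants),
    adherence_all(completions, schedule, eligible_participants),
    by = c("wave", "denominator")
  ) |>
    dplyr::select("wave", "n_any", "n_all", "denominator",
                  "p_any", "p_all", "pct_any", "pct_all")
}

# questions shown on each app step: none on the intro and thank-you steps,
# items spread as evenly as possible over the intermediate steps
questions_per_step <- function(n_items, n_steps) {
  mid <- n_steps - 2L
  if (mid < 1L) return(rep(n_items / n_steps, n_steps))
  base <- n_items %/% mid
  rem <- n_items %% mid
  c(0L, base + as.integer(seq_len(mid) <= rem), 0L)
}

#' Survey timing metrics
#'
#' Per survey type and wave: survey return time (deployment to return, days),
#' touch time (start to return, minutes), step time (per app step, seconds)
#' and per-question time (step time divided by the questions on that step,
#' seconds), each summarised as median and quartiles (linear interpolation,
#' type 7). Instances violating the timestamp ordering
#' `deployment <= start <= return` are dropped and logged in the `dropped`
#' attribute.
#'
#' @param survey_returns Survey-return tibble with timestamps and `step_ts`
#'   (semicolon-joined step completion times).
#' @param assignments Wave assignments from [assign_waves()].
#' @param instruments Instrument table, default [survey_instruments()].
#' @return A tibble `survey_type, wave, metric, unit, n, q1, median, q3`,
#'   with attribute `dropped` listing excluded instances.
#' @export
timing_metrics <- function(survey_returns, assignments,
                           instruments = survey_instruments()) {
  x <- survey_returns |>
    dplyr::inner_join(dplyr::select(assignments, "instance_id", "wave"),
                      by = "instance_id") |>
    dplyr::filter(.data$wave %in% wave_levels())
  bad <- dplyr::filter(x, .data$start_ts < .data$deployment_ts |
                         .data$return_ts < .data$start_ts)
  if (nrow(bad)) {
    x <- dplyr::anti_join(x, bad, by = "instance_id")
  }

  inst_long <- x |>
    dplyr::mutate(
      return_time = (.data$return_ts - .data$deployment_ts) / 86400,
      touch_time = (.data$return_ts - .data$start_ts) / 60
    )

  steps <- x |>
    dplyr::inner_join(dplyr::select(instruments, "survey_type", "n_items", "n_steps"),
                      by = "survey_type")
  step_rows <- purrr::pmap(
    list(steps$instance_id, steps$survey_type, steps$wave, steps$start_ts,
         steps$step_ts, steps$n_items, steps$n_steps),
    function(iid, type, wave, start, step_str, n_items, n_steps) {
      ts <- as.numeric(strsplit(step_str, ";", fixed = TRUE)[[1]])
      dur <- diff(c(start, ts))
      qs <- questions_per_step(n_items, length(ts))
      if (length(qs) != length(dur)) qs <- rep(n_items / length(dur), length(dur))
      tibble::tibble(
        survey_type = type, wave = wave,
        step_time = dur,
        question_time = ifelse(qs > 0, dur / qs, NA_real_)
      )
    }
  ) |> purrr::list_rbind()

  summarise_metric <- function(df, col, metric, unit) {
    df |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::summarise(
        n = dplyr::n(),
        q1 = quantile(.data[[col]], 0.25, type = 7, names = FALSE),
        median = quantile(.data[[col]], 0.5, type = 7, names = FALSE),
        q3 = quantile(.data[[col]], 0.75, type = 7, names = FALSE),
        .by = c("survey_type", "wave")
      ) |>
      dplyr::mutate(metric = metric, unit = unit, .after = "wave")
  }

  out <- dplyr::bind_rows(
    summarise_metric(inst_long, "return_time", "return_time", "days"),
    summarise_metric(inst_long, "touch_time", "touch_time", "minutes"),
    summarise_metric(step_rows, "step_time", "step_time", "seconds"),
    summarise_metric(step_rows, "question_time", "question_time", "seconds")
  ) |>
    dplyr::arrange(factor(.data$wave, levels = wave_levels()),
                   .data$survey_type, .data$metric)
  attr(out, "dropped") <- dplyr::select(bad, "instance_id")
  out
}
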