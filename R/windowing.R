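# Time-window assignment: every returned survey is mapped to one of five
# contiguous 90-day windows from the participant's registration date, or
# excluded beyond the last window. Day indices are whole elapsed days
# (floored), and every boundary is inclusive, so "0 to 89 days" means day
# index in {0, ..., 89}.

#' Day ranges defining the five protocol waves
#'
#' @return A tibble with columns `wave`, `day_min`, `day_max`: baseline
#'   0-89, 3 months 90-179, 6 months 180-269, 9 months 270-359, 12 months
#'   360-449. Returns later than day 449 fall outside every window.
#' @export
#' @examples
#' window_rule()
window_rule <- function() {
  tibble::tibble(
    wave = wave_levels(),
    day_min = c(0L, 90L, 180L, 270L, 360L),
    day_max = c(89L, 179L, 269L, 359L, 449L)
  )
}

#' Whole days elapsed between registration and a survey return
#'
#' @param registration_ts,return_ts Timestamps in whole seconds since epoch
#'   (vectorised).
#' @param instance_id Optional instance labels used in the error message for
#'   returns that precede registration.
#' @return Integer vector of floored elapsed days.
#' @export
#' @examples
#' days_since_registration(0, 89 * 86400 + 86399) # 89
#' days_since_registration(0, 90 * 86400)         # 90
days_since_registration <- function(registration_ts, return_ts, instance_id = NULL) {
  bad <- which(return_ts < registration_ts)
  if (length(bad)) {
    lab <- if (is.null(instance_id)) paste(bad, collapse = ", ") else
      paste(instance_id[bad], collapse = ", ")
    abort(sprintf("Return precedes registration for instance(s): %s", lab),
          class = "ecohortr_data_error")
  }
  as.integer(floor((return_ts - registration_ts) / 86400))
}

#' Assign a day index to a protocol wave
#'
#' @param days Integer vector of nonnegative day indices (floored whole days
#'   since registration).
#' @return Character vector: one of `baseline, m3, m6, m9, m12`, or
#'   `"excluded"` for days beyond 449.
#' @export
#' @examples
#' assign_window(c(0, 89, 90, 179, 449, 455))
assign_window <- function(days) {
  if (any(days < 0, na.rm = TRUE)) {
    abort("`days` must be nonnegative.", class = "ecohortr_domain_error")
  }
  rule <- window_rule()
  idx <- findInterval(days, c(rule$day_min, 450L))
  out <- c(rule$wave, "excluded")[idx]
  out[is.na(days)] <- NA_character_
  out
}

#' Assign every survey return to a protocol wave
#'
#' Joins returns to their participant's registration timestamp, computes
#' floored elapsed days, and maps each return to a wave via
#' [assign_window()].
#'
#' @param survey_returns Survey-return tibble (`participant_id`,
#'   `instance_id`, `survey_type`, `return_ts`, ...).
#' @param participants Participant tibble with `id` and `registration_ts`.
#' @return A tibble `participant_id, instance_id, survey_type, days, wave`.
#' @export
assign_waves <- function(survey_returns, participants) {
  joined <- survey_returns |>
    dplyr::inner_join(
      dplyr::select(participants, participant_id = "id", "registration_ts"),
      by = "participant_id"
    )
  joined |>
    dplyr::mutate(
      days = days_since_registration(.data$registration_ts, .data$return_ts,
                                     .data$instance_id),
      wave = assign_window(.data$days)
    ) |>
    dplyr::select("participant_id", "instance_id", "survey_type", "days", "wave")
}

#' Apply the cohort eligibility rules
#'
#' Drops, in order: (a) participants with under `min_followup_days` of
#' follow-up; then (b) among participants with any return, those whose
#' earliest return falls on day 90 or later (their first data cannot be a
#' baseline survey). Participants with no returns at all are retained — they
#' count in adherence denominators. The operation is idempotent.
#'
#' @param participants Participant tibble (enrolled participants).
#' @param assignments Wave assignments from [assign_waves()].
#' @param min_followup_days Minimum follow-up, default 365 (inclusive).
#' @return A list with `participants` (the eligible subset) and `exclusions`
#'   (tibble `participant_id, rule`, rules `short_followup` and
#'   `late_first_return`).
#' @export
apply_eligibility <- function(participants, assignments, min_followup_days = 365) {
  enrolled <- dplyr::filter(participants, .data$enrolled == 1L)
  short <- enrolled |>
    dplyr::filter(!is.na(.data$followup_days) &
                    .data$followup_days < min_followup_days)
  kept <- dplyr::anti_join(enrolled, short, by = "id")

  returned <- dplyr::filter(assignments, .data$participant_id %in% kept$id)
  first_ret <- if (nrow(returned) == 0) {
    tibble::tibble(participant_id = character(0), first_day = integer(0))
  } else {
    dplyr::summarise(returned, first_day = min(.data$days), .by = "participant_id")
  }
  late <- dplyr::filter(first_ret, .data$first_day >= 90L)
  kept <- dplyr::filter(kept, !.data$id %in% late$participant_id)

  exclusions <- dplyr::bind_rows(
    tibble::tibble(participant_id = short$id, rule = "short_followup"),
    tibble::tibble(participant_id = late$participant_id, rule = "late_first_return")
  )
  list(participants = kept, exclusions = exclusions)
}
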