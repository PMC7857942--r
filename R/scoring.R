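# Scoring of the three analysed measures, with the missing-item rules used
# in the app/clinic comparison: single-missing imputation for the activity
# index, mean-rescaling for 1-5 missing CES-D items, and the simple
# drinks-per-day x drinking-days product for weekly alcohol intake.

.score_pai <- function(hours, weights = pai_weights(), tol = 1e-6) {
  if (length(hours) != 5) {
    abort("PAI requires exactly 5 duration values.", class = "ecohortr_data_error")
  }
  if (any(hours < 0, na.rm = TRUE)) {
    abort("Activity hours must be nonnegative.", class = "ecohortr_data_error")
  }
  n_miss <- sum(is.na(hours))
  if (n_miss >= 2) {
    return(list(value = NA_real_, imputed = FALSE, n_items_missing = n_miss, issue = NA_character_))
  }
  if (n_miss == 1) {
    others <- sum(hours, na.rm = TRUE)
    if (others > 24 + tol) {
      return(list(value = NA_real_, imputed = FALSE, n_items_missing = 1L,
                  issue = "hours_exceed_24"))
    }
    hours[is.na(hours)] <- max(0, 24 - others)
    return(list(value = sum(weights * hours), imputed = TRUE, n_items_missing = 1L,
                issue = NA_character_))
  }
  list(value = sum(weights * hours), imputed = FALSE, n_items_missing = 0L,
       issue = NA_character_)
}

#' Score the Physical Activity Index
#'
#' Weighted sum of the daily hours spent in five activity intensities
#' (sleep, sedentary, slight, moderate, heavy) with weights
#' 1 / 1.1 / 1.5 / 2.4 / 5. Hours are constrained to sum to 24, so if
#' exactly one category is missing it is imputed as `max(0, 24 - sum of the
#' other four)`; with two or more missing the score is missing. If the four
#' present hours already exceed 24 (beyond a 1e-6 tolerance) the imputation
#' would be negative: the instance is flagged and the score left missing.
#'
#' @param hours Numeric vector of 5 daily hours in the order sleep,
#'   sedentary, slight, moderate, heavy; `NA` = missing.
#' @param weights Category weights, default [pai_weights()].
#' @return A one-row tibble `value, imputed, n_items_missing` (value in
#'   24-120 when present).
#' @export
#' @examples
#' score_pai(c(8, 10, 4, 1.5, 0.5))   # 31.1
#' score_pai(c(8, 10, 4, NA, 0.5))    # moderate imputed as 1.5 -> 31.1
score_pai <- function(hours, weights = pai_weights()) {
  s <- .score_pai(hours, weights)
  if (!is.na(s$issue)) {
    warn("Present hours exceed 24 with one item missing; score set to missing.")
  }
  tibble::tibble(value = s$value, imputed = s$imputed,
                 n_items_missing = s$n_items_missing)
}

.score_cesd <- function(items, reverse_coded = c(4L, 8L, 12L, 16L)) {
  if (length(items) != 20) {
    abort("CES-D requires exactly 20 items.", class = "ecohortr_data_error")
  }
  present <- !is.na(items)
  if (any(items[present] < 0 | items[present] > 3)) {
    abort("CES-D items must be integers in 0..3.", class = "ecohortr_data_error")
  }
  items[reverse_coded] <- 3 - items[reverse_coded]
  n_miss <- sum(!present)
  value <- if (n_miss == 0) {
    sum(items)
  } else if (n_miss <= 5) {
    mean(items[present]) * 20
  } else {
    NA_real_
  }
  list(value = value, flag = ifelse(is.na(value), NA_integer_, as.integer(value >= 16)),
       imputed = n_miss >= 1 && n_miss <= 5, n_items_missing = n_miss)
}

#' Score the CES-D depressive-symptoms scale
#'
#' Sum of 20 items scored 0-3, with the standard reverse-scored items mapped
#' `v -> 3 - v` before summing. Missing items: with 1-5 missing, the mean of
#' the non-missing items is multiplied by 20; with more than 5 missing the
#' score is missing. A binary depression indicator flags continuous scores
#' of 16 or more.
#'
#' @param items Numeric vector of 20 item responses in 0..3; `NA` = skipped.
#' @param reverse_coded 1-based indices of reverse-scored items. The
#'   instrument's standard positive-affect items (4, 8, 12, 16) by default;
#'   set to `integer(0)` if responses arrive already reverse-coded.
#' @return A one-row tibble `value, flag, imputed, n_items_missing`.
#' @export
#' @examples
#' score_cesd(rep(0, 20))                        # 0, flag 0
#' score_cesd(c(rep(1, 18), NA, NA))             # mean 1 x 20, but note
#'                                               # reverse coding of items 4,8,12,16
score_cesd <- function(items, reverse_coded = c(4L, 8L, 12L, 16L)) {
  s <- .score_cesd(items, reverse_coded)
  tibble::tibble(value = s$value, flag = s$flag, imputed = s$imputed,
                 n_items_missing = s$n_items_missing)
}

#' Average drinks per week
#'
#' The number of drinks consumed on a drinking day times the number of days
#' per week with any alcoholic beverage.
#'
#' @param drinks_per_day Nonnegative drinks per drinking day (vectorised).
#' @param days_per_week Integer days per week with any drink, 0..7.
#' @return Numeric vector of weekly drinks; 0 whenever `days_per_week` is 0.
#' @export
#' @examples
#' drinks_per_week(2, 3)    # 6
#' drinks_per_week(1.5, 7)  # 10.5
drinks_per_week <- function(drinks_per_day, days_per_week) {
  if (any(days_per_week > 7 | days_per_week < 0, na.rm = TRUE)) {
    abort("`days_per_week` must be in 0..7.", class = "ecohortr_data_error")
  }
  if (any(drinks_per_day < 0, na.rm = TRUE)) {
    abort("`drinks_per_day` must be nonnegative.", class = "ecohortr_data_error")
  }
  ifelse(days_per_week == 0, 0, drinks_per_day * days_per_week)
}

#' Score all analysed measures from the item-response table
#'
#' Scores physical activity, CES-D and alcohol instances and attaches each
#' score to its participant and wave. When a participant returns the same
#' survey type more than once in a wave, the instance with the earliest
#' return timestamp is scored.
#'
#' @param responses Long item-response tibble.
#' @param assignments Wave assignments from [assign_waves()].
#' @param survey_returns Survey-return tibble (for return timestamps).
#' @param reverse_coded CES-D reverse-scored item indices, as in
#'   [score_cesd()].
#' @return A tibble `participant_id, wave, measure, value, flag, imputed,
#'   n_items_missing` with measures `pai`, `cesd_sum`, `drinks_per_week`
#'   (`flag` is non-missing only for `cesd_sum`).
#' @export
score_responses <- function(responses, assignments, survey_returns,
                            reverse_coded = c(4L, 8L, 12L, 16L)) {
  scored_types <- c(pai = "pai", cesd = "cesd_sum", alcohol = "drinks_per_week")
  picks <- assignments |>
    dplyr::filter(.data$survey_type %in% names(scored_types),
                  .data$wave %in% wave_levels()) |>
    dplyr::inner_join(dplyr::select(survey_returns, "instance_id", "return_ts"),
                      by = "instance_id") |>
    dplyr::slice_min(.data$return_ts, n = 1, with_ties = FALSE,
                     by = c("participant_id", "survey_type", "wave"))

  vals <- responses |>
    dplyr::semi_join(picks, by = "instance_id") |>
    dplyr::arrange(.data$instance_id, .data$item_index)
  by_inst <- split(vals$value, vals$instance_id)

  one <- function(iid, type) {
    v <- by_inst[[iid]]
    if (type == "pai") {
      if (is.null(v)) v <- rep(NA_real_, 5)
      s <- .score_pai(v)
      list(value = s$value, flag = NA_integer_, imputed = s$imputed,
           n_items_missing = s$n_items_missing)
    } else if (type == "cesd") {
      if (is.null(v)) v <- rep(NA_real_, 20)
      s <- .score_cesd(v, reverse_coded)
      s["issue"] <- NULL
      s
    } else {
      if (is.null(v)) v <- rep(NA_real_, 2)
      miss <- sum(is.na(v))
      val <- if (miss > 0) NA_real_ else drinks_per_week(v[1], v[2])
      list(value = val, flag = NA_integer_, imputed = FALSE, n_items_missing = miss)
    }
  }

  scored <- purrr::map2(picks$instance_id, picks$survey_type, one)
  picks |>
    dplyr::mutate(
      measure = scored_types[.data$survey_type],
      value = purrr::map_dbl(scored, "value"),
      flag = purrr::map_int(scored, "flag"),
      imputed = purrr::map_lgl(scored, "imputed"),
      n_items_missing = purrr::map_int(scored, "n_items_missing")
    ) |>
    dplyr::select("participant_id", "wave", "measure", "value", "flag",
                  "imputed", "n_items_missing")
}
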