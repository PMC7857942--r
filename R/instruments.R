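#' Survey instruments deployed in the app protocol
#'
#' One row per survey type, with its item count and the number of app screens
#' ("steps") used to administer it. The first and last steps of every survey
#' are an introduction and a thank-you screen that carry no questions; the
#' remaining items are spread evenly over the intermediate steps.
#'
#' The three analysed instruments have fixed item counts: the Physical
#' Activity Index survey asks 5 daily-hour duration questions, the CES-D
#' depressive-symptoms scale has 20 items scored 0-3, and the alcohol survey
#' asks 2 questions (drinks per day, drinking days per week). Item counts for
#' the remaining instruments only enter completion accounting and the
#' synthetic generator.
#'
#' @return A tibble with columns `survey_type`, `n_items`, `n_steps`.
#' @export
#' @examples
#' survey_instruments()
survey_instruments <- function() {
  tibble::tribble(
    ~survey_type,          ~n_items, ~n_steps,
    "sociodemographic",    10L,      7L,
    "smoking",             8L,       6L,
    "meds_risk_factors",   14L,      9L,
    "cvd_history",         10L,      7L,
    "noncvd_history",      12L,      8L,
    "pai",                 5L,       7L,
    "alcohol",             2L,       4L,
    "health",              12L,      8L,
    "cesd",                20L,      12L,
    "med_history_update",  18L,      11L
  )
}

#' Default deployment schedule
#'
#' Which survey types are deployed at which protocol wave. The default mirrors
#' a 12-month eCohort protocol that deploys 22 surveys in total: nine baseline
#' surveys; the physical-activity survey at every 3-month wave; medical history
#' update, CES-D and the health survey at 6 and 12 months; and smoking,
#' alcohol and medication/risk-factor surveys again at 12 months.
#'
#' @return A tibble with columns `survey_type`, `wave`.
#' @export
#' @examples
#' dplyr::count(default_schedule(), wave) # 9 + 1 + 4 + 1 + 7 = 22
default_schedule <- function() {
  base9 <- c(
    "sociodemographic", "smoking", "meds_risk_factors", "cvd_history",
    "noncvd_history", "pai", "alcohol", "health", "cesd"
  )
  dplyr::bind_rows(
    tibble::tibble(survey_type = base9, wave = "baseline"),
    tibble::tibble(survey_type = "pai", wave = c("m3", "m6", "m9", "m12")),
    tibble::tibble(
      survey_type = rep(c("med_history_update", "cesd", "health"), each = 2),
      wave = rep(c("m6", "m12"), 3)
    ),
    tibble::tibble(survey_type = c("smoking", "alcohol", "meds_risk_factors"), wave = "m12")
  ) |>
    dplyr::mutate(wave = factor(.data$wave, levels = wave_levels())) |>
    dplyr::arrange(.data$wave, .data$survey_type) |>
    dplyr::mutate(wave = as.character(.data$wave))
}

#' Protocol wave labels, in order
#'
#' @return Character vector `c("baseline", "m3", "m6", "m9", "m12")`.
#' @export
wave_levels <- function() c("baseline", "m3", "m6", "m9", "m12")

#' Physical Activity Index category weights
#'
#' Unitless multipliers applied to the daily hours spent in each activity
#' intensity; the five hour inputs are constrained to sum to 24, so the index
#' ranges from 24 (all sleep) to 120 (all heavy activity).
#'
#' @return Named numeric vector of weights for sleep, sedentary, slight,
#'   moderate and heavy activity.
#' @export
#' @examples
#' pai_weights()
pai_weights <- function() {
  c(sleep = 1, sedentary = 1.1, slight = 1.5, moderate = 2.4, heavy = 5)
}
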