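#' Write cohort tables to a directory of CSV files
#'
#' Writes `participants.csv`, `survey_returns.csv` (step timestamps as a
#' semicolon-delimited list), `responses.csv` (long format, empty cell =
#' missing) and `clinic.csv`. The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param tables An `ecohort_tables` list from [simulate_cohort()] (or any
#'   list with the same four tibbles).
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", dir), class = "ecohortr_io_error")
  }
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    survey_returns = file.path(dir, "survey_returns.csv"),
    responses = file.path(dir, "responses.csv"),
    clinic = file.path(dir, "clinic.csv")
  )
  readr::write_csv(tables$participants, paths[["participants"]], na = "")
  readr::write_csv(tables$survey_returns, paths[["survey_returns"]], na = "")
  readr::write_csv(tables$responses, paths[["responses"]], na = "")
  readr::write_csv(tables$clinic, paths[["clinic"]], na = "")
  invisible(paths)
}

#' Read cohort tables from a directory of CSV files
#'
#' Counterpart of [write_cohort()].
#'
#' @param dir Directory containing the four cohort CSV files.
#' @return A list of class `ecohort_tables` (without a `config` element).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("participants.csv", "survey_returns.csv",
                           "responses.csv", "clinic.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(sprintf("Missing cohort files: %s", paste(basename(missing), collapse = ", ")),
          class = "ecohortr_io_error")
  }
  participants <- readr::read_csv(
    need[1],
    col_types = readr::cols(
      id = "c", enrolled = "i", age = "d", female = "i", current_smoker = "i",
      education = "i", married = "i", employed = "i", bmi = "d",
      registration_ts = "d", followup_days = "i"
    )
  )
  survey_returns <- readr::read_csv(
    need[2],
    col_types = readr::cols(
      participant_id = "c", instance_id = "c", survey_type = "c",
      deployment_ts = "d", start_ts = "d", return_ts = "d", step_ts = "c"
    )
  )
  responses <- readr::read_csv(
    need[3],
    col_types = readr::cols(
      participant_id = "c", instance_id = "c", item_index = "i", value = "d"
    )
  )
  clinic <- readr::read_csv(
    need[4],
    col_types = readr::cols(participant_id = "c", measure = "c", value = "d")
  )
  structure(
    list(participants = participants, survey_returns = survey_returns,
         responses = responses, clinic = clinic),
    class = "ecohort_tables"
  )
}
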