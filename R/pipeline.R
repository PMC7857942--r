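# End-to-end pipeline: simulate (or load) the cohort tables, validate,
# assign waves, apply eligibility, compute adherence and timing, score the
# measures, and run the agreement, group-comparison and trend analyses.
# Deterministic given the config seed; every output table carries the run's
# config hash in its metadata sidecar.

#' Validate cohort tables
#'
#' Schema and consistency checks: required columns, duplicate instance IDs,
#' timestamp ordering (`deployment <= start <= return`, nondecreasing step
#' times, return not before registration), and per-instrument item counts in
#' the response table. All issues are reported, none thrown.
#'
#' @param tables An `ecohort_tables` list.
#' @return A tibble `table, id, issue`; zero rows when clean.
#' @export
validate_cohort <- function(tables) {
  issues <- list()
  add <- function(table, id, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, id = as.character(id), issue = issue
    )
  }
  need <- list(
    participants = c("id", "enrolled", "registration_ts", "followup_days"),
    survey_returns = c("participant_id", "instance_id", "survey_type",
                       "deployment_ts", "start_ts", "return_ts", "step_ts"),
    responses = c("participant_id", "instance_id", "item_index", "value"),
    clinic = c("participant_id", "measure", "value")
  )
  for (tb in names(need)) {
    miss <- setdiff(need[[tb]], names(tables[[tb]]))
    if (length(miss)) add(tb, NA, sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (length(issues)) return(purrr::list_rbind(issues))

  sr <- tables$survey_returns
  dup <- sr$instance_id[duplicated(sr$instance_id)]
  for (d in unique(dup)) add("survey_returns", d, "duplicate instance_id")
  bad_order <- sr |>
    dplyr::filter(.data$start_ts < .data$deployment_ts | .data$return_ts < .data$start_ts)
  for (d in bad_order$instance_id) add("survey_returns", d, "timestamp ordering violated")
  reg <- tables$participants |>
    dplyr::select(participant_id = "id", "registration_ts")
  early <- sr |>
    dplyr::inner_join(reg, by = "participant_id") |>
    dplyr::filter(.data$return_ts < .data$registration_ts)
  for (d in early$instance_id) add("survey_returns", d, "return precedes registration")
  nondecr <- vapply(strsplit(sr$step_ts, ";", fixed = TRUE),
                    function(s) !is.unsorted(as.numeric(s)), logical(1))
  for (d in sr$instance_id[!nondecr]) add("survey_returns", d, "step times decrease")

  counts <- tables$responses |>
    dplyr::count(.data$instance_id, name = "n_rows") |>
    dplyr::inner_join(dplyr::select(sr, "instance_id", "survey_type"), by = "instance_id") |>
    dplyr::inner_join(survey_instruments(), by = "survey_type") |>
    dplyr::filter(.data$n_rows != .data$n_items)
  for (i in seq_len(nrow(counts))) {
    add("responses", counts$instance_id[i],
        sprintf("item count %d, instrument expects %d",
                counts$n_rows[i], counts$n_items[i]))
  }
  if (length(issues)) purrr::list_rbind(issues) else
    tibble::tibble(table = character(), id = character(), issue = character())
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> validate -> wave assignment -> eligibility ->
#' completion & adherence -> timing -> scoring -> agreement -> group
#' comparison -> trends, logging per-stage record counts to stderr.
#' Deterministic: rerunning with the same config reproduces identical
#' tables.
#'
#' @param config A [cohort_config()]; ignored when `input_dir` is given
#'   except for the schedule.
#' @param input_dir Optional directory of cohort CSVs ([read_cohort()]
#'   layout) to analyse instead of simulating.
#' @param analyses Character subset of
#'   `c("adherence", "agreement", "comparison", "trend")`.
#' @param min_followup_days Eligibility threshold, default 365.
#' @param threshold Survey completion threshold, default 0.75.
#' @param quiet Suppress stage logging.
#' @return An object of class `ecohort_report`: a list of result tibbles
#'   (`adherence`, `timing`, `agreement`, `ba_points`, `table1`,
#'   `returner_model`, `trend`, `boxplots`, `exclusions`, `validation`)
#'   plus `tables`, `scores` and `metadata`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(cohort_config(n_participants = 300, seed = 1))
#' rep$adherence
#' }
run_pipeline <- function(config = cohort_config(),
                         input_dir = NULL,
                         analyses = c("adherence", "agreement", "comparison", "trend"),
                         min_followup_days = 365,
                         threshold = 0.75,
                         quiet = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))

  tables <- if (is.null(input_dir)) simulate_cohort(config) else read_cohort(input_dir)
  log("stage simulate/load: %d participants, %d survey instances",
      nrow(tables$participants), nrow(tables$survey_returns))

  validation <- validate_cohort(tables)
  if (nrow(validation)) log("stage validate: %d issue(s)", nrow(validation))

  enrolled <- dplyr::filter(tables$participants, .data$enrolled == 1L)
  assignments <- assign_waves(tables$survey_returns, tables$participants)
  elig <- apply_eligibility(tables$participants, assignments, min_followup_days)
  log("stage eligibility: %d enrolled -> %d eligible (%d excluded: %s)",
      nrow(enrolled), nrow(elig$participants), nrow(elig$exclusions),
      paste(names(table(elig$exclusions$rule)), table(elig$exclusions$rule),
            sep = "=", collapse = ", "))

  completions <- completion_status(tables$responses, assignments,
                                   threshold = threshold)
  scores <- score_responses(tables$responses, assignments, tables$survey_returns)

  out <- list(tables = tables, scores = scores, exclusions = elig$exclusions,
              validation = validation, assignments = assignments)

  if ("adherence" %in% analyses) {
    out$adherence <- survey_adherence(completions, config$schedule, elig$participants)
    out$timing <- timing_metrics(tables$survey_returns, assignments)
    log("stage adherence: baseline any-survey %.2f%%", 100 * out$adherence$p_any[1])
  }
  if ("agreement" %in% analyses) {
    agr <- agreement_analysis(scores, tables$clinic)
    out$agreement <- agr$agreement
    out$ba_points <- agr$ba_points
    log("stage agreement: %d statistics over %d measures",
        nrow(agr$agreement), length(unique(agr$agreement$measure)))
  }
  if ("comparison" %in% analyses) {
    out$table1 <- table_one(tables$participants)
    returner_data <- enrolled |>
      dplyr::mutate(returned = as.integer(.data$id %in% assignments$participant_id))
    out$returner_model <- tryCatch(
      tidy(fit_returner_model(returner_data)),
      error = function(e) {
        log("stage comparison: returner model failed (%s)", conditionMessage(e))
        NULL
      }
    )
    log("stage comparison: %d returners of %d enrolled",
        sum(returner_data$returned), nrow(returner_data))
  }
  if ("trend" %in% analyses) {
    tr <- longitudinal_trends(scores)
    out$trend <- tr$trend
    out$boxplots <- tr$boxplots
    log("stage trend: %d measure-wave effects", nrow(tr$trend %||% tibble::tibble()))
  }

  cfg_for_hash <- if (is.null(input_dir)) unclass(config) else list(input_dir = input_dir)
  out$metadata <- tibble::tibble(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    n_participants = nrow(enrolled),
    n_eligible = nrow(elig$participants),
    analyses = paste(sort(analyses), collapse = "+"),
    package_version = as.character(utils::packageVersion("ecohortr"))
  )
  structure(out, class = "ecohort_report")
}

#' @export
print.ecohort_report <- function(x, ...) {
  cat("<ecohort_report>  config", x$metadata$config_hash, "\n")
  cat(sprintf("  %d enrolled, %d eligible; analyses: %s\n",
              x$metadata$n_participants, x$metadata$n_eligible, x$metadata$analyses))
  for (nm in c("adherence", "agreement", "table1", "returner_model", "trend")) {
    if (!is.null(x[[nm]])) cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per result table plus a JSON metadata sidecar carrying the run's
#' config hash and seed.
#'
#' @param report An `ecohort_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- as.list(report$metadata)
  tables <- c("adherence", "timing", "agreement", "ba_points", "table1",
              "returner_model", "trend", "boxplots", "exclusions", "validation")
  paths <- character()
  for (nm in tables) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(report[[nm]], p, na = "")
    jsonlite::write_json(c(meta, list(table = nm)),
                         file.path(dir, paste0(nm, ".meta.json")),
                         auto_unbox = TRUE)
    paths <- c(paths, p)
  }
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"), auto_unbox = TRUE)
  invisible(paths)
}

#' Plot adherence over waves
#'
#' Line plot of the proportion of eligible participants completing at least
#' one survey and completing all scheduled surveys at each wave.
#'
#' @param adherence Adherence table from [survey_adherence()].
#' @return A ggplot object.
#' @export
plot_adherence <- function(adherence) {
  d <- adherence |>
    tidyr::pivot_longer(c("p_any", "p_all"), names_to = "metric", values_to = "p") |>
    dplyr::mutate(
      wave = factor(.data$wave, levels = wave_levels()),
      metric = dplyr::recode(.data$metric, p_any = "At least one survey",
                             p_all = "All scheduled surveys")
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wave, y = .data$p,
                                  group = .data$metric, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Protocol wave", y = "Adherence", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-wave score distributions
#'
#' Box-and-whisker display of the balanced-panel score distributions per
#' measure and wave, from precomputed five-number summaries.
#'
#' @param boxplots Boxplot summary tibble from [longitudinal_trends()].
#' @return A ggplot object.
#' @export
plot_trends <- function(boxplots) {
  d <- dplyr::mutate(boxplots, wave = factor(.data$wave, levels = wave_levels()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wave)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", width = 0.6, fill = "grey90"
    ) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Protocol wave", y = "Score") +
    ggplot2::theme_minimal()
}
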