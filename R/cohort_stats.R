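# Group characteristics and returner modelling: clinical-table style
# summaries with per-variable complete-case denominators, two-group tests
# (pooled-variance t, Pearson chi-square), and an adjusted logistic model of
# who returns surveys.

#' Summarise one variable in clinical-table style
#'
#' Continuous-normal variables are summarised as `mean (SD)`,
#' continuous-skewed as `median (IQR)` (quartiles, type 7), and categorical
#' as `n (%)`. Percentages use the non-missing denominator and are rounded
#' half-up to 2 decimals, the usual printed-table convention.
#'
#' @param values Vector of observations (may contain `NA`).
#' @param kind One of `"continuous-normal"`, `"continuous-skewed"`,
#'   `"categorical"`.
#' @param digits Decimals for continuous summaries (default 2).
#' @return A tibble with one row per summary line: `level` (categorical
#'   levels, `NA` otherwise), `n`, `denominator`, `percent`, `summary`.
#' @export
#' @examples
#' summarize_variable(c(rep(1, 1109), rep(0, 839)), "categorical")
summarize_variable <- function(values, kind = c("continuous-normal",
                                                "continuous-skewed",
                                                "categorical"),
                               digits = 2) {
  kind <- match.arg(kind)
  ok <- !is.na(values)
  denom <- sum(ok)
  if (denom == 0) {
    return(tibble::tibble(level = NA_character_, n = 0L, denominator = 0L,
                          percent = NA_real_, summary = NA_character_))
  }
  v <- values[ok]
  if (kind == "categorical") {
    tab <- table(v)
    tibble::tibble(
      level = names(tab),
      n = as.integer(tab),
      denominator = denom,
      percent = round_half_up(100 * as.integer(tab) / denom, 2),
      summary = sprintf("%d (%.2f)", as.integer(tab),
                        round_half_up(100 * as.integer(tab) / denom, 2))
    )
  } else if (kind == "continuous-normal") {
    tibble::tibble(
      level = NA_character_, n = denom, denominator = denom, percent = NA_real_,
      summary = sprintf("%.*f (%.*f)", digits, mean(v), digits, stats::sd(v))
    )
  } else {
    q <- quartiles(v)
    tibble::tibble(
      level = NA_character_, n = denom, denominator = denom, percent = NA_real_,
      summary = sprintf("%.*f (%.*f-%.*f)", digits, q$median, digits, q$q1,
                        digits, q$q3)
    )
  }
}

#' Compare two groups variable by variable
#'
#' Continuous variables are compared with pooled-variance (Student) two-sample
#' t tests, categorical variables with Pearson chi-square tests on the full
#' contingency table without continuity correction; all p values two-sided.
#'
#' @param data A data frame.
#' @param group Column defining the two groups (tidy-eval).
#' @param specs Named character vector mapping variable names to their kind
#'   (`"continuous-normal"`, `"continuous-skewed"`, `"categorical"`).
#'   Skewed continuous variables are still compared with a t test, matching
#'   common clinical-table practice; the kind only controls the summary.
#' @param welch Use Welch's t instead of the pooled-variance test.
#' @return A tibble `variable, summary_<group1>, summary_<group2>, test,
#'   statistic, p`.
#' @export
compare_groups <- function(data, group, specs, welch = FALSE) {
  gv <- dplyr::pull(data, {{ group }})
  lev <- sort(unique(gv[!is.na(gv)]), decreasing = TRUE)
  if (length(lev) != 2) {
    abort("`group` must have exactly two levels.", class = "ecohortr_data_error")
  }
  rows <- purrr::imap(specs, function(kind, var) {
    v <- data[[var]]
    s1 <- summarize_variable(v[gv == lev[1]], kind)
    s2 <- summarize_variable(v[gv == lev[2]], kind)
    fmt <- function(s) {
      if (all(is.na(s$level))) s$summary else
        paste(sprintf("%s: %s", s$level, s$summary), collapse = "; ")
    }
    if (kind == "categorical") {
      tab <- table(factor(gv[!is.na(v)]), v[!is.na(v)])
      ts <- tryCatch(suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
                     error = function(e) NULL)
      tibble::tibble(
        variable = var, group1 = fmt(s1), group2 = fmt(s2), test = "chi-square",
        statistic = if (is.null(ts)) NA_real_ else unname(ts$statistic),
        p = if (is.null(ts)) NA_real_ else ts$p.value
      )
    } else {
      g1 <- v[gv == lev[1] & !is.na(v)]
      g2 <- v[gv == lev[2] & !is.na(v)]
      if (length(g1) < 2 || length(g2) < 2) {
        return(tibble::tibble(variable = var, group1 = fmt(s1), group2 = fmt(s2),
                              test = "t", statistic = NA_real_, p = NA_real_))
      }
      ts <- stats::t.test(g1, g2, var.equal = !welch)
      tibble::tibble(variable = var, group1 = fmt(s1), group2 = fmt(s2),
                     test = "t", statistic = unname(ts$statistic), p = ts$p.value)
    }
  })
  out <- purrr::list_rbind(unname(rows))
  names(out)[names(out) == "group1"] <- paste0("summary_", lev[1])
  names(out)[names(out) == "group2"] <- paste0("summary_", lev[2])
  out
}

#' Characteristics table for the cohort tables
#'
#' Convenience wrapper building the enrolled-versus-comparison
#' characteristics table from a participant tibble.
#'
#' @param participants Participant tibble from [simulate_cohort()] or
#'   [read_cohort()].
#' @return [compare_groups()] output for the standard covariate set.
#' @export
table_one <- function(participants) {
  specs <- c(
    age = "continuous-normal", female = "categorical",
    current_smoker = "categorical", education = "categorical",
    married = "categorical", employed = "categorical",
    bmi = "continuous-skewed"
  )
  compare_groups(participants, enrolled, specs)
}

#' Adjusted logistic model of survey return
#'
#' Fits a maximum-likelihood logistic regression of a return indicator on
#' age, sex, current smoking and highest education level (entered as
#' indicators against the lowest category), complete-case. Odds-ratio scale
#' Wald confidence intervals.
#'
#' @param data Data frame with columns `returned` (0/1), `age`, `female`,
#'   `current_smoker`, `education` (1-5 ordinal, treated as categorical).
#' @param education_ref Reference education level (default 1, the lowest).
#' @param alpha CI type-I error.
#' @return An object of class `returner_fit` wrapping the `glm` fit; use
#'   [tidy()] for the aOR table.
#' @export
fit_returner_model <- function(data, education_ref = 1L, alpha = 0.05) {
  d <- data |>
    dplyr::select("returned", "age", "female", "current_smoker", "education") |>
    dplyr::filter(dplyr::if_all(dplyr::everything(), ~ !is.na(.x)))
  if (length(unique(d$returned)) < 2) {
    abort("`returned` must include both classes.", class = "ecohortr_data_error")
  }
  keep <- vapply(c("age", "female", "current_smoker", "education"),
                 function(v) length(unique(d[[v]])) > 1, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warn(sprintf("Zero-variance covariate(s) dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  terms <- names(keep)[keep]
  if ("education" %in% terms) {
    d$education <- stats::relevel(factor(d$education), ref = as.character(education_ref))
  }
  fml <- stats::reformulate(terms, response = "returned")
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  co <- stats::coef(fit)
  if (!fit$converged || any(abs(co[-1]) > 15, na.rm = TRUE)) {
    abort("Separation detected: logistic fit has unbounded coefficients.",
          class = "ecohortr_separation_error")
  }
  structure(list(fit = fit, alpha = alpha, n = nrow(d)), class = "returner_fit")
}

#' @export
print.returner_fit <- function(x, ...) {
  cat("<returner_fit>  n =", x$n, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy the returner model on the odds-ratio scale
#'
#' @param x A `returner_fit`.
#' @param ... Unused.
#' @return A tibble `term, aOR, ci_low, ci_high, p` (intercept omitted).
#' @method tidy returner_fit
#' @export
tidy.returner_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  zc <- qnorm(1 - x$alpha / 2)
  out <- tibble::tibble(
    term = rownames(s),
    aOR = exp(s[, "Estimate"]),
    ci_low = exp(s[, "Estimate"] - zc * s[, "Std. Error"]),
    ci_high = exp(s[, "Estimate"] + zc * s[, "Std. Error"]),
    p = s[, "Pr(>|z|)"]
  )
  dplyr::filter(out, .data$term != "(Intercept)")
}

#' @method glance returner_fit
#' @export
glance.returner_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}
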