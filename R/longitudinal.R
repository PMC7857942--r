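# Longitudinal comparisons across waves. Trend analyses are restricted to
# participants observed at every required wave (complete-case balanced
# panels, mirroring the "returned at all time points" subgroups), where the
# random-intercept model has an exact closed form: wave effects are the
# wave-mean differences from baseline and the variance components follow
# from the within/between mean squares (method of moments, equal to REML on
# balanced data).

#' Restrict a long measure table to a balanced panel
#'
#' Keeps participants with exactly one value at every required wave.
#'
#' @param long Tibble `participant_id, wave, value`.
#' @param waves Required waves (default: all waves present in `long`).
#' @return The filtered tibble, with waves ordered per [wave_levels()].
#' @export
complete_panel <- function(long, waves = NULL) {
  waves <- waves %||% intersect(wave_levels(), unique(long$wave))
  dup <- long |>
    dplyr::count(.data$participant_id, .data$wave) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort("More than one value per participant and wave; resolve duplicates first.",
          class = "ecohortr_data_error")
  }
  keep <- long |>
    dplyr::filter(.data$wave %in% waves, !is.na(.data$value)) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == length(waves))
  long |>
    dplyr::filter(.data$wave %in% waves, !is.na(.data$value)) |>
    dplyr::semi_join(keep, by = "participant_id") |>
    dplyr::mutate(wave = factor(.data$wave, levels = intersect(wave_levels(), waves)))
}

#' Random-intercept model on a balanced panel
#'
#' Fits `value_it = mu + beta_wave + b_i + e_it` with `b_i ~ N(0, tau^2)`
#' and `e_it ~ N(0, sigma^2)`, wave categorical with the first wave as
#' reference. On a balanced panel the wave effects are exactly the wave-mean
#' differences from the reference wave; `sigma^2` is the interaction mean
#' square and `tau^2 = (MS_subject - sigma^2) / k` (clamped at 0 with a
#' warning if the moment estimate is negative). Wald z tests per wave
#' effect, with `SE = sqrt(2 sigma^2 / n)`.
#'
#' @param long Tibble `participant_id, wave, value`, balanced (use
#'   [complete_panel()] first).
#' @return An object of class `wave_lmm`; see [tidy.wave_lmm()] and
#'   [glance.wave_lmm()].
#' @export
fit_random_intercept <- function(long) {
  long <- dplyr::mutate(long, wave = as.character(.data$wave))
  waves <- intersect(wave_levels(), unique(long$wave))
  if (length(waves) < 2) {
    abort("At least two waves are required.", class = "ecohortr_data_error")
  }
  counts <- long |>
    dplyr::count(.data$participant_id) |>
    dplyr::pull(.data$n)
  per_wave <- long |> dplyr::count(.data$participant_id, .data$wave)
  if (any(per_wave$n != 1) || any(counts != length(waves))) {
    abort("Panel is unbalanced; restrict to a complete panel (see complete_panel()).",
          class = "ecohortr_data_error")
  }
  n <- length(unique(long$participant_id))
  k <- length(waves)
  y_bar <- mean(long$value)
  wave_means <- long |>
    dplyr::summarise(m = mean(.data$value), .by = "wave") |>
    dplyr::arrange(factor(.data$wave, levels = waves))
  subj_means <- long |>
    dplyr::summarise(m = mean(.data$value), .by = "participant_id")

  resid2 <- long |>
    dplyr::left_join(dplyr::rename(wave_means, wm = "m"), by = "wave") |>
    dplyr::left_join(dplyr::rename(subj_means, sm = "m"), by = "participant_id") |>
    dplyr::mutate(r = .data$value - .data$wm - .data$sm + y_bar)
  sigma2 <- sum(resid2$r^2) / ((n - 1) * (k - 1))
  ms_subj <- k * sum((subj_means$m - y_bar)^2) / (n - 1)
  tau2 <- (ms_subj - sigma2) / k
  if (tau2 < 0) {
    warn("Moment estimate of the between-participant variance was negative; clamped to 0.")
    tau2 <- 0
  }

  est <- wave_means$m - wave_means$m[1]
  se <- sqrt(2 * sigma2 / n)
  zstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf)
  effects <- tibble::tibble(
    wave = wave_means$wave,
    estimate = est,
    se = c(NA_real_, rep(se, k - 1)),
    p = c(NA_real_, (2 * pnorm(-abs(zstat)))[-1])
  )

  structure(
    list(effects = effects, tau2 = tau2, sigma2 = sigma2, n = n, k = k,
         reference = waves[1], grand_mean = y_bar),
    class = "wave_lmm"
  )
}

#' @export
print.wave_lmm <- function(x, ...) {
  cat(sprintf("<wave_lmm>  n = %d participants x %d waves (reference %s)\n",
              x$n, x$k, x$reference))
  cat(sprintf("  tau^2 = %.4f, sigma^2 = %.4f\n", x$tau2, x$sigma2))
  print(x$effects, ...)
  invisible(x)
}

#' Tidy wave effects of a random-intercept fit
#'
#' @param x A `wave_lmm` object.
#' @param ... Unused.
#' @return Tibble `wave, estimate, se, p` (reference wave has estimate 0 and
#'   no test).
#' @method tidy wave_lmm
#' @export
tidy.wave_lmm <- function(x, ...) x$effects

#' @method glance wave_lmm
#' @export
glance.wave_lmm <- function(x, ...) {
  tibble::tibble(n = x$n, k_waves = x$k, tau2 = x$tau2, sigma2 = x$sigma2,
                 grand_mean = x$grand_mean)
}

#' Paired t test between two waves
#'
#' Classical paired t on within-participant differences, two-sided. With
#' zero-variance differences the t statistic is degenerate: p is reported as
#' 1 when the mean difference is 0 and as 0 (limit) otherwise, with a note
#' attribute.
#'
#' @param x,y Paired numeric vectors (e.g. baseline and 12-month values);
#'   pairs with a missing side are dropped.
#' @return Tibble `mean_diff, t, p, n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(2, 2, 5))
paired_t <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  d <- y[keep] - x[keep]
  n <- length(d)
  if (n < 2) abort("Paired t requires at least 2 complete pairs.",
                   class = "ecohortr_sample_error")
  if (stats::sd(d) == 0) {
    out <- tibble::tibble(mean_diff = mean(d), t = ifelse(mean(d) == 0, 0, Inf),
                          p = ifelse(mean(d) == 0, 1, 0), n = n)
    attr(out, "note") <- "zero-variance differences; p reported as limit"
    return(out)
  }
  tt <- stats::t.test(y[keep], x[keep], paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 p = tt$p.value, n = n)
}

#' Trend analysis for all analysed measures
#'
#' Physical activity (five waves) and CES-D (baseline, 6, 12 months) are
#' analysed with the balanced random-intercept model; weekly alcohol intake
#' (baseline vs 12 months) with a paired t test. Each analysis is restricted
#' to participants observed at all of that measure's waves.
#'
#' @param scores Scored measures from [score_responses()].
#' @return A list with `trend` (tibble `measure, wave, estimate, se, p,
#'   tau2, sigma2, n`) and `boxplots` (tibble `measure, wave, n, min, q1,
#'   median, q3, max` of the panel values).
#' @export
longitudinal_trends <- function(scores) {
  plan <- list(
    pai = wave_levels(),
    cesd_sum = c("baseline", "m6", "m12"),
    drinks_per_week = c("baseline", "m12")
  )
  trend <- list(); box <- list()
  for (m in names(plan)) {
    long <- scores |>
      dplyr::filter(.data$measure == m) |>
      dplyr::select("participant_id", "wave", "value")
    panel <- complete_panel(long, plan[[m]])
    if (nrow(panel) == 0) next
    box[[m]] <- panel |>
      dplyr::summarise(
        n = dplyr::n(), min = min(.data$value),
        q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
        median = quantile(.data$value, 0.5, type = 7, names = FALSE),
        q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
        max = max(.data$value), .by = "wave"
      ) |>
      dplyr::mutate(measure = m, wave = as.character(.data$wave), .before = 1)
    if (m == "drinks_per_week") {
      wide <- panel |>
        tidyr::pivot_wider(names_from = "wave", values_from = "value")
      pt <- paired_t(wide$baseline, wide$m12)
      trend[[m]] <- tibble::tibble(
        measure = m, wave = "m12", estimate = pt$mean_diff,
        se = NA_real_, p = pt$p, tau2 = NA_real_, sigma2 = NA_real_, n = pt$n
      )
    } else {
      fit <- fit_random_intercept(panel)
      trend[[m]] <- tidy(fit) |>
        dplyr::mutate(measure = m, .before = 1) |>
        dplyr::mutate(tau2 = fit$tau2, sigma2 = fit$sigma2, n = fit$n,
                      wave = as.character(.data$wave))
    }
  }
  list(trend = purrr::list_rbind(unname(trend)),
       boxplots = purrr::list_rbind(unname(box)))
}
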