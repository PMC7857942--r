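# App-versus-clinic agreement statistics: Lin's concordance correlation
# coefficient with a Fisher-z confidence interval, unweighted Cohen's kappa
# with its asymptotic standard error, and Bland-Altman bias with 95% limits
# of agreement. Clinic measurements are treated as the gold standard; pairs
# with either side missing are dropped (complete-case) and counted.

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired continuous measurements, combining precision
#' (Pearson correlation) and accuracy (location and scale shift):
#' \deqn{\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with 1/n moment estimators. The confidence interval is computed on the
#' Fisher z scale with the standard asymptotic variance
#' \deqn{SE_z^2 = \frac{1}{n-2}\left[
#'   \frac{(1-r^2)\hat\rho_c^2}{(1-\hat\rho_c^2) r^2}
#'   + \frac{2\hat\rho_c^3 (1-\hat\rho_c) u^2}{r (1-\hat\rho_c^2)^2}
#'   - \frac{\hat\rho_c^4 u^4}{2 r^2 (1-\hat\rho_c^2)^2}\right]}
#' where \eqn{r} is the Pearson correlation and
#' \eqn{u = (\bar x - \bar y)/\sqrt{s_x s_y}}, then back-transformed.
#'
#' @param data A data frame of paired measurements.
#' @param x,y Columns holding the two measurements (tidy-eval); `x` is the
#'   gold standard. Defaults `clinic` and `app`.
#' @param alpha Two-sided type-I error for the CI (default 0.05).
#' @return A one-row tibble `statistic, estimate, ci_low, ci_high, n_pairs`.
#' @export
#' @examples
#' d <- simulate_agreement_pairs(500, 0, 1, 0.5, sqrt(0.125), sqrt(0.125))
#' ccc(d)
ccc <- function(data, x = clinic, y = app, alpha = 0.05) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("CCC requires at least 3 complete pairs.", class = "ecohortr_sample_error")
  sx2 <- mean((xv - mean(xv))^2)
  sy2 <- mean((yv - mean(yv))^2)
  if (sx2 == 0 || sy2 == 0) {
    abort("CCC is undefined when either measurement has zero variance.",
          class = "ecohortr_degenerate_error")
  }
  sxy <- mean((xv - mean(xv)) * (yv - mean(yv)))
  est <- 2 * sxy / (sx2 + sy2 + (mean(xv) - mean(yv))^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mean(xv) - mean(yv)) / sqrt(sqrt(sx2) * sqrt(sy2))
  if (abs(est) >= 1 || r == 0) {
    ci <- c(est, est) # perfect or undefined precision: degenerate CI
  } else {
    z <- atanh(est)
    se_z2 <- ((1 - r^2) * est^2 / ((1 - est^2) * r^2) +
                2 * est^3 * (1 - est) * u^2 / (r * (1 - est^2)^2) -
                est^4 * u^4 / (2 * r^2 * (1 - est^2)^2)) / (n - 2)
    se_z <- sqrt(max(se_z2, 0))
    zc <- qnorm(1 - alpha / 2)
    ci <- tanh(c(z - zc * se_z, z + zc * se_z))
  }
  tibble::tibble(statistic = "ccc", estimate = est,
                 ci_low = ci[1], ci_high = ci[2], n_pairs = n)
}

#' Cohen's kappa for two categorical ratings
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' expected agreement from the marginal products, and the standard
#' asymptotic Wald interval with
#' \eqn{SE = \sqrt{p_o(1-p_o) / (n (1-p_e)^2)}}. Unweighted.
#'
#' @param data Either a data frame of paired ratings, or a square confusion
#'   matrix of counts.
#' @param a,b Rating columns (tidy-eval) when `data` is a data frame;
#'   defaults `clinic` and `app`.
#' @param alpha Two-sided type-I error for the CI.
#' @return A one-row tibble `statistic, estimate, ci_low, ci_high, n_pairs`.
#'   When both raters are constant and identical (`p_e = 1`) the estimate is
#'   degenerate and reported as `NA`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(40, 10, 10, 40), 2)) # kappa = 0.6
cohen_kappa <- function(data, a = clinic, b = app, alpha = 0.05) {
  if (is.matrix(data) || is.table(data)) {
    tab <- as.matrix(data)
    if (nrow(tab) != ncol(tab)) {
      abort("Confusion matrix must be square.", class = "ecohortr_data_error")
    }
  } else {
    av <- dplyr::pull(data, {{ a }})
    bv <- dplyr::pull(data, {{ b }})
    keep <- stats::complete.cases(av, bv)
    av <- av[keep]; bv <- bv[keep]
    lev <- sort(unique(c(av, bv)))
    tab <- table(factor(av, levels = lev), factor(bv, levels = lev))
  }
  n <- sum(tab)
  if (n < 1) abort("No complete rating pairs.", class = "ecohortr_sample_error")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    return(tibble::tibble(statistic = "kappa", estimate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, n_pairs = as.integer(n)))
  }
  k <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  zc <- qnorm(1 - alpha / 2)
  tibble::tibble(statistic = "kappa", estimate = k,
                 ci_low = k - zc * se, ci_high = k + zc * se,
                 n_pairs = as.integer(n))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `y - x` (app minus clinic gold standard). The
#' bias is the mean difference and the limits of agreement are
#' `bias +/- k * sd(diff)` with the usual `n - 1` SD and `k = 1.96` by
#' default. The per-pair (mean, difference) scatter is retained for
#' plotting; see [ggplot2::autoplot()].
#'
#' @param data A data frame of paired measurements.
#' @param x,y Columns (tidy-eval); `x` is the gold standard. Defaults
#'   `clinic` and `app`.
#' @param k Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `bland_altman`: a list with `stats` (one-row
#'   tibble `bias, sd_diff, lower, upper, n_pairs`) and `points` (tibble
#'   `mean, diff`).
#' @export
#' @examples
#' d <- simulate_agreement_pairs(200, 10, 2, 1, 0.5, 0.5)
#' ba <- bland_altman(d)
#' ba$stats
bland_altman <- function(data, x = clinic, y = app, k = 1.96) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 2) {
    abort("Bland-Altman analysis requires at least 2 complete pairs.",
          class = "ecohortr_sample_error")
  }
  d <- yv - xv
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      stats = tibble::tibble(bias = bias, sd_diff = s,
                             lower = bias - k * s, upper = bias + k * s,
                             n_pairs = length(d)),
      points = tibble::tibble(mean = (xv + yv) / 2, diff = d),
      k = k
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>  n =", x$stats$n_pairs, "\n")
  cat(sprintf("  bias %.4f, limits of agreement [%.4f, %.4f] (k = %.2f)\n",
              x$stats$bias, x$stats$lower, x$stats$upper, x$k))
  invisible(x)
}

#' Mean app-minus-clinic difference
#'
#' @inheritParams bland_altman
#' @return The mean of `y - x` over complete pairs (equals the Bland-Altman
#'   bias).
#' @export
#' @examples
#' mean_difference(tibble::tibble(clinic = 1:3, app = c(3, 4, 5))) # 2
mean_difference <- function(data, x = clinic, y = app) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  if (!any(keep)) abort("No complete pairs.", class = "ecohortr_sample_error")
  mean(yv[keep] - xv[keep])
}

#' App-versus-clinic agreement for all analysed measures
#'
#' Pairs each participant's baseline app score with their clinic
#' measurement (complete-case) and computes, per measure, the CCC, the mean
#' difference, and Bland-Altman bias and limits; for the binary depression
#' indicator (CES-D sum >= 16 on both sides) it computes Cohen's kappa.
#'
#' @param scores Scored measures from [score_responses()].
#' @param clinic Clinic-measurement tibble (`participant_id, measure,
#'   value`).
#' @param wave Wave of app scores to compare (default `"baseline"`).
#' @param alpha CI type-I error.
#' @return A list with `agreement` (tibble `measure, statistic, estimate,
#'   ci_low, ci_high, n_pairs, n_dropped`) and `ba_points` (tibble
#'   `measure, mean, diff` for Bland-Altman scatter).
#' @export
agreement_analysis <- function(scores, clinic, wave = "baseline", alpha = 0.05) {
  app <- scores |>
    dplyr::filter(.data$wave == !!wave) |>
    dplyr::select("participant_id", "measure", app = "value")
  paired <- clinic |>
    dplyr::rename(clinic = "value") |>
    dplyr::full_join(app, by = c("participant_id", "measure"))

  rows <- list(); pts <- list()
  for (m in c("pai", "cesd_sum", "drinks_per_week")) {
    pm <- dplyr::filter(paired, .data$measure == m)
    cc <- sum(stats::complete.cases(pm$clinic, pm$app))
    dropped <- nrow(pm) - cc
    if (cc >= 3) {
      ba <- bland_altman(pm)
      res <- dplyr::bind_rows(
        ccc(pm, alpha = alpha),
        tibble::tibble(statistic = "mean_difference",
                       estimate = ba$stats$bias, ci_low = NA_real_,
                       ci_high = NA_real_, n_pairs = ba$stats$n_pairs),
        tibble::tibble(statistic = c("ba_bias", "ba_lower", "ba_upper"),
                       estimate = c(ba$stats$bias, ba$stats$lower, ba$stats$upper),
                       ci_low = NA_real_, ci_high = NA_real_,
                       n_pairs = ba$stats$n_pairs)
      )
      rows[[m]] <- dplyr::mutate(res, measure = m, n_dropped = dropped, .before = 1)
      pts[[m]] <- dplyr::mutate(ba$points, measure = m, .before = 1)
    }
  }
  dep <- paired |>
    dplyr::filter(.data$measure == "cesd_sum") |>
    dplyr::mutate(clinic = as.integer(.data$clinic >= 16),
                  app = as.integer(.data$app >= 16))
  cc_dep <- sum(stats::complete.cases(dep$clinic, dep$app))
  if (cc_dep >= 2) {
    rows[["depression"]] <- cohen_kappa(dep, alpha = alpha) |>
      dplyr::mutate(measure = "depression_flag",
                    n_dropped = nrow(dep) - cc_dep, .before = 1)
  }
  list(
    agreement = purrr::list_rbind(unname(rows)),
    ba_points = purrr::list_rbind(unname(pts))
  )
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = s$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(s$lower, s$upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (app - clinic)",
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                                  s$bias, s$lower, s$upper)) +
    ggplot2::theme_minimal()
}
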