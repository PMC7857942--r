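#' Configuration for the synthetic eCohort generator
#'
#' Builds a validated configuration object describing the cohort to simulate:
#' sample size, per-wave survey-return propensities, covariate effects on
#' return, item-level missingness, latent-trait and measurement-error
#' parameters for the three analysed measures, survey-timing distributions,
#' and the deployment schedule.
#'
#' Defaults describe a 12-month smartphone eCohort embedded in a clinic
#' cohort: 1948 enrolled participants, any-survey return propensities of
#' 0.89/0.59/0.52/0.42/0.40 across the five 90-day waves, app-minus-clinic
#' biases of 2.27 index points (physical activity), 0.03 points (CES-D) and
#' 0.54 drinks/week (alcohol), with noise standard deviations chosen so the
#' population concordance between app and clinic values is about
#' 0.56 / 0.77 / 0.82 respectively.
#'
#' @param n_participants Number of enrolled participants (positive integer).
#' @param seed Master integer seed; every table is drawn from an independent
#'   substream derived from it.
#' @param wave_return_prob Named probabilities of returning surveys at each
#'   wave, names `baseline, m3, m6, m9, m12`.
#' @param covariate_effects Named log-odds increments on the per-wave return
#'   logit for `female` and `current_smoker`. Covariates are centred at their
#'   population means, so `wave_return_prob` stays interpretable as the
#'   approximate marginal return probability.
#' @param item_missing_prob Probability that any single item of a returned
#'   survey is skipped.
#' @param survey_return_prob Probability that a given scheduled survey is
#'   returned, conditional on the participant returning anything at that
#'   wave. A scalar, or a tibble `survey_type, wave, prob` of overrides of
#'   the scalar default.
#' @param nonreturner_penalty Log-odds penalty applied to follow-up-wave
#'   return for participants who returned nothing at baseline; induces the
#'   realistic positive correlation of return behaviour across waves. Set to
#'   0 for independent waves.
#' @param trait_params Per-measure latent-trait parameters: for `pai` a
#'   Dirichlet mean (5 activity-hour fractions) and concentration; for
#'   `cesd` and `drinks` a latent normal `mean` and `sd`. Any measure may
#'   carry `wave_effects`, named per-wave shifts added to the app-measured
#'   value at follow-up waves (default: a small CES-D increase at 6 and 12
#'   months).
#' @param agreement_params Per-measure measurement model: app bias `delta`,
#'   clinic noise SD `sigma_c`, app noise SD `sigma_a`. App and clinic values
#'   are `trait + delta + N(0, sigma_a^2)` and `trait + N(0, sigma_c^2)`.
#' @param timing_params Lognormal `meanlog`/`sdlog` (seconds) for the
#'   deployment-to-start lag and the start-to-return touch duration.
#' @param schedule Deployment schedule tibble (`survey_type`, `wave`);
#'   defaults to [default_schedule()].
#' @param n_comparison Number of non-enrolled comparison participants
#'   generated for group contrasts (they have covariates but no surveys).
#' @param short_followup_frac Fraction of enrolled participants generated
#'   with under 12 months of follow-up (flagged, excluded downstream).
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [simulate_cohort()], [expected_ccc()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 200, seed = 42)
#' cfg$wave_return_prob
cohort_config <- function(n_participants = 1948,
                          seed = 1,
                          wave_return_prob = c(
                            baseline = 0.89, m3 = 0.594, m6 = 0.52,
                            m9 = 0.42, m12 = 0.40
                          ),
                          covariate_effects = c(
                            female = log(1.58), current_smoker = log(0.53)
                          ),
                          item_missing_prob = 0.002,
                          survey_return_prob = tibble::tibble(
                            survey_type = c("med_history_update", "med_history_update"),
                            wave = c("m6", "m12"),
                            prob = c(0.83, 0.04)
                          ),
                          nonreturner_penalty = -3,
                          trait_params = list(
                            pai = list(
                              dirichlet_mean = c(
                                sleep = 8, sedentary = 9.5, slight = 4,
                                moderate = 1.8, heavy = 0.7
                              ) / 24,
                              concentration = 18.5
                            ),
                            cesd = list(mean = 10, sd = 5,
                                        wave_effects = c(m6 = 1.01, m12 = 0.84)),
                            drinks = list(mean = 6, sd = 3)
                          ),
                          agreement_params = list(
                            pai = list(delta = 2.27, sigma_c = 3.16, sigma_a = 3.16),
                            cesd = list(delta = 0.03, sigma_c = 2.73, sigma_a = 2.73),
                            drinks = list(delta = 0.54, sigma_c = 1.35, sigma_a = 1.35)
                          ),
                          timing_params = list(
                            start_lag = c(meanlog = log(1.8 * 86400), sdlog = 1.6),
                            touch = c(meanlog = log(180), sdlog = 0.6)
                          ),
                          schedule = default_schedule(),
                          n_comparison = NULL,
                          short_followup_frac = 0) {
  if (length(n_participants) != 1 || is.na(n_participants) || n_participants < 0 ||
      n_participants != floor(n_participants)) {
    abort("`n_participants` must be a nonnegative integer.", class = "ecohortr_config_error")
  }
  if (length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "ecohortr_config_error")
  }
  missing_waves <- setdiff(wave_levels(), names(wave_return_prob))
  if (length(missing_waves)) {
    abort(sprintf("`wave_return_prob` lacks waves: %s", paste(missing_waves, collapse = ", ")),
          class = "ecohortr_config_error")
  }
  assert_prob(wave_return_prob, "wave_return_prob")
  assert_prob(item_missing_prob, "item_missing_prob")
  assert_prob(short_followup_frac, "short_followup_frac")
  srp_default <- 0.977
  if (is.numeric(survey_return_prob) && length(survey_return_prob) == 1) {
    assert_prob(survey_return_prob, "survey_return_prob")
    srp_default <- survey_return_prob
    survey_return_prob <- tibble::tibble(
      survey_type = character(), wave = character(), prob = numeric()
    )
  } else {
    assert_prob(survey_return_prob$prob, "survey_return_prob$prob")
  }
  for (m in names(agreement_params)) {
    p <- agreement_params[[m]]
    if (p$sigma_c < 0 || p$sigma_a < 0) {
      abort(sprintf("Noise SDs for measure '%s' must be nonnegative.", m),
            class = "ecohortr_config_error")
    }
  }
  if (trait_params$cesd$sd < 0 || trait_params$drinks$sd < 0 ||
      trait_params$pai$concentration <= 0) {
    abort("Trait SDs must be nonnegative and the Dirichlet concentration positive.",
          class = "ecohortr_config_error")
  }
  if (is.null(n_comparison)) n_comparison <- round(0.804 * n_participants)

  structure(
    list(
      n_participants = as.integer(n_participants),
      seed = as.integer(seed),
      wave_return_prob = wave_return_prob[wave_levels()],
      covariate_effects = covariate_effects,
      item_missing_prob = item_missing_prob,
      survey_return_prob_default = srp_default,
      survey_return_prob = survey_return_prob,
      nonreturner_penalty = nonreturner_penalty,
      trait_params = trait_params,
      agreement_params = agreement_params,
      timing_params = timing_params,
      schedule = schedule,
      n_comparison = as.integer(n_comparison),
      short_followup_frac = short_followup_frac
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  participants:", x$n_participants, "enrolled +", x$n_comparison, "comparison\n")
  cat("  seed:", x$seed, "\n")
  cat("  wave return prob:",
      paste(sprintf("%s=%.2f", names(x$wave_return_prob), x$wave_return_prob), collapse = " "),
      "\n")
  cat("  surveys scheduled:", nrow(x$schedule), "\n")
  invisible(x)
}

#' Population concordance implied by the generator's measurement model
#'
#' For clinic value \eqn{x = t + e_c} and app value
#' \eqn{y = t + \delta + e_a} with a shared latent trait of variance
#' \eqn{\tau^2}, the population concordance correlation coefficient is
#' \deqn{\rho_c = \frac{2\tau^2}{2\tau^2 + \sigma_c^2 + \sigma_a^2 + \delta^2}.}
#' Used as the closed-form oracle for agreement-recovery tests.
#'
#' @param trait_variance Variance \eqn{\tau^2} of the latent trait (> 0).
#' @param delta App bias \eqn{\delta}.
#' @param sigma_c,sigma_a Clinic and app noise SDs (>= 0).
#' @return The population CCC, in (0, 1].
#' @export
#' @examples
#' expected_ccc(1, 0.5, sqrt(0.125), sqrt(0.125)) # 0.8
expected_ccc <- function(trait_variance, delta = 0, sigma_c = 0, sigma_a = 0) {
  if (!is.finite(trait_variance) || trait_variance <= 0) {
    abort("`trait_variance` must be positive.", class = "ecohortr_domain_error")
  }
  if (sigma_c < 0 || sigma_a < 0) {
    abort("Noise SDs must be nonnegative.", class = "ecohortr_domain_error")
  }
  2 * trait_variance / (2 * trait_variance + sigma_c^2 + sigma_a^2 + delta^2)
}
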