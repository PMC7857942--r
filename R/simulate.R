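# Synthetic eCohort generator. Emits four tables with the statistical
# structure the downstream pipeline assumes: participants (enrolled +
# non-enrolled comparison), survey returns with timestamps, long-format item
# responses, and paired clinic measurements. All randomness flows from the
# config's master seed through named substreams, so adding a table does not
# perturb draws in another.

# covariate distributions used for enrolled and comparison participants
covariate_profiles <- function() {
  list(
    enrolled = list(
      age_mean = 52.8, age_sd = 8.7, p_female = 0.5693, p_smoker = 0.0555,
      edu_prob = c(0.0067, 0.0866, 0.2408, 0.3822, 0.2837),
      p_married = 0.7473, p_employed = 0.7019,
      bmi_meanlog = log(27.3), bmi_sdlog = 0.188
    ),
    comparison = list(
      age_mean = 56.6, age_sd = 9.8, p_female = 0.4994, p_smoker = 0.0799,
      edu_prob = c(0.0226, 0.1946, 0.2851, 0.3096, 0.1881),
      p_married = 0.6515, p_employed = 0.5932,
      bmi_meanlog = log(28.2), bmi_sdlog = 0.209
    )
  )
}

wave_start_day <- function(wave) {
  c(baseline = 0L, m3 = 90L, m6 = 180L, m9 = 270L, m12 = 360L)[wave]
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Reallocate activity hours so the weighted score hits `target` exactly while
# the hours stay nonnegative and keep summing to 24. Hours are shifted into
# the heaviest category (to raise the score) or into sleep (to lower it).
pai_shift_hours <- function(hours, target, w = pai_weights()) {
  score <- sum(w * hours)
  delta <- target - score
  tol <- 1e-9
  if (abs(delta) <= tol) return(hours)
  if (delta > 0) {
    for (i in order(w)) {
      if (i == which.max(w)) next
      gain <- w[which.max(w)] - w[i]
      m <- min(hours[i], delta / gain)
      hours[i] <- hours[i] - m
      hours[which.max(w)] <- hours[which.max(w)] + m
      delta <- delta - m * gain
      if (delta <= tol) break
    }
  } else {
    for (i in rev(order(w))) {
      if (i == which.min(w)) next
      drop <- w[i] - w[which.min(w)]
      m <- min(hours[i], -delta / drop)
      hours[i] <- hours[i] - m
      hours[which.min(w)] <- hours[which.min(w)] + m
      delta <- delta + m * drop
      if (delta >= -tol) break
    }
  }
  hours
}

# Split an integer CES-D sum over 20 items in {0..3}; positions for the
# remainder are randomised so item-level missingness stays meaningful.
cesd_allocate_items <- function(total, n_items = 20L) {
  base <- total %/% n_items
  rem <- total %% n_items
  items <- rep(base, n_items)
  if (rem > 0) {
    bump <- sample.int(n_items, rem)
    items[bump] <- items[bump] + 1L
  }
  as.integer(items)
}

sim_participants <- function(config) {
  prof <- covariate_profiles()
  origin <- 1464739200L # 2016-06-01 00:00 UTC, in whole seconds
  draw_group <- function(n, p, enrolled, id_offset) {
    tibble::tibble(
      id = sprintf("P%05d", id_offset + seq_len(n)),
      enrolled = as.integer(enrolled),
      age = round(rnorm(n, p$age_mean, p$age_sd), 1),
      female = rbinom(n, 1, p$p_female),
      current_smoker = rbinom(n, 1, p$p_smoker),
      education = sample.int(5L, n, replace = TRUE, prob = p$edu_prob),
      married = rbinom(n, 1, p$p_married),
      employed = rbinom(n, 1, p$p_employed),
      bmi = round(rlnorm(n, p$bmi_meanlog, p$bmi_sdlog), 1)
    )
  }
  with_substream(config$seed, "participants", {
    n <- config$n_participants
    enrolled <- draw_group(n, prof$enrolled, 1L, 0L)
    short <- rbinom(n, 1, config$short_followup_frac)
    enrolled$registration_ts <- origin + floor(runif(n, 0, 730 * 86400))
    enrolled$followup_days <- as.integer(ifelse(
      short == 1L,
      30 + floor(runif(n, 0, 335)),
      365 + floor(runif(n, 0, 731))
    ))
    comparison <- draw_group(config$n_comparison, prof$comparison, 0L, n)
    comparison$registration_ts <- NA_integer_
    comparison$followup_days <- NA_integer_
    dplyr::bind_rows(enrolled, comparison)
  })
}

sim_traits <- function(config, participants) {
  enrolled <- dplyr::filter(participants, .data$enrolled == 1L)
  n <- nrow(enrolled)
  tp <- config$trait_params
  with_substream(config$seed, "traits", {
    alpha <- tp$pai$concentration * tp$pai$dirichlet_mean
    g <- matrix(rgamma(n * 5, shape = rep(alpha, each = n)), nrow = n, ncol = 5)
    hours <- 24 * g / rowSums(g)
    colnames(hours) <- names(pai_weights())
    list(
      id = enrolled$id,
      pai_hours = hours,
      pai = as.numeric(hours %*% pai_weights()),
      cesd = pmin(pmax(rnorm(n, tp$cesd$mean, tp$cesd$sd), 0), 60),
      drinks = pmax(rnorm(n, tp$drinks$mean, tp$drinks$sd), 0)
    )
  })
}

sim_clinic <- function(config, traits) {
  ap <- config$agreement_params
  n <- length(traits$id)
  with_substream(config$seed, "clinic", {
    tibble::tibble(
      participant_id = rep(traits$id, 3),
      measure = rep(c("pai", "cesd_sum", "drinks_per_week"), each = n),
      value = c(
        traits$pai + rnorm(n, 0, ap$pai$sigma_c),
        traits$cesd + rnorm(n, 0, ap$cesd$sigma_c),
        traits$drinks + rnorm(n, 0, ap$drinks$sigma_c)
      )
    )
  })
}

# wave-level return indicators: Bernoulli on a logit scale with centred
# covariate effects; optional penalty for baseline non-returners at follow-up
sim_wave_returns <- function(config, participants) {
  enrolled <- dplyr::filter(participants, .data$enrolled == 1L)
  prof <- covariate_profiles()$enrolled
  eff <- config$covariate_effects
  shift <- (eff[["female"]] %||% 0) * (enrolled$female - prof$p_female) +
    (eff[["current_smoker"]] %||% 0) * (enrolled$current_smoker - prof$p_smoker)
  with_substream(config$seed, "returns", {
    base_logit <- qlogis(config$wave_return_prob[["baseline"]]) + shift
    r_base <- rbinom(nrow(enrolled), 1, plogis(base_logit))
    out <- list(baseline = r_base)
    for (w in setdiff(wave_levels(), "baseline")) {
      lg <- qlogis(config$wave_return_prob[[w]]) + shift +
        config$nonreturner_penalty * (1 - r_base)
      out[[w]] <- rbinom(nrow(enrolled), 1, plogis(lg))
    }
    tibble::tibble(
      participant_id = rep(enrolled$id, length(wave_levels())),
      wave = rep(wave_levels(), each = nrow(enrolled)),
      returned = unlist(out, use.names = FALSE)
    )
  })
}

survey_return_lookup <- function(config) {
  sched <- config$schedule
  over <- config$survey_return_prob
  sched |>
    dplyr::left_join(over, by = c("survey_type", "wave")) |>
    dplyr::mutate(prob = dplyr::coalesce(.data$prob, config$survey_return_prob_default))
}

#' Generate a synthetic eCohort
#'
#' Simulates the four tables the analysis pipeline consumes: a participant
#' table (enrolled participants plus a non-enrolled comparison group), a
#' survey-return table with deployment/start/return/step timestamps, a
#' long-format item-response table, and a clinic-measurement table paired to
#' the app measures.
#'
#' The generative model: each enrolled participant carries one latent trait
#' per analysed measure (physical-activity hours from a Dirichlet scaled to
#' 24 h, CES-D and drinks/week from truncated normals). The clinic value is
#' `trait + N(0, sigma_c^2)`; item responses for returned surveys are
#' constructed so that the scored app value equals
#' `trait + wave shift + delta + N(0, sigma_a^2)` (exactly for PAI and
#' alcohol, to integer rounding for CES-D), giving a closed-form population
#' concordance via [expected_ccc()]. Wave-level return indicators are
#' Bernoulli with a logit combining the wave propensity and centred
#' covariate effects; individual scheduled surveys are then returned with a
#' conditional per-survey probability. Item responses are independently
#' missing with `item_missing_prob`. Timestamps are lognormal start-lags and
#' touch durations, truncated so every return lands inside its intended
#' 90-day wave window.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `ecohort_tables` with tibbles `participants`,
#'   `survey_returns`, `responses`, `clinic`, and the `config` used.
#' @export
#' @examples
#' tabs <- simulate_cohort(cohort_config(n_participants = 50, seed = 7))
#' names(tabs)
#' nrow(tabs$participants)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().", class = "ecohortr_config_error")
  }
  participants <- sim_participants(config)
  traits <- sim_traits(config, participants)
  clinic <- sim_clinic(config, traits)
  wave_ret <- sim_wave_returns(config, participants)

  enrolled <- dplyr::filter(participants, .data$enrolled == 1L)
  lookup <- survey_return_lookup(config)
  instr <- survey_instruments()

  # instance table: one candidate row per participant x scheduled survey at
  # a returned wave, thinned by the per-survey conditional return probability
  inst <- wave_ret |>
    dplyr::filter(.data$returned == 1L) |>
    dplyr::inner_join(lookup, by = "wave", relationship = "many-to-many") |>
    dplyr::inner_join(instr, by = "survey_type")
  with_substream(config$seed, "survey_thinning", {
    inst <- dplyr::filter(inst, runif(dplyr::n()) < .data$prob)
  })
  inst <- inst |>
    dplyr::inner_join(
      dplyr::select(enrolled, "id", "registration_ts"),
      by = c(participant_id = "id")
    ) |>
    dplyr::mutate(instance_id = sprintf("%s-%s-%s", .data$participant_id,
                                        .data$survey_type, .data$wave))

  # timestamps: deployment at the wave start; truncated lognormal start lag
  # keeps each return inside its 90-day window
  tm <- config$timing_params
  with_substream(config$seed, "timing", {
    n_i <- nrow(inst)
    touch <- rlnorm(n_i, tm$touch[["meanlog"]], tm$touch[["sdlog"]])
    touch <- pmin(touch, 40 * 86400)
    limit <- 90 * 86400 - touch - 2
    u <- runif(n_i) * stats::plnorm(limit, tm$start_lag[["meanlog"]], tm$start_lag[["sdlog"]])
    lag <- stats::qlnorm(u, tm$start_lag[["meanlog"]], tm$start_lag[["sdlog"]])
    inst$deployment_ts <- inst$registration_ts + wave_start_day(inst$wave) * 86400L
    inst$start_ts <- inst$deployment_ts + floor(lag)
    inst$return_ts <- inst$start_ts + pmax(1, floor(touch))
    # completion timestamp of each app step, as a semicolon-joined list
    inst$step_ts <- vapply(seq_len(n_i), function(i) {
      k <- inst$n_steps[i]
      frac <- rgamma(k, 1)
      cum <- cumsum(frac) / sum(frac)
      ts <- inst$start_ts[i] + round(cum * (inst$return_ts[i] - inst$start_ts[i]))
      paste(sort(ts), collapse = ";")
    }, character(1))
  })

  responses <- sim_responses(config, inst, traits)

  survey_returns <- inst |>
    dplyr::select("participant_id", "instance_id", "survey_type",
                  "deployment_ts", "start_ts", "return_ts", "step_ts") |>
    dplyr::arrange(.data$participant_id, .data$deployment_ts, .data$survey_type)

  structure(
    list(
      participants = participants,
      survey_returns = survey_returns,
      responses = responses,
      clinic = clinic,
      config = config
    ),
    class = "ecohort_tables"
  )
}

# Item responses per returned instance. The scored app value for the three
# analysed instruments is trait + wave shift + delta + noise by construction.
sim_responses <- function(config, inst, traits) {
  ap <- config$agreement_params
  tp <- config$trait_params
  trait_ix <- match(inst$participant_id, traits$id)

  with_substream(config$seed, "responses", {
    resp <- vector("list", nrow(inst))
    for (i in seq_len(nrow(inst))) {
      type <- inst$survey_type[i]
      wave <- inst$wave[i]
      k <- trait_ix[i]
      if (type == "pai") {
        shift <- (tp$pai$wave_effects %||% c())[wave] %||% 0
        shift <- if (is.na(shift)) 0 else shift
        target <- rnorm_trunc(1, traits$pai[k] + shift + ap$pai$delta,
                              ap$pai$sigma_a, 24 + 1e-6, 120 - 1e-6)
        vals <- pai_shift_hours(traits$pai_hours[k, ], target)
      } else if (type == "cesd") {
        shift <- (tp$cesd$wave_effects %||% c())[wave] %||% 0
        shift <- if (is.na(shift)) 0 else shift
        target <- round(min(max(
          traits$cesd[k] + shift + rnorm(1, 0, ap$cesd$sigma_a) + ap$cesd$delta, 0), 60))
        items <- cesd_allocate_items(as.integer(target))
        rev_ix <- c(4L, 8L, 12L, 16L)
        items[rev_ix] <- 3L - items[rev_ix] # stored in raw instrument coding
        vals <- as.numeric(items)
      } else if (type == "alcohol") {
        shift <- (tp$drinks$wave_effects %||% c())[wave] %||% 0
        shift <- if (is.na(shift)) 0 else shift
        target <- max(traits$drinks[k] + shift + ap$drinks$delta +
                        rnorm(1, 0, ap$drinks$sigma_a), 0)
        if (target == 0) {
          vals <- c(0, 0)
        } else {
          days <- sample.int(7L, 1)
          vals <- c(target / days, days)
        }
      } else {
        vals <- as.numeric(sample(0:4, inst$n_items[i], replace = TRUE))
      }
      miss <- runif(length(vals)) < config$item_missing_prob
      vals[miss] <- NA_real_
      resp[[i]] <- vals
    }
    tibble::tibble(
      participant_id = rep(inst$participant_id, inst$n_items),
      instance_id = rep(inst$instance_id, inst$n_items),
      item_index = as.integer(unlist(lapply(inst$n_items, seq_len), use.names = FALSE)),
      value = as.numeric(unlist(resp, use.names = FALSE))
    )
  })
}

#' Simulate paired app/clinic measurements directly
#'
#' Draws `n` (clinic, app) pairs from the generator's measurement model
#' without building a full cohort: a latent trait `t ~ N(trait_mean,
#' trait_sd^2)`, clinic value `t + N(0, sigma_c^2)` and app value
#' `t + delta + N(0, sigma_a^2)`. Useful for agreement-estimator calibration
#' studies where only the paired values matter.
#'
#' @param n Number of pairs.
#' @param trait_mean,trait_sd Latent trait mean and SD.
#' @param delta App bias.
#' @param sigma_c,sigma_a Clinic and app noise SDs.
#' @return A tibble with columns `clinic` and `app`.
#' @export
#' @examples
#' pairs <- simulate_agreement_pairs(100, 0, 1, 0.5, sqrt(0.125), sqrt(0.125))
simulate_agreement_pairs <- function(n, trait_mean = 0, trait_sd = 1,
                                     delta = 0, sigma_c = 0, sigma_a = 0) {
  t <- rnorm(n, trait_mean, trait_sd)
  tibble::tibble(
    clinic = t + rnorm(n, 0, sigma_c),
    app = t + delta + rnorm(n, 0, sigma_a)
  )
}

#' @export
print.ecohort_tables <- function(x, ...) {
  cat("<ecohort_tables>\n")
  cat(sprintf("  participants:   %d (%d enrolled)\n", nrow(x$participants),
              sum(x$participants$enrolled)))
  cat(sprintf("  survey_returns: %d instances\n", nrow(x$survey_returns)))
  cat(sprintf("  responses:      %d items\n", nrow(x$responses)))
  cat(sprintf("  clinic:         %d measurements\n", nrow(x$clinic)))
  invisible(x)
}
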