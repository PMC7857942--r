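# The generator: determinism, calibration of return propensities, the
# closed-form concordance oracle, window-respecting timestamps, and CSV
# round-tripping.

test_that("same config and seed reproduce identical tables", {
  cfg <- cohort_config(n_participants = 120, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$survey_returns, b$survey_returns)
  expect_identical(a$responses, b$responses)
  expect_identical(a$clinic, b$clinic)
})

test_that("unit return propensities and zero effects yield full return", {
  cfg <- cohort_config(
    n_participants = 40, seed = 7,
    wave_return_prob = c(baseline = 1, m3 = 1, m6 = 1, m9 = 1, m12 = 1),
    covariate_effects = c(female = 0, current_smoker = 0),
    survey_return_prob = 1,
    item_missing_prob = 0
  )
  tabs <- simulate_cohort(cfg)
  expect_equal(nrow(tabs$survey_returns), 40 * nrow(cfg$schedule))
})

test_that("default schedule deploys 22 surveys as 9+1+4+1+7", {
  sched <- default_schedule()
  expect_equal(nrow(sched), 22L)
  counts <- dplyr::count(sched, wave)
  expect_equal(
    counts$n[match(wave_levels(), counts$wave)],
    c(9L, 1L, 4L, 1L, 7L)
  )
})

test_that("expected_ccc matches hand arithmetic and limits", {
  expect_equal(expected_ccc(1, 0, 0, 0), 1.0)
  expect_equal(expected_ccc(1, 0.5, sqrt(0.125), sqrt(0.125)), 0.8)
  expect_lt(expected_ccc(1, 1e6, 1, 1), 1e-9)
  expect_error(expected_ccc(0, 0, 0, 0), class = "ecohortr_domain_error")
  expect_error(expected_ccc(1, 0, -1, 0), class = "ecohortr_domain_error")
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(cohort_config(n_participants = -5), class = "ecohortr_config_error")
  expect_error(cohort_config(item_missing_prob = 1.2), class = "ecohortr_config_error")
  expect_error(
    cohort_config(wave_return_prob = c(baseline = 2, m3 = 0, m6 = 0, m9 = 0, m12 = 0)),
    class = "ecohortr_config_error"
  )
})

test_that("cohort tables round-trip through CSV, including the empty cohort", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_participants = 30, seed = 9, n_comparison = 10)
  tabs <- simulate_cohort(cfg)
  write_cohort(tabs, dir)
  back <- read_cohort(dir)
  for (nm in c("participants", "survey_returns", "responses", "clinic")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(tabs[[nm]]))
  }

  dir0 <- withr::local_tempdir()
  empty <- simulate_cohort(cohort_config(n_participants = 0, seed = 1, n_comparison = 0))
  write_cohort(empty, dir0)
  back0 <- read_cohort(dir0)
  expect_equal(nrow(back0$participants), 0L)
  expect_equal(nrow(back0$survey_returns), 0L)
})

test_that("study-size default writes one participant row per enrollee", {
  cfg <- cohort_config(seed = 1)
  expect_equal(cfg$n_participants, 1948L)
  p <- ecohortr:::sim_participants(cfg)
  expect_equal(sum(p$enrolled == 1L), 1948L)
})

# one moderately large cohort shared by the statistical-structure checks
big <- simulate_cohort(cohort_config(n_participants = 5000, seed = 11))

test_that("baseline return fraction matches its propensity at n = 5000", {
  returned_baseline <- big$survey_returns |>
    assign_waves(big$participants) |>
    dplyr::filter(wave == "baseline") |>
    dplyr::distinct(participant_id)
  frac <- nrow(returned_baseline) / 5000
  expect_lt(abs(frac - 0.89), 0.02)
})

test_that("all returns land inside their intended wave window", {
  asn <- assign_waves(big$survey_returns, big$participants)
  expect_true(all(asn$wave %in% wave_levels()))
  # the instance id encodes the intended wave; the assigned wave must agree
  intended <- sub(".*-", "", asn$instance_id)
  expect_equal(asn$wave, intended)
})

test_that("scored app values agree with the closed-form concordance", {
  cfg <- big$config
  asn <- assign_waves(big$survey_returns, big$participants)
  scores <- score_responses(big$responses, asn, big$survey_returns)
  traits <- ecohortr:::sim_traits(cfg, big$participants)
  tau2 <- list(pai = var(traits$pai), cesd_sum = var(traits$cesd),
               drinks_per_week = var(traits$drinks))
  pmap <- c(pai = "pai", cesd_sum = "cesd", drinks_per_week = "drinks")
  agr <- agreement_analysis(scores, big$clinic)
  for (m in names(tau2)) {
    ap <- cfg$agreement_params[[pmap[[m]]]]
    expected <- expected_ccc(tau2[[m]], ap$delta, ap$sigma_c, ap$sigma_a)
    got <- agr$agreement$estimate[agr$agreement$measure == m &
                                    agr$agreement$statistic == "ccc"]
    expect_lt(abs(got - expected), 0.02)
  }
})

test_that("return behaviour is exchangeable across sex when effects are zero", {
  cfg <- cohort_config(
    n_participants = 5000, seed = 3,
    covariate_effects = c(female = 0, current_smoker = 0),
    nonreturner_penalty = 0
  )
  parts <- ecohortr:::sim_participants(cfg)
  ret <- ecohortr:::sim_wave_returns(cfg, parts)
  base <- ret[ret$wave == "baseline", ]
  enrolled <- parts[parts$enrolled == 1L, ]
  tab <- table(enrolled$female[match(base$participant_id, enrolled$id)],
               base$returned)
  p <- stats::chisq.test(tab, correct = FALSE)$p.value
  expect_gt(p, 0.05)
})
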