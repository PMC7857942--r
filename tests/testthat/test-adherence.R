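# The 75% completion rule, both adherence metrics against a brute-force
# oracle, and the timing summaries.

test_that("75% completion rule is inclusive at the boundary", {
  expect_true(is_complete(c(rep(1, 15), rep(NA, 5))))   # 15/20
  expect_false(is_complete(c(rep(1, 14), rep(NA, 6))))  # 14/20
  expect_true(is_complete(c(1, 2, 3, NA)))              # 3/4 exactly 75%
  expect_error(is_complete(numeric(0)), class = "ecohortr_data_error")
})

test_that("toy cohort adherence equals hand counts", {
  ids <- sprintf("P%02d", 1:10)
  parts <- toy_participants(ids)
  sched <- tibble::tibble(
    survey_type = c("pai", "cesd", "pai", "pai", "pai", "pai"),
    wave = c("baseline", "baseline", "m3", "m6", "m9", "m12")
  )
  comp <- toy_completions(tibble::tibble(
    participant_id = c("P01", "P01", "P02", "P03", "P03", "P04", "P05"),
    survey_type = c("pai", "cesd", "pai", "pai", "cesd", "cesd", "pai"),
    wave = c("baseline", "baseline", "baseline", "baseline", "baseline",
             "baseline", "m3"),
    complete = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  ))
  adh <- survey_adherence(comp, sched, parts)
  # by hand: baseline any = P01,P02,P03,P04 -> 4/10; all = P01 -> 1/10
  expect_equal(adh$n_any[adh$wave == "baseline"], 4L)
  expect_equal(adh$n_all[adh$wave == "baseline"], 1L)
  expect_equal(adh$p_any[adh$wave == "baseline"], 0.4)
  # m3 has a single scheduled survey: p_all equals p_any
  expect_equal(adh$n_all[adh$wave == "m3"], adh$n_any[adh$wave == "m3"])
})

test_that("adherence equals brute-force enumeration on random small cohorts", {
  sched <- default_schedule()
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(5:20, 1)
    ids <- sprintf("P%02d", seq_len(n))
    parts <- toy_participants(ids)
    rows <- sched[sample.int(22, 40, replace = TRUE), ]
    rows$participant_id <- sample(ids, 40, replace = TRUE)
    rows$complete <- runif(40) < 0.7
    rows <- dplyr::distinct(rows, participant_id, survey_type, wave,
                            .keep_all = TRUE)
    comp <- toy_completions(rows)
    adh <- survey_adherence(comp, sched, parts)
    oracle <- oracle_adherence(comp, sched, ids)
    expect_equal(adh$n_any, oracle$n_any)
    expect_equal(adh$n_all, oracle$n_all)
    expect_equal(adh$p_any, oracle$p_any)
    expect_equal(adh$p_all, oracle$p_all)
    # ordering and monotonicity properties
    expect_true(all(adh$n_all <= adh$n_any))
    expect_true(all(adh$n_any <= adh$denominator))
    incomplete <- which(!rows$complete)
    if (length(incomplete)) {
      rows2 <- rows
      rows2$complete[incomplete[1]] <- TRUE
      adh2 <- survey_adherence(toy_completions(rows2), sched, parts)
      expect_true(all(adh2$p_any >= adh$p_any))
      expect_true(all(adh2$p_all >= adh$p_all))
    }
  }
})

test_that("percent formatting reproduces the printed baseline proportion", {
  # 1704 of 1918 eligible participants completing >= 1 baseline survey
  expect_equal(round_half_up(100 * 1704 / 1918, 2), 88.84)
})

test_that("timing quartiles match hand computation on a constructed set", {
  reg <- 0
  ret_days <- c(1, 2, 3, 4, 10) # deployment at 0
  sr <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:5),
    instance_id = sprintf("I%d", 1:5),
    survey_type = "pai",
    deployment_ts = 0,
    start_ts = ret_days * 86400 - 300,
    return_ts = ret_days * 86400,
    step_ts = vapply(ret_days * 86400, function(r)
      paste(seq(r - 240, r, length.out = 7), collapse = ";"), character(1))
  )
  asn <- tibble::tibble(
    participant_id = sr$participant_id, instance_id = sr$instance_id,
    survey_type = "pai", days = ret_days, wave = "baseline"
  )
  tm <- timing_metrics(sr, asn)
  rt <- tm[tm$metric == "return_time", ]
  expect_equal(rt$median, 3)         # median of 1,2,3,4,10
  expect_equal(rt$q1, 2)             # type-7 quartiles
  expect_equal(rt$q3, 4)
  tt <- tm[tm$metric == "touch_time", ]
  expect_equal(tt$median, 5)         # 300 s = 5 min for every instance
  expect_equal(tt$q3 - tt$q1, 0)
})

test_that("ordering violations are dropped and logged", {
  sr <- tibble::tibble(
    participant_id = c("P01", "P02"),
    instance_id = c("ok", "bad"),
    survey_type = "pai",
    deployment_ts = c(0, 0),
    start_ts = c(100, 500),
    return_ts = c(400, 300), # bad: return before start
    step_ts = c("200;400", "250;300")
  )
  asn <- tibble::tibble(participant_id = sr$participant_id,
                        instance_id = sr$instance_id,
                        survey_type = "pai", days = 0L, wave = "baseline")
  tm <- timing_metrics(sr, asn)
  expect_equal(attr(tm, "dropped")$instance_id, "bad")
  expect_true(all(tm$n == 1 | tm$metric %in% c("step_time", "question_time")))
})

test_that("default timing parameters give sub-5-minute touch times", {
  tabs <- simulate_cohort(cohort_config(n_participants = 300, seed = 21))
  asn <- assign_waves(tabs$survey_returns, tabs$participants)
  tm <- timing_metrics(tabs$survey_returns, asn)
  touch <- tm[tm$metric == "touch_time", ]
  expect_lt(stats::median(touch$median), 5)
  rt <- tm[tm$metric == "return_time", ]
  expect_true(all(rt$median < 90))
})
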