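# Scorers for the three analysed measures, covering every imputation branch.

test_that("PAI weighted sum and single-missing imputation", {
  expect_equal(score_pai(c(8, 10, 4, 1.5, 0.5))$value, 31.1)
  expect_equal(score_pai(c(24, 0, 0, 0, 0))$value, 24)
  s <- score_pai(c(8, 10, 4, NA, 0.5))
  expect_equal(s$value, 31.1) # moderate imputed as 24 - 22.5 = 1.5
  expect_true(s$imputed)
  expect_equal(s$n_items_missing, 1L)
  expect_true(is.na(score_pai(c(8, NA, NA, 1, 1))$value))
  expect_warning(s2 <- score_pai(c(10, 10, 5, NA, 0.5)))
  expect_true(is.na(s2$value)) # others already exceed 24
  expect_error(score_pai(c(-1, 10, 4, 1.5, 0.5)), class = "ecohortr_data_error")
})

test_that("PAI is monotone in activity intensity", {
  base <- c(8, 9, 4, 2, 1)
  w <- pai_weights()
  for (i in 1:4) {
    shifted <- base
    shifted[i] <- shifted[i] - 1
    shifted[i + 1] <- shifted[i + 1] + 1
    expect_gt(score_pai(shifted)$value, score_pai(base)$value)
  }
  expect_equal(score_pai(c(0, 0, 0, 0, 24))$value, 120)
})

test_that("CES-D branches: plain sum, rescale, too many missing", {
  # literal scoring (no reverse-coded items): all-zero items give 0
  expect_equal(score_cesd(rep(0, 20), reverse_coded = integer(0))$value, 0)
  expect_equal(score_cesd(rep(0, 20), reverse_coded = integer(0))$flag, 0L)
  # default standard form reverse-scores items 4, 8, 12, 16
  expect_equal(score_cesd(rep(0, 20))$value, 12)
  # 18 present averaging 1 after reverse coding -> 1 x 20 = 20, flagged
  items <- rep(1, 20)
  items[c(4, 8, 12, 16)] <- 2 # reverse-coded back to 1
  items[c(19, 20)] <- NA
  s <- score_cesd(items)
  expect_equal(s$value, 20)
  expect_equal(s$flag, 1L)
  expect_true(s$imputed)
  s6 <- score_cesd(c(rep(1, 14), rep(NA, 6)))
  expect_true(is.na(s6$value))
  expect_true(is.na(s6$flag))
  expect_error(score_cesd(c(rep(5, 20))), class = "ecohortr_data_error")
  expect_error(score_cesd(rep(0, 19)), class = "ecohortr_data_error")
})

test_that("CES-D rescale is the identity with no missing items", {
  for (items in random_cesd_items(50)) {
    full <- score_cesd(items, reverse_coded = integer(0))$value
    expect_equal(full, sum(items))
    expect_equal(mean(items) * 20, sum(items))
  }
})

test_that("CES-D with all items present equals a brute-force sum", {
  set.seed(42)
  for (items in random_cesd_items(1000)) {
    s <- score_cesd(items)
    brute <- 0
    for (j in 1:20) {
      v <- if (j %in% c(4, 8, 12, 16)) 3 - items[j] else items[j]
      brute <- brute + v
    }
    expect_identical(s$value, as.numeric(brute))
    expect_identical(s$flag, as.integer(brute >= 16))
  }
})

test_that("drinks per week is the day-count product with a zero short-circuit", {
  expect_equal(drinks_per_week(2, 3), 6)
  expect_equal(drinks_per_week(99, 0), 0)
  expect_equal(drinks_per_week(1.5, 7), 10.5)
  expect_error(drinks_per_week(1, 8), class = "ecohortr_data_error")
  expect_error(drinks_per_week(-1, 2), class = "ecohortr_data_error")
})

test_that("score_responses picks the earliest instance and scores by type", {
  reg <- 0
  sr <- tibble::tibble(
    participant_id = "P01",
    instance_id = c("pai-late", "pai-early", "alc-1"),
    survey_type = c("pai", "pai", "alcohol"),
    deployment_ts = 0,
    start_ts = c(5000, 1000, 2000),
    return_ts = c(6000, 2000, 3000),
    step_ts = ""
  )
  asn <- tibble::tibble(
    participant_id = "P01",
    instance_id = sr$instance_id,
    survey_type = sr$survey_type,
    days = 0L, wave = "baseline"
  )
  resp <- dplyr::bind_rows(
    tibble::tibble(participant_id = "P01", instance_id = "pai-late",
                   item_index = 1:5, value = c(0, 0, 0, 0, 24)),
    tibble::tibble(participant_id = "P01", instance_id = "pai-early",
                   item_index = 1:5, value = c(24, 0, 0, 0, 0)),
    tibble::tibble(participant_id = "P01", instance_id = "alc-1",
                   item_index = 1:2, value = c(2, 3))
  )
  sc <- score_responses(resp, asn, sr)
  expect_equal(sc$value[sc$measure == "pai"], 24) # earliest instance wins
  expect_equal(sc$value[sc$measure == "drinks_per_week"], 6)
})
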