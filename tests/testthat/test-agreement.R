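# Agreement statistics: CCC, kappa, Bland-Altman.

test_that("CCC is 1 for identical series and vanishes under large shifts", {
  d <- tibble::tibble(clinic = rnorm(50, 10, 2))
  d$app <- d$clinic
  expect_equal(ccc(d)$estimate, 1.0)
  d$app <- d$clinic + 1e6
  expect_lt(abs(ccc(d)$estimate), 1e-6)
})

test_that("CCC errors on degenerate inputs", {
  expect_error(ccc(tibble::tibble(clinic = 1:2, app = 2:3)),
               class = "ecohortr_sample_error")
  expect_error(ccc(tibble::tibble(clinic = rep(1, 10), app = rnorm(10))),
               class = "ecohortr_degenerate_error")
})

test_that("CCC is symmetric and bounded by |Pearson r|", {
  set.seed(5)
  for (i in 1:20) {
    d <- simulate_agreement_pairs(80, runif(1, -5, 5), runif(1, 0.5, 3),
                                  runif(1, -2, 2), runif(1, 0, 2), runif(1, 0, 2))
    a <- ccc(d, clinic, app)$estimate
    b <- ccc(d, app, clinic)$estimate
    expect_equal(a, b)
    expect_lte(abs(a), abs(cor(d$clinic, d$app)) + 1e-12)
  }
})

test_that("kappa examples: perfect, hand-computed table, independence null", {
  ident <- tibble::tibble(clinic = rep(c(0, 1), 20), app = rep(c(0, 1), 20))
  expect_equal(cohen_kappa(ident)$estimate, 1)
  k <- cohen_kappa(matrix(c(40, 10, 10, 40), 2))
  expect_equal(k$estimate, 0.6) # p_o = 0.8, p_e = 0.5
  set.seed(8)
  null <- tibble::tibble(clinic = rbinom(10000, 1, 0.5),
                         app = rbinom(10000, 1, 0.5))
  expect_lt(abs(cohen_kappa(null)$estimate), 0.05)
})

test_that("kappa equals one minus the disagreement ratio", {
  set.seed(9)
  for (i in 1:10) {
    d <- tibble::tibble(clinic = sample(1:3, 200, replace = TRUE),
                        app = sample(1:3, 200, replace = TRUE))
    k <- cohen_kappa(d)$estimate
    lev <- 1:3
    tab <- table(factor(d$clinic, levels = lev), factor(d$app, levels = lev))
    n <- sum(tab)
    obs_dis <- 1 - sum(diag(tab)) / n
    exp_dis <- 1 - sum(rowSums(tab) * colSums(tab)) / n^2
    expect_equal(k, 1 - obs_dis / exp_dis)
  }
})

test_that("kappa degenerates gracefully when both raters are constant", {
  d <- tibble::tibble(clinic = rep(1, 10), app = rep(1, 10))
  k <- cohen_kappa(d)
  expect_true(is.na(k$estimate))
})

test_that("Bland-Altman bias and limits on constructed pairs", {
  d <- tibble::tibble(clinic = rnorm(20, 5))
  d$app <- d$clinic
  ba <- bland_altman(d)
  expect_equal(ba$stats$bias, 0)
  expect_equal(ba$stats$lower, 0)
  expect_equal(ba$stats$upper, 0)
  d$app <- d$clinic + 1
  ba1 <- bland_altman(d)
  expect_equal(ba1$stats$bias, 1)
  expect_equal(ba1$stats$sd_diff, 0)
  expect_equal(c(ba1$stats$lower, ba1$stats$upper), c(1, 1))
  expect_error(bland_altman(d[1, ]), class = "ecohortr_sample_error")
})

test_that("mean difference equals the brute-force mean of differences", {
  set.seed(3)
  d <- simulate_agreement_pairs(100, 2, 1, 2.27, 0.5, 0.5)
  expect_equal(mean_difference(d), mean(d$app - d$clinic))
  expect_equal(mean_difference(d), bland_altman(d)$stats$bias)
  d0 <- tibble::tibble(clinic = 1:5, app = 1:5 + 2.27)
  expect_equal(mean_difference(d0), 2.27)
})

test_that("agreement_analysis drops incomplete pairs and counts them", {
  scores <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:6), wave = "baseline",
    measure = "pai", value = c(30, 31, NA, 33, 34, 35),
    flag = NA_integer_, imputed = FALSE, n_items_missing = 0L
  )
  clinic <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:6), measure = "pai",
    value = c(29, NA, 31, 32, 33, 34)
  )
  agr <- agreement_analysis(scores, clinic)
  row <- agr$agreement[agr$agreement$statistic == "ccc", ]
  expect_equal(row$n_pairs, 4L)
  expect_equal(row$n_dropped, 2L)
})
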