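# Balanced random-intercept model and paired t.

make_panel <- function(n, waves, tau = 3, sigma = 2, shifts = NULL, mu = 10) {
  if (is.null(shifts)) shifts <- rep(0, length(waves))
  b <- rnorm(n, 0, tau)
  tibble::tibble(
    participant_id = rep(sprintf("P%04d", 1:n), each = length(waves)),
    wave = rep(waves, n),
    value = mu + rep(shifts, n) + rep(b, each = length(waves)) +
      rnorm(n * length(waves), 0, sigma)
  )
}

test_that("identical values give zero effects and zero residual variance", {
  long <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 3),
    wave = rep(c("baseline", "m6", "m12"), 2),
    value = 7
  )
  fit <- suppressWarnings(fit_random_intercept(long))
  expect_equal(tidy(fit)$estimate, c(0, 0, 0))
  expect_equal(fit$sigma2, 0)
  expect_equal(tidy(fit)$p[-1], c(1, 1))
})

test_that("wave effects equal wave-mean differences on any balanced panel", {
  set.seed(31)
  for (i in 1:5) {
    waves <- c("baseline", "m3", "m6")
    long <- make_panel(40, waves, shifts = c(0, runif(1, -2, 2), runif(1, -2, 2)))
    fit <- fit_random_intercept(long)
    means <- tapply(long$value, long$wave, mean)[waves]
    expect_equal(tidy(fit)$estimate, as.vector(means - means[1]))
  }
})

test_that("closed form agrees with REML from an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(32)
  long <- make_panel(120, c("baseline", "m6", "m12"), tau = 3, sigma = 2,
                     shifts = c(0, 1, 0.8))
  fit <- fit_random_intercept(long)
  long$wave <- factor(long$wave, levels = c("baseline", "m6", "m12"))
  m <- lme4::lmer(value ~ wave + (1 | participant_id), data = long, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-6)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-6)
  expect_equal(tidy(fit)$estimate[-1], unname(lme4::fixef(m)[-1]),
               tolerance = 1e-6)
})

test_that("variance components are recovered across replicates", {
  set.seed(33)
  est <- replicate(60, {
    long <- make_panel(400, c("baseline", "m3", "m6", "m9", "m12"),
                       tau = 3, sigma = 2)
    fit <- fit_random_intercept(long)
    c(fit$tau2, fit$sigma2)
  })
  expect_lt(abs(mean(est[1, ]) - 9) / 9, 0.1)
  expect_lt(abs(mean(est[2, ]) - 4) / 4, 0.1)
})

test_that("wave-shift recovery at study scale", {
  set.seed(34)
  reps <- replicate(30, {
    long <- make_panel(644, c("baseline", "m6", "m12"), tau = 3, sigma = 2,
                       shifts = c(0, 1.01, 0.84))
    tidy(fit_random_intercept(long))$estimate[2]
  })
  expect_true(all(abs(reps - 1.01) < 0.25))
})

test_that("unbalanced panels are rejected with guidance", {
  long <- tibble::tibble(
    participant_id = c("A", "A", "B"),
    wave = c("baseline", "m6", "baseline"),
    value = 1:3
  )
  expect_error(fit_random_intercept(long), "complete_panel",
               class = "ecohortr_data_error")
  panel <- complete_panel(long, c("baseline", "m6"))
  expect_equal(unique(as.character(panel$participant_id)), "A")
})

test_that("paired t matches hand arithmetic and identity with one-sample t", {
  x <- c(1, 2, 3); y <- c(2, 2, 5)
  out <- paired_t(x, y)
  d <- y - x
  tstat <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$t, tstat)
  expect_equal(out$p, 2 * pt(-abs(tstat), df = 2))
  expect_equal(out$mean_diff, 1)
  ident <- paired_t(x, x)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$p, 1)
})

test_that("paired t null p values are uniform at study scale", {
  set.seed(35)
  ps <- replicate(200, {
    x <- rnorm(613); y <- x + rnorm(613)
    paired_t(x, y)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
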