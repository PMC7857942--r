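# Brute-force oracles and tiny fixture builders shared across test files.

# Enumerate adherence per participant and wave by explicit loops, the slow
# way, as an independent oracle for the vectorised implementation.
oracle_adherence <- function(completions, schedule, eligible_ids) {
  waves <- wave_levels()
  denom <- length(eligible_ids)
  out <- data.frame(wave = waves, n_any = 0L, n_all = 0L)
  for (w in waves) {
    sched_types <- schedule$survey_type[schedule$wave == w]
    for (pid in eligible_ids) {
      rows <- completions[completions$participant_id == pid &
                            completions$wave == w & completions$complete, ]
      if (nrow(rows) > 0) {
        out$n_any[out$wave == w] <- out$n_any[out$wave == w] + 1L
      }
      if (length(sched_types) > 0 && all(sched_types %in% rows$survey_type)) {
        out$n_all[out$wave == w] <- out$n_all[out$wave == w] + 1L
      }
    }
  }
  out$denominator <- denom
  out$p_any <- out$n_any / denom
  out$p_all <- out$n_all / denom
  out
}

# completion table built directly (no response generation), for toy cohorts
toy_completions <- function(df) {
  tibble::tibble(
    participant_id = df$participant_id,
    instance_id = paste0(df$participant_id, "-", df$survey_type, "-", df$wave,
                         "-", seq_len(nrow(df))),
    survey_type = df$survey_type,
    wave = df$wave,
    n_answered = ifelse(df$complete, 20L, 0L),
    n_items = 20L,
    complete = df$complete
  )
}

toy_participants <- function(ids) {
  tibble::tibble(
    id = ids, enrolled = 1L, age = 50, female = 0L, current_smoker = 0L,
    education = 3L, married = 1L, employed = 1L, bmi = 25,
    registration_ts = 0, followup_days = 400L
  )
}

# random item vectors for scorer property tests
random_cesd_items <- function(n) {
  replicate(n, sample(0:3, 20, replace = TRUE), simplify = FALSE)
}

# Newton-Raphson logistic MLE, independent of stats::glm, for cross-checks
oracle_logistic <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    beta <- beta + solve(info, score)
  }
  as.vector(beta)
}
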