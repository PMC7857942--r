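---
title: "Models and design of the ecohortr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the ecohortr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecohortr)
library(dplyr)
```

This vignette is the package's account of the science it implements: the
time-window and adherence definitions, the scoring and imputation rules,
the agreement and trend models with their assumptions, what the synthetic
cohort generator emulates (and deliberately does not), and the numerical
choices made where the design was genuinely open.

## 1. Protocol time windows

App surveys can be returned at any moment, so longitudinal analysis first
needs a rule mapping each return to a protocol wave. We use whole elapsed
days since registration, floored (`floor((return − registration)/86400)`),
and five contiguous inclusive 90-day windows:

```{r}
window_rule()
```

Day boundaries are inclusive integer day indices. This reproduces printed
ranges such as "0 to 89 days" exactly and avoids timezone and daylight
arithmetic entirely — timestamps are carried as whole seconds since epoch
and day arithmetic happens in one place. Calendar-month arithmetic is a
non-goal: the windows are day counts.

Two eligibility exclusions are applied in a fixed order, and the order
matters for the exclusion log: first, participants with under 365 days of
follow-up (they never had the chance to complete the protocol); second,
among participants who returned anything, those whose *first* return falls
on day 90 or later — their earliest data cannot be a baseline survey, so
no baseline comparison is possible. Whether "after 90 days" means day
≥ 90 or day > 90 is ambiguous in prose; we chose **day ≥ 90** for
consistency with the baseline window ending at day 89. Participants who
returned nothing at all are *retained*: they belong in adherence
denominators. Applying the rules twice equals applying them once (tested).

## 2. Completion and adherence

A survey instance is *complete* when at least 75% of its items were
answered (inclusive: 3 of 4 counts). Adherence at a wave is reported two
ways over the same fixed post-exclusion denominator:

* `p_any` — the proportion of eligible participants with ≥ 1 completed
  survey assigned to that wave;
* `p_all` — the proportion completing *every* survey type scheduled at
  that wave.

`p_all ≤ p_any` always, both are monotone in added completions, and both
are tested against a brute-force per-participant enumeration. When the
same survey type is returned twice in one wave, the participant counts as
complete if any instance passes the rule, and the earliest return is used
for scoring — the most favourable reading consistent with "completed at
least one survey". Percentages are rounded half-up to 2 decimals (the
convention in printed tables; `round_half_up()`), with the raw proportions
always emitted alongside.

Timing metrics summarise, per survey type and wave, the survey return time
(deployment to return, days), touch time (start to return, minutes), step
time and per-question time (seconds). Quartiles use linear interpolation
(type 7) — IQR values depend on the quartile convention, so it is fixed
and documented rather than left to defaults.

## 3. Scoring and imputation

**Physical Activity Index.** A weighted sum of daily hours in five
intensities, weights 1 (sleep), 1.1 (sedentary), 1.5 (slight), 2.4
(moderate), 5 (heavy); hours sum to 24, so the score lives in [24, 120].
With exactly one category missing, the constraint identifies it:
`max(0, 24 − Σ others)`. If the four present hours already exceed 24 the
imputation would be negative; hours are physical quantities, so the
instance is flagged and scored missing rather than clamped silently. Two
or more missing categories are unscorable.

**CES-D.** Twenty items in 0–3, summed after mapping reverse-scored items
`v → 3 − v`. With 1–5 items missing the mean of the present items is
multiplied by 20 (the identity when nothing is missing); with more than 5
missing the score is missing. A binary depression indicator flags scores
≥ 16. The instrument's standard form reverse-scores items 4, 8, 12 and 16,
and that is the default; some study databases store responses already
reverse-coded, so `reverse_coded = integer(0)` switches to literal
summation. This default-plus-override design keeps fidelity to the
instrument without guessing what a particular upstream system did.

**Alcohol.** Weekly drinks = drinks per drinking day × drinking days per
week (0–7), zero whenever the day count is zero. Whether "drinks per day"
was averaged over drinking days or all days is an open question for any
given survey text; the product rule here assumes drinking days.

Scores are carried at full floating precision; rounding happens only in
report formatting.

## 4. Agreement

Clinic measurements are the gold standard; pairs with either side missing
are dropped and counted (`n_dropped`), matching the complete-case
per-measure sample sizes such studies report.

**Lin's CCC.** With 1/n moment estimators,
$$\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$
penalising both imprecision (low correlation) and inaccuracy (location or
scale shift). The 1/n scaling is Lin's original definition; 1/(n−1)
scaling agrees to O(1/n) and the choice is immaterial at cohort sizes, but
it is fixed and documented. The confidence interval is computed on the
Fisher z scale with the later-corrected form of Lin's asymptotic variance
(the version involving the Pearson correlation $r$ and the standardised
location shift $u = (\bar x-\bar y)/\sqrt{s_x s_y}$), then
back-transformed; the CI is degenerate by construction at $|\hat\rho_c| = 1$.
Empirical coverage at n = 200 sits in the nominal band (tested over 500
replicates).

**Cohen's κ** is unweighted — the compared indicator (depression flag) is
binary, so weighting is moot — with the standard asymptotic Wald interval
$SE = \sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$. When both raters are constant and
identical, $p_e = 1$ and κ is reported as degenerate (missing), not
thrown.

**Bland-Altman.** Differences are app − clinic; limits of agreement are
`bias ± 1.96·sd(diff)` with the n−1 SD. The per-pair (mean, difference)
scatter is part of the result object so the funnel shape (spread growing
with the mean, typical for skewed measures) can be inspected via
`autoplot()`.

## 5. Longitudinal trends

Trend analyses are restricted to participants observed at *all* of a
measure's waves — the "returned at all time points" subgroups. On such a
balanced panel the random-intercept model
$$y_{it} = \mu + \beta_{w(t)} + b_i + e_{it},\quad b_i \sim N(0,\tau^2),
\; e_{it} \sim N(0,\sigma^2)$$
has an exact closed form: $\hat\beta_w$ is the wave-mean difference from
baseline, $\hat\sigma^2$ is the participant × wave interaction mean
square, and $\hat\tau^2 = (MS_{subject} - \hat\sigma^2)/k$, clamped at
zero with a warning when the moment estimate is negative. This is
identical to REML on balanced data (verified against lme4 in the test
suite) and needs no iterative solver. Wald z inference is used for the
wave effects ($SE = \sqrt{2\hat\sigma^2/n}$); with panels in the hundreds
of participants, small-sample corrections would change nothing visible.
A general unbalanced mixed-model solver is deliberately out of scope —
unbalanced data should be fitted with lme4 directly. Wave is categorical
throughout (the "slope" language sometimes used for such contrasts
notwithstanding); the two-wave alcohol comparison uses the classical
paired t test, which equals a one-sample t on the differences.

## 6. The synthetic cohort generator

The generator exists so that the full pipeline — windowing, completion,
scoring, agreement, comparison, trends — can be exercised and calibrated
without access to any real participant records. Its guiding principle is
that **every scored app value has a known additive error structure**, so
agreement estimators can be checked against a closed form: for latent
trait $t$ with variance $\tau^2$, clinic value $t + e_c$ and app value
$t + \delta + e_a$,
$$\rho_c^{pop} = \frac{2\tau^2}{2\tau^2 + \sigma_c^2 + \sigma_a^2 + \delta^2}
\quad(\texttt{expected\_ccc()}).$$

Per enrolled participant: activity hours come from a Dirichlet scaled to
24 h (concentration 18.5 around realistic category means, giving a trait
SD of about 4 index points); CES-D and drinks latents are normal (means
10 and 6, SDs 5 and 3), clamped to their scales. Item responses are then
*constructed to hit a target score exactly*:

* PAI: the participant's hours are reallocated between intensity
  categories (into the heaviest category to raise the score, into sleep to
  lower it) until the weighted sum equals the target, preserving
  nonnegativity and the sum-to-24 constraint the scorer relies on. A
  Dirichlet resampling of the hours was considered and rejected: it
  perturbs the score with a variance that depends on the hour profile,
  destroying the clean additive structure the closed form assumes.
* CES-D: the integer target sum is spread over 20 items in 0–3 (remainder
  positions randomised so item-level missingness stays meaningful), then
  reverse-coded items are stored inverted so the scorer's reverse coding
  recovers the target.
* Alcohol: a drinking-day count in 1–7 is drawn and drinks/day set so the
  product equals the target.

Return behaviour is Bernoulli per wave on the logit scale:
`qlogis(wave prob) + covariate effects (centred) + penalty`, where the
penalty (default −3 log-odds) applies at follow-up waves to participants
who returned nothing at baseline. Without it, independent waves make
~10% of participants "late first returners", an order of magnitude more
than real eCohorts show; with it the late-first-return exclusion affects
~2%. Conditional on returning at a wave, each scheduled survey is returned
with probability 0.977, lowered for the medical-history update (0.83 at 6
months, 0.04 at 12 months) so that all-survey adherence collapses at 12
months the way long instruments empirically do. Items are skipped
independently at rate 0.002, the order of magnitude implied by observed
skip counts in app surveys. Timing uses lognormal start-lags (median 1.8
days) and touch durations (median 3 minutes), truncated so every return
lands inside its intended window. Default operating points — wave return
propensities 0.89/0.59/0.52/0.42/0.40, biases δ = 2.27/0.03/0.54 and
noise SDs solved from target concordances 0.56/0.77/0.82 — were fixed
once, up front, at values a 12-month smartphone eCohort embedded in a
clinic cohort realistically shows.

**What the generator does not emulate**, and hence what passing tests do
not demonstrate about real data:

* Real CES-D and drinks distributions are right-skewed with a floor at
  zero; the Gaussian latents here are kept interior to the scale so the
  additive error model stays essentially exact. Boundary clamping still
  introduces a small bias (e.g. the realised CES-D mean difference is a
  few tenths above δ), visible in simulation output.
* Return behaviour across waves is only weakly coupled (through the
  baseline penalty); real engagement is strongly participant-correlated,
  so all-wave panel sizes here are smaller relative to cohort size than in
  real studies.
* Clinic values are continuous even for integer-valued instruments, and
  measurement error is homoscedastic — no funnel in the Bland-Altman
  scatter unless you inject one.
* Because the covariate effect on return applies at every wave, the
  odds ratio for *ever* returning exceeds the per-wave generating odds
  ratio; parameter-recovery tests therefore use single-wave
  configurations where the mapping is exact.

## 7. Numerical and design details

* Determinism: one master seed drives named substreams (participants,
  traits, clinic, returns, thinning, timing, responses), so adding a table
  leaves the others' draws untouched; the whole pipeline is byte-identical
  under a fixed config.
* Degenerate inputs: zero-variance series make the CCC undefined (error),
  κ with both raters constant is reported missing, zero-variance paired
  differences report p as the appropriate limit with a note, and a
  negative between-participant variance moment is clamped to zero with a
  warning.
* The logistic returner model is a plain ML `glm` with Wald odds-ratio
  intervals; education enters as indicators against the lowest category
  (configurable — the reference level is a reporting choice, not a model
  one). Separation is detected and raised as an explicit error. Education
  as ordinal vs categorical was an open choice; categorical was chosen as
  the less restrictive model.
* Group comparisons use the pooled-variance Student t (Welch behind a
  flag) and the Pearson chi-square without continuity correction on the
  full contingency table.
* Problem sizes in the shipped tests were chosen so the whole suite runs
  in a few minutes on one CPU: calibration loops use hundreds of
  replicates at n in the hundreds-to-thousands; the generator's
  statistical-structure checks use one cohort of 5000.

## 8. A complete run

```{r, eval = FALSE}
report <- run_pipeline(cohort_config(n_participants = 2000, seed = 42))
report$adherence
plot_adherence(report$adherence)

# Bland-Altman plot for the physical activity measure
pai_pairs <- report$tables$clinic |>
  filter(measure == "pai") |>
  rename(clinic = value) |>
  inner_join(
    report$scores |>
      filter(measure == "pai", wave == "baseline") |>
      select(participant_id, app = value),
    by = "participant_id"
  )
autoplot(bland_altman(pai_pairs))

plot_trends(report$boxplots)
write_report_bundle(report, "out/")
```

Every written table carries a JSON sidecar with the run's config hash and
seed, so a bundle is traceable to the exact configuration that produced
it.
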