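test_that("the step primitive takes the value one half at zero", {
  expect_identical(heaviside(0), 0.5)
  expect_identical(heaviside(c(-1e-9, 0, 1e-9)), c(0, 0.5, 1))
})

test_that("step thresholds land between the last stay and first skip", {
  # stays at 4/6/8, skips at 10/12: unique SSE minimum at the 8-10 midpoint
  expect_equal(fit_heaviside_threshold(c(4, 6, 8, 10, 12), c(1, 1, 1, 0, 0)), 9)
  # extreme cases stay finite: the minimal or maximal delay offered
  expect_equal(fit_heaviside_threshold(c(4, 9, 22), c(1, 1, 1)), 22)
  expect_equal(fit_heaviside_threshold(c(4, 9, 22), c(0, 0, 0)), 4)
  expect_equal(fit_heaviside_threshold(c(4, 9, 22), c("stay", "stay", "stay")), 22)
  expect_error(fit_heaviside_threshold(numeric(0), numeric(0)), "at least one")
  expect_error(fit_heaviside_threshold(c(4, 5), c("yes", "no")), "stay")
  expect_error(fit_heaviside_threshold(c(4, 5), c(2, 0)), "1/0")
})

test_that("the fit matches exhaustive SSE minimization on random data", {
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    delay <- sample(3:30, n, replace = TRUE)
    stay <- rbinom(n, 1, 0.5)
    expect_identical(fit_heaviside_threshold(delay, stay),
                     oracle_step_threshold(delay, stay))
  }
})

test_that("leave-one-out thresholds equal brute-force refits", {
  set.seed(62)
  delay <- sample(3:30, 12, replace = TRUE)
  stay <- as.numeric(delay < 15)
  loo <- loo_threshold_vector(delay, stay)
  brute <- sapply(seq_along(delay), function(i) {
    oracle_step_threshold(delay[-i], stay[-i])
  })
  expect_identical(loo, brute)
  # a redundant point leaves the threshold unchanged
  expect_true(all(loo_threshold_vector(c(5, 5, 20, 20), c(1, 1, 0, 0)) == 12.5))
  # all-stay galleries peg at the maximum offered mid
  expect_identical(loo_threshold_vector(c(5, 9, 14), c(1, 1, 1)), c(14, 14, 9))
  expect_error(loo_threshold_vector(10, 1), "at least 2")
})

test_that("trial thresholds assign LOO values to risky and the mean to non-risky", {
  trials <- make_trials(tibble::tibble(
    low = c(8L, 10L, 16L, 10L, 10L),
    mid = c(10L, 12L, 18L, 10L, 10L),
    high = c(12L, 14L, 20L, 10L, 10L),
    is_risky = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    choice = c("stay", "stay", "skip", "stay", "stay"),
    realized_delay = c(10L, 12L, NA, 10L, 10L),
    outcome_class = c("mid", "mid", "none", "nonrisk", "nonrisk"),
    rating = c(3L, 2L, NA, 3L, 4L)
  ))
  ts <- assign_trial_thresholds(trials)
  risky_thr <- ts$assigned_threshold[ts$is_risky]
  nonrisky_thr <- ts$assigned_threshold[!ts$is_risky]
  expect_true(all(nonrisky_thr == mean(risky_thr)))
  expect_equal(ts$expected_value,
               ts$assigned_threshold - (trials$low + trials$mid + trials$high) / 3)
  # a gallery with a single risky trial cannot support leave-one-out
  lone <- make_trials(tibble::tibble(
    low = c(8L, 10L), mid = c(10L, 10L), high = c(12L, 10L),
    is_risky = c(TRUE, FALSE), choice = c("stay", "stay"),
    realized_delay = c(10L, 10L), outcome_class = c("mid", "nonrisk"),
    rating = c(3L, 3L)
  ))
  ts2 <- assign_trial_thresholds(lone)
  expect_true(all(is.na(ts2$assigned_threshold)))
  expect_true(all(ts2$flag == "insufficient_risky_trials"))
})

test_that("each subject gets exactly four gallery thresholds", {
  thr <- small_thresholds()
  gal <- subject_thresholds(thr)
  counts <- dplyr::count(gal, subject_id)
  expect_true(all(counts$n == 4))
  expect_true(all(gal$threshold >= 3 & gal$threshold <= 30, na.rm = TRUE))
})

test_that("expected value is linear and permutation-invariant in the delays", {
  expect_equal(expected_value(5, 10, 15, threshold = 20), 10)
  expect_equal(expected_value(10, 10, 10, threshold = 10), 0)
  expect_equal(expected_value(30, 30, 30, threshold = 3), -27)
  expect_equal(expected_value(5, 10, 15, 20), expected_value(15, 10, 5, 20))
  expect_error(expected_value(5, 10, 15, NA), "present")
})

test_that("validity correlations detect stated-preference consistency", {
  # gallery thresholds 7/11/15/19 paired with constant ratings 1/2/3/4:
  # both stated-preference measures are exactly linear in the threshold
  mids <- c(4L, 6L, 8L, 10L) + rep(c(0L, 4L, 8L, 12L), each = 4)
  choice <- rep(c("stay", "stay", "skip", "skip"), 4)
  trials <- make_trials(tibble::tibble(
    gallery = rep(c("a", "b", "c", "d"), each = 4),
    low = mids - 2L, mid = mids, high = mids + 2L,
    is_risky = TRUE,
    choice = choice,
    realized_delay = ifelse(choice == "stay", mids, NA_integer_),
    outcome_class = ifelse(choice == "stay", "mid", "none"),
    rating = ifelse(choice == "stay", rep(1:4, each = 4), NA_integer_)
  ))
  ts <- assign_trial_thresholds(trials)
  rankings <- tibble::tibble(subject_id = "S001", gallery = c("a", "b", "c", "d"),
                             ranking = c(4L, 3L, 2L, 1L))
  v <- validity_correlations(trials, ts, rankings)
  expect_equal(v$r_rating, 1)
  expect_equal(v$r_ranking, 1)  # rank 1 = most preferred, reverse-coded
  expect_true(is.na(v$flag))
})

test_that("a positive rating-threshold link yields high validity correlations", {
  study <- simulate_study(population_config(n_subjects = 30, seed = 73),
                          session_config(), seed = 73)
  ts <- assign_trial_thresholds(study$trials)
  v <- validity_correlations(study$trials, ts, study$rankings)
  expect_gt(median(v$r_rating, na.rm = TRUE), 0.5)
  expect_gt(median(v$r_ranking, na.rm = TRUE), 0.3)
})

test_that("degenerate validity inputs are flagged, not zeroed", {
  trials <- make_trials(tibble::tibble(
    gallery = rep(c("a", "b", "c", "d"), each = 3),
    low = 8L, mid = 10L, high = 12L, is_risky = TRUE,
    choice = rep(c("stay", "stay", "skip"), 4),
    realized_delay = rep(c(10L, 10L, NA), 4),
    outcome_class = rep(c("mid", "mid", "none"), 4),
    rating = rep(c(3L, 3L, NA), 4)
  ))
  ts <- assign_trial_thresholds(trials)
  rankings <- tibble::tibble(subject_id = "S001", gallery = c("a", "b", "c", "d"),
                             ranking = 1:4)
  v <- validity_correlations(trials, ts, rankings)
  expect_true(is.na(v$r_rating))
  expect_match(v$flag, "undefined")
})

test_that("psychophysics curves step at the threshold for noise-free agents", {
  # near-deterministic agents: high beta approximates the hard step
  pop <- sample_population(population_config(n_subjects = 6, seed = 71,
                                             beta_mean = 25, beta_sd = 0))
  study <- simulate_study(pop, session_config(session_minutes = 20), seed = 71)
  ts <- assign_trial_thresholds(study$trials)
  curve <- psychophysics_curve(ts)
  expect_true(all(curve$stay_rate >= 0 & curve$stay_rate <= 1))
  left <- curve$stay_rate[curve$bin < -1.5]
  right <- curve$stay_rate[curve$bin > 1.5]
  expect_true(mean(left) > 0.95)
  expect_true(mean(right) < 0.05)
})

test_that("logistic agents cross one half at their threshold", {
  pop <- sample_population(population_config(n_subjects = 40, seed = 72,
                                             beta_mean = 0.5, beta_sd = 0))
  study <- simulate_study(pop, session_config(), seed = 72)
  ts <- assign_trial_thresholds(study$trials)
  curve <- psychophysics_curve(ts)
  risky <- curve[curve$condition == "risky", ]
  at_zero <- mean(risky$stay_rate[abs(risky$bin) == 0.5])
  expect_lt(abs(at_zero - 0.5), 0.05)
  # and the profile falls from well above to well below one half
  expect_gt(mean(risky$stay_rate[risky$bin < -5]), 0.75)
  expect_lt(mean(risky$stay_rate[risky$bin > 5]), 0.25)
})
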