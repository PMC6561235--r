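# simulate directly from the analysis-model family (random-intercept
# logistic): independent truth for fit_mixed_model
simulate_choice_family <- function(n_subj, n_trial, b_value, b_bad, b_mid = 0,
                                   sd_subj = 0.5) {
  subj <- rep(sprintf("P%02d", 1:n_subj), each = n_trial)
  intercepts <- rep(rnorm(n_subj, 0, sd_subj), each = n_trial)
  value_prev <- runif(n_subj * n_trial, -12, 12)
  class_prev <- factor(sample(c("good", "bad", "mid"), n_subj * n_trial, TRUE),
                       levels = c("good", "bad", "mid"))
  lp <- intercepts + b_value * value_prev + b_bad * (class_prev == "bad") +
    b_mid * (class_prev == "mid")
  tibble::tibble(subject_id = subj, value_prev = value_prev,
                 class_prev = class_prev,
                 stay = rbinom(n_subj * n_trial, 1, plogis(lp)))
}

test_that("the mixed logistic model recovers its own generating coefficients", {
  set.seed(91)
  covered <- pvals <- numeric(10)
  for (r in 1:10) {
    d <- simulate_choice_family(40, 60, b_value = 0.04, b_bad = -0.6)
    m <- fit_mixed_model(d, stay ~ value_prev + class_prev + (1 | subject_id),
                         "binary")
    row <- m$table[m$table$term == "class_prevbad", ]
    covered[r] <- row$ci_lo <= -0.6 && -0.6 <= row$ci_hi
    pvals[r] <- row$p
  }
  expect_gte(mean(covered), 0.8)
  expect_true(all(pvals < 0.05))  # a -0.6 logit effect is detectable here
})

test_that("a null framing effect is recovered as centered on zero", {
  set.seed(92)
  ests <- numeric(12)
  for (r in 1:12) {
    d <- simulate_choice_family(30, 50, b_value = 0.04, b_bad = 0)
    m <- fit_mixed_model(d, stay ~ value_prev + class_prev + (1 | subject_id),
                         "binary")
    ests[r] <- m$table$estimate[m$table$term == "class_prevbad"]
  }
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("single-subject data fall back to fixed effects with a flag", {
  set.seed(93)
  d <- simulate_choice_family(1, 80, b_value = 0.05, b_bad = -0.5)
  m <- fit_mixed_model(d, stay ~ value_prev + class_prev + (1 | subject_id),
                       "binary")
  expect_true("single_group_fixed_effects" %in% m$flags)
  expect_true(nrow(m$table) == 4)
})

test_that("coefficient tables satisfy the interval and FDR layout contract", {
  study <- small_study()
  suite <- run_model_suite(study$trials, small_thresholds())
  tab <- tidy(suite)
  expect_true(all(c("model", "term", "estimate", "ci_lo", "ci_hi", "p", "p_adj")
                  %in% names(tab)))
  # interval contains the estimate; adjusted p never below raw p
  expect_true(all(tab$ci_lo <= tab$estimate & tab$estimate <= tab$ci_hi,
                  na.rm = TRUE))
  nonint <- tab[tab$term != "(Intercept)", ]
  expect_true(all(nonint$p_adj >= nonint$p - 1e-12, na.rm = TRUE))
  expect_true("choice_primary" %in% tab$model)
  expect_true(any(grepl("matched", tab$model)))
  # the secondary model uses the three-level framing-and-risk coding
  sec <- tab[tab$model == "secondary_integrated", ]
  expect_true(any(grepl("class_prevgood", sec$term)))
  expect_true(any(grepl("class_prevnonrisk", sec$term)))
})

test_that("post-loss slowing is recovered by the reaction-time model", {
  pop <- population_config(n_subjects = 50, seed = 94, delta = 0.1)
  study <- simulate_study(pop, session_config(), seed = 94)
  ts <- assign_trial_thresholds(study$trials)
  d <- prepare_sequential_dataset(study$trials, ts, "rt")
  m <- fit_mixed_model(d, log_rt ~ value_prev + class_prev + (1 | subject_id),
                       "continuous")
  row <- m$table[m$table$term == "class_prevbad", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.05)
  # and the magnitude is close to the generative slowing
  expect_lt(abs(row$estimate - 0.1), 0.05)
})

test_that("a value-by-loss interaction in the generator surfaces in the matched model", {
  pop <- population_config(n_subjects = 80, seed = 95, eta = 0.15, gamma_E = 0)
  study <- simulate_study(pop, session_config(), seed = 95)
  ts <- assign_trial_thresholds(study$trials)
  d <- prepare_sequential_dataset(study$trials, ts, "choice")
  m <- build_matched_subsets(d, "class_prev", "value_prev", c("bad", "good"), 0.5)
  m <- dplyr::mutate(m, class_prev = factor(as.character(class_prev),
                                            levels = c("good", "bad")))
  fit <- fit_mixed_model(m, stay ~ value_prev * class_prev + (value_prev | subject_id),
                         "binary")
  inter <- fit$table[fit$table$term == "value_prev:class_prevbad", ]
  expect_gt(inter$estimate, 0)
})

test_that("an empty model dataset is skipped with a reason, not an error", {
  trials <- make_trials(tibble::tibble(
    low = c(8L, 8L, 8L), mid = c(10L, 10L, 10L), high = c(12L, 12L, 12L),
    is_risky = TRUE, choice = "skip",
    realized_delay = NA_integer_, outcome_class = "none", rating = NA_integer_
  ))
  ts <- assign_trial_thresholds(trials)
  suite <- run_model_suite(trials, ts)
  expect_true(length(suite$skipped) > 0)
  expect_false("choice_primary" %in% names(suite$models))
})
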