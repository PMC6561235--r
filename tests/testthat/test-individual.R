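test_that("subject-specific coefficients recover the framing heterogeneity", {
  # framing coefficients spread widely across agents; plentiful risky data.
  # Per-subject maximum-likelihood fits on one session are noisy (previous
  # value and outcome class are partly collinear by construction), so the
  # recovery bound is moderate; it tightens as sessions accumulate.
  pop <- population_config(n_subjects = 100, seed = 111, gamma0 = -0.5,
                           gamma_E = 0.87)  # gamma spread roughly (-2, 1)
  study <- simulate_study(pop, session_config(risky_fraction = 0.9), seed = 111)
  ts <- assign_trial_thresholds(study$trials)
  coeffs <- fit_subject_models(study$trials, ts)
  j <- dplyr::left_join(coeffs, study$agents, by = "subject_id")
  rho <- cor(j$choice_outcome_coeff, j$gamma, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.2)
})

test_that("an all-stay subject is flagged unestimable", {
  trials <- make_trials(tibble::tibble(
    low = rep(c(8L, 10L), 6), mid = rep(c(10L, 12L), 6),
    high = rep(c(12L, 14L), 6), is_risky = TRUE, choice = "stay",
    realized_delay = rep(c(12L, 14L), 6),
    outcome_class = rep(c("bad", "bad"), 6), rating = 3L
  ))
  ts <- assign_trial_thresholds(trials)
  coeffs <- fit_subject_models(trials, ts)
  expect_true(is.na(coeffs$choice_outcome_coeff))
  expect_false(is.na(coeffs$choice_flag))
})

test_that("ESI scoring applies the sum, log transform and retention rule", {
  design <- esi_item_design()
  zero <- tibble::tibble(subject_id = "Z", item = design$item,
                         subfactor = design$subfactor,
                         subscale = design$subscale, response = 0L)
  prof <- score_esi(zero)
  expect_equal(prof$esi_total, 0)
  expect_equal(prof$esi_total_log, 0)  # ln(0 + 1)
  expect_false(prof$alcohol_retained)
  expect_false(prof$marijuana_retained)
  expect_false(prof$drug_retained)
  # a single endorsed alcohol item flips retention
  one <- zero
  one$response[which(design$subscale == "alcohol")[1]] <- 1L
  prof1 <- score_esi(one)
  expect_true(prof1$alcohol_retained)
  expect_false(prof1$marijuana_retained)
  expect_equal(prof1$esi_total_log, log(2))
  # identical responses give identical profiles
  two <- dplyr::bind_rows(one, dplyr::mutate(one, subject_id = "Z2"))
  prof2 <- score_esi(two)
  expect_equal(prof2$esi_total, rep(1, 2))
  # incomplete response sets are rejected
  expect_error(score_esi(zero[-1, ]), "Incomplete|every item")
})

test_that("percentage-bend correlation agrees with Pearson under normality", {
  set.seed(112)
  diffs <- replicate(30, {
    x <- rnorm(200); y <- 0.4 * x + rnorm(200)
    covars <- data.frame(c1 = rnorm(200))  # independent of x and y
    res <- robust_partial_correlation(x, y, covars)
    abs(res$r - cor(x, y))
  })
  expect_lt(median(diffs), 0.03)
  expect_lt(max(diffs), 0.08)
})

test_that("identity and degenerate inputs behave as documented", {
  x <- rnorm(50)
  res <- robust_partial_correlation(x, x)
  expect_equal(res$r, 1)
  short <- robust_partial_correlation(1:5, 5:1)
  expect_identical(short$flag, "too_few_cases")
  const <- robust_partial_correlation(rep(1, 20), rnorm(20))
  expect_identical(const$flag, "constant_residuals")
})

test_that("the bend protects against a planted extreme outlier", {
  set.seed(113)
  wins <- replicate(100, {
    x <- rnorm(100); y <- 0.5 * x + rnorm(100)
    r_clean <- robust_partial_correlation(x, y)$r
    x[1] <- 40; y[1] <- -40
    r_rob <- robust_partial_correlation(x, y)$r
    r_pea <- cor(x, y)
    abs(r_rob - r_clean) < abs(r_pea - r_clean)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("one-tailed p-values respect the stated direction", {
  set.seed(114)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  two <- robust_partial_correlation(x, y, tails = "two")
  pos <- robust_partial_correlation(x, y, tails = "one", direction = 1)
  neg <- robust_partial_correlation(x, y, tails = "one", direction = -1)
  expect_equal(pos$p, two$p / 2)
  expect_equal(neg$p, 1 - two$p / 2)
})

test_that("the trait report has the primary/follow-up/adjusted structure", {
  set.seed(115)
  n <- 60
  coeffs <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    choice_outcome_coeff = rnorm(n),
    rating_outcome_coeff = rnorm(n)
  )
  profiles <- tibble::tibble(
    subject_id = coeffs$subject_id,
    esi_total_log = 0.5 * coeffs$choice_outcome_coeff + rnorm(n, 0, 0.8),
    disinhibition = rnorm(n), substance = rnorm(n), aggression = rnorm(n),
    alcohol = rbinom(n, 3, 0.2), marijuana = 0L, drug = rbinom(n, 2, 0.1),
    alcohol_retained = TRUE, marijuana_retained = FALSE, drug_retained = TRUE
  )
  profiles$marijuana_retained[1:5] <- TRUE  # below the n >= 8 floor
  demo <- tibble::tibble(subject_id = coeffs$subject_id,
                         age = rnorm(n, 20, 1.5),
                         sex = sample(c("female", "male"), n, TRUE),
                         ethnicity = sample(c("a", "b"), n, TRUE))
  disc <- tibble::tibble(subject_id = coeffs$subject_id,
                         logk_delay = rnorm(n, -5, 2),
                         logk_prob = rnorm(n, 0.3, 0.8))
  rep <- run_trait_correlations(coeffs, profiles, demo, disc)
  expect_setequal(unique(rep$family),
                  c("primary", "followup", "unique_contribution",
                    "discounting_adjusted"))
  # the planted choice-ESI link is found; follow-up BH is monotone
  prim <- rep[rep$pair == "choice_coeff~esi_total_log" & rep$family == "primary", ]
  expect_lt(prim$p, 0.05)
  expect_gt(prim$r, 0)
  fu <- rep[rep$family == "followup" & !is.na(rep$p), ]
  ord <- order(fu$p)
  expect_true(all(diff(fu$p_adj[ord]) >= -1e-12))
  # the under-populated subscale is skipped with a reason
  mj <- rep[rep$pair == "choice_coeff~marijuana", ]
  expect_identical(mj$note, "fewer_than_8_retained")
  expect_true(is.na(mj$r))
})
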