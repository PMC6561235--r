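test_that("population draws are reproducible with the documented structure", {
  pop <- population_config(n_subjects = 105, seed = 7)
  a1 <- sample_population(pop)
  a2 <- sample_population(pop)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 105)
  expect_equal(a1$gamma, pop$gamma0 + pop$gamma_E * a1$E)
  expect_true(all(a1[, c("tau_1", "tau_2", "tau_3", "tau_4")] >= 3 &
                    a1[, c("tau_1", "tau_2", "tau_3", "tau_4")] <= 30))
  expect_true(all(a1$beta > 0))
})

test_that("zero externalizing slope collapses framing to its population mean", {
  a <- sample_population(population_config(n_subjects = 50, seed = 8,
                                           gamma0 = -0.4, gamma_E = 0))
  expect_true(all(a$gamma == -0.4))
})

test_that("delay discounting rates center on the published population median", {
  a <- sample_population(population_config(n_subjects = 10000, seed = 9))
  expect_lt(abs(median(a$logk_delay) - (-5.26)), 0.1)
  expect_lt(abs(sd(a$logk_delay) - 2.05), 0.1)
})

test_that("the choice rule is a logistic in threshold-relative value", {
  agent <- list(tau = c(20, 20, 20, 20), beta = 0.5, gamma = -1, eta = 0,
                alpha0 = 0, sigma_rt = 0.1)
  gal <- session_config()$galleries
  offer_at <- function(d) list(gallery = gal[1], low = d, mid = d, high = d,
                               is_risky = FALSE)
  set.seed(31)
  expect_equal(agent_decide(agent, offer_at(20))$stay_probability, 0.5)
  expect_equal(agent_decide(agent, offer_at(10))$stay_probability,
               plogis(5), tolerance = 1e-12)
  # a prior risky loss strictly lowers the stay probability when gamma < 0
  prev_bad <- list(gallery = gal[2], is_risky = TRUE, choice = "stay",
                   outcome_class = "bad", realized_delay = 25L)
  prev_good <- list(gallery = gal[2], is_risky = TRUE, choice = "stay",
                    outcome_class = "good", realized_delay = 5L)
  p_bad <- agent_decide(agent, offer_at(15), prev = prev_bad)$stay_probability
  p_good <- agent_decide(agent, offer_at(15), prev = prev_good)$stay_probability
  expect_lt(p_bad, p_good)
  expect_equal(p_good, plogis(0.5 * 5))  # good outcomes carry no framing term
})

test_that("ratings discretize the latent scale through the cutpoints", {
  gal <- session_config()$galleries
  base <- list(tau = c(20, 20, 20, 20), beta = 0.5, mu = rep(0, 4),
               sigma_r = 1e-9, cutpoints = c(-0.5, 0, 0.5))
  trial <- function(realized, class) {
    list(gallery = gal[1], choice = "stay", realized_delay = realized,
         outcome_class = class)
  }
  # latent 0.1 (rate_a chosen so value term lands at 0.1) -> third bin
  ag <- c(base, list(rate_a = 0.01, rate_b = 0, rate_c = 0))
  expect_identical(agent_rate(ag, trial(10L, "mid")), 3L)  # latent = 0.1
  # latent below all cutpoints -> rating 1
  ag2 <- c(base, list(rate_a = 0.5, rate_b = 0, rate_c = 0))
  expect_identical(agent_rate(ag2, trial(30L, "bad")), 1L)  # latent = -5
  expect_error(agent_rate(ag, list(choice = "skip")), "stay")
})

test_that("a positive loss offset raises mean ratings after bad outcomes", {
  gal <- session_config()$galleries
  ag <- list(tau = c(20, 20, 20, 20), mu = rep(0, 4), rate_a = 0,
             rate_b = 0.5, rate_c = 0, sigma_r = 1, cutpoints = c(-1, 0, 1))
  set.seed(33)
  r_bad <- replicate(5000, agent_rate(ag, list(gallery = gal[1], choice = "stay",
                                               realized_delay = 15L,
                                               outcome_class = "bad")))
  r_good <- replicate(5000, agent_rate(ag, list(gallery = gal[1], choice = "stay",
                                                realized_delay = 15L,
                                                outcome_class = "good")))
  # Monte-Carlo against the ordered-latent expectation: shift b > 0 must
  # raise the mean rating at matched value
  expect_gt(mean(r_bad), mean(r_good))
  expect_gt(mean(r_bad) - mean(r_good), 0.1)
})

test_that("item endorsement follows the logistic item-response model", {
  design <- esi_item_design()
  # null loadings: endorsement rate of each item approaches logistic(-c_j)
  agents <- sample_population(population_config(n_subjects = 4000, seed = 41))
  resp <- generate_esi_responses(agents, design, a_E = 0, b_F = 0, seed = 41)
  rates <- resp |>
    dplyr::summarise(rate = mean(response), .by = item) |>
    dplyr::left_join(design, by = "item")
  expected <- plogis(-rates$difficulty)
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(rates$rate - expected) < 4 * se))
  # determinism
  r2 <- generate_esi_responses(agents[1:5, ], design, seed = 99)
  r3 <- generate_esi_responses(agents[1:5, ], design, seed = 99)
  expect_identical(r2, r3)
  # extreme externalizing saturates endorsement
  hot <- agents[1, ]
  hot$E <- 60
  rhot <- generate_esi_responses(hot, design, seed = 1)
  expect_true(all(rhot$response == 1))
  expect_error(generate_esi_responses(agents[1:2, ],
                                      dplyr::mutate(design, subfactor = NA)),
               "subfactor")
})

test_that("problem subscales are zero-inflated at the population level", {
  agents <- sample_population(population_config(n_subjects = 400, seed = 43))
  prof <- score_esi(generate_esi_responses(agents, seed = 43))
  # most agents endorse no problem items, but a meaningful minority does
  retention <- mean(prof$alcohol_retained)
  expect_gt(retention, 0.05)
  expect_lt(retention, 0.6)
})

test_that("discounting choices maximize discounted value when sharp", {
  menu <- discounting_menu()
  agent <- tibble::tibble(subject_id = "S001", logk_delay = -5.26,
                          logk_prob = 0.28, choice_sharpness = Inf)
  resp <- generate_discounting_responses(agent, menu, seed = 51)
  k <- exp(-5.26)
  delay <- resp[resp$mode == "delay", ]
  v <- delay$amount_later / (1 + k * delay$condition)
  expect_identical(delay$choice, ifelse(v > delay$amount_sooner, "later", "sooner"))
  # negligible discounting values the later amount at face value
  flat <- tibble::tibble(subject_id = "S002", logk_delay = -30,
                         logk_prob = -30, choice_sharpness = Inf)
  r2 <- generate_discounting_responses(flat, menu, seed = 52)
  later_rate <- mean(r2$choice[r2$amount_sooner < 10] == "later")
  expect_equal(later_rate, 1)
  expect_error(discounting_menu(sooner_grid = c(0.25, 1)), "0.50")
})

test_that("the odds-against transform has its defining identities", {
  expect_equal(odds_against(0.5), 1)
  expect_equal(odds_against(0.9), 1 / 9)
  expect_equal(odds_against(1), 0)
  expect_error(odds_against(0), "0, 1")
})
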