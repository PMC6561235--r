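#' Population configuration for synthetic subjects
#'
#' Describes the generative population from which synthetic subjects are
#' drawn. Each agent carries per-gallery delay thresholds (`tau`), a
#' logistic choice noise scale (`beta`, the inverse temperature per second
#' of offer value), a framing sensitivity coupling the previous risky loss
#' to the next risky choice, a latent externalizing score `E` that
#' modulates that framing sensitivity, ordered-latent rating parameters,
#' log-normal reaction-time parameters with post-loss slowing, and
#' hyperbolic discounting rates.
#'
#' The agent's effective framing coefficient is
#' `gamma_i = gamma0 + gamma_E * E_i`: a negative `gamma0` produces
#' group-level risk aversion after a risky loss, while a positive `gamma_E`
#' attenuates or reverses it for high-externalizing agents. By default `E`
#' enters only the choice pathway, not the rating pathway, so pursuit and
#' valuation dissociate at the trait level.
#'
#' @param n_subjects Number of subjects to draw.
#' @param seed Integer seed for the draw.
#' @param tau_means Per-gallery threshold means (seconds, length 4).
#'   Equal means (the default) make gallery preferences idiosyncratic per
#'   subject; population-aligned means would let the fixed gallery cycle
#'   leak the previous gallery's attractiveness into the sequential-choice
#'   covariates.
#' @param tau_subject_sd Between-subject SD of the subject-level mean
#'   threshold (seconds).
#' @param tau_gallery_sd Within-subject SD of per-gallery threshold
#'   deviations (seconds). Kept moderate: with only four galleries on a
#'   fixed cycle, large within-subject threshold variance induces a
#'   mechanical negative lag-1 autocovariance (about -sd^2/4) between
#'   consecutive galleries' attractiveness that a subject intercept cannot
#'   absorb, biasing sequential-choice covariates. Draws are clamped to
#'   the task delay range.
#' @param beta_mean,beta_sd Choice inverse temperature (1/s).
#' @param gamma0 Population mean of the post-risky-loss framing effect on
#'   the stay logit (negative means risk aversion after a loss).
#' @param gamma_E Slope of the framing effect on latent externalizing.
#' @param eta Value-by-loss interaction on the stay logit (per second of
#'   previous actual value).
#' @param rating_link Coupling of a gallery's latent rating mean to the
#'   subject's own threshold deviation for that gallery (drives the
#'   validity correlation between thresholds and mean ratings).
#' @param rate_a Latent-rating slope on the current trial's actual value.
#' @param rate_b Latent-rating offset for a bad (long-delay) outcome.
#' @param rate_c Latent-rating value-by-bad interaction.
#' @param sigma_r Latent rating noise SD.
#' @param cutpoints Three increasing cutpoints discretizing the latent
#'   rating into the 1-4 scale.
#' @param alpha0_mean,alpha0_sd Log-seconds intercept of decision RT.
#' @param delta Post-risky-loss RT slowing on the log scale.
#' @param sigma_rt Log-RT noise SD.
#' @param logk_delay_mean,logk_delay_sd Population distribution of the log
#'   hyperbolic delay-discounting rate (per day).
#' @param logk_prob_mean,logk_prob_sd Population distribution of the log
#'   hyperbolic probability-discounting rate (per unit odds-against).
#' @param choice_sharpness Logistic sharpness (per dollar) of discounting
#'   choices.
#' @param ranking_sd Noise SD (seconds) of the post-task gallery ranking
#'   relative to the subject's true thresholds.
#' @param delay_range Task delay range used to clamp thresholds.
#' @return A list of class `rf_population_config`.
#' @export
population_config <- function(n_subjects = 105,
                              seed = 1L,
                              tau_means = c(16, 16, 16, 16),
                              tau_subject_sd = 2.5,
                              tau_gallery_sd = 2,
                              beta_mean = 0.5,
                              beta_sd = 0.1,
                              gamma0 = -0.6,
                              gamma_E = 1.2,
                              eta = 0,
                              rating_link = 0.15,
                              rate_a = 0.05,
                              rate_b = 0.3,
                              rate_c = 0,
                              sigma_r = 1,
                              cutpoints = c(-1, 0, 1),
                              alpha0_mean = log(1.2),
                              alpha0_sd = 0.2,
                              delta = 0.1,
                              sigma_rt = 0.35,
                              logk_delay_mean = -5.26,
                              logk_delay_sd = 2.05,
                              logk_prob_mean = 0.28,
                              logk_prob_sd = 0.84,
                              choice_sharpness = 5,
                              ranking_sd = 2,
                              delay_range = c(3, 30)) {
  assert_that(n_subjects >= 1, "`n_subjects` must be >= 1.")
  assert_that(length(tau_means) == 4, "`tau_means` must have length 4 (one per gallery).")
  assert_that(all(c(tau_subject_sd, tau_gallery_sd, beta_sd, alpha0_sd,
                    logk_delay_sd, logk_prob_sd) >= 0),
              "Population SDs must be non-negative.")
  assert_that(sigma_r > 0 && sigma_rt > 0, "`sigma_r` and `sigma_rt` must be positive.")
  assert_that(beta_mean > 0, "`beta_mean` must be positive.")
  assert_that(all(diff(cutpoints) > 0) && length(cutpoints) == 3,
              "`cutpoints` must be 3 strictly increasing values.")
  cfg <- as.list(environment())
  structure(cfg, class = "rf_population_config")
}

#' Draw a population of synthetic subjects
#'
#' Samples agent parameters from [population_config()]. Latent
#' externalizing `E` is standard normal; the effective framing coefficient
#' is `gamma0 + gamma_E * E`; log discounting rates are normal (so the
#' population median of `logk_delay` equals `logk_delay_mean`). Demographic
#' covariates (age, sex, ethnicity) are drawn independently of behavior.
#'
#' @param pop An [population_config()] object.
#' @return A tibble with one row per subject containing every generative
#'   parameter (ground truth for recovery scoring), with the configuration
#'   attached as attribute `"config"`.
#' @examples
#' agents <- sample_population(population_config(n_subjects = 3, seed = 42))
#' agents$gamma - (-0.6 + 0.8 * agents$E)
#' @export
sample_population <- function(pop = population_config()) {
  stopifnot(inherits(pop, "rf_population_config"))
  set.seed(pop$seed)
  n <- pop$n_subjects
  E <- rnorm(n)
  subj_level <- rnorm(n, 0, pop$tau_subject_sd)
  tau <- sapply(seq_along(pop$tau_means), function(g) {
    raw <- pop$tau_means[g] + subj_level + rnorm(n, 0, pop$tau_gallery_sd)
    pmin(pmax(raw, pop$delay_range[1]), pop$delay_range[2])
  })
  if (n == 1) tau <- matrix(tau, nrow = 1)
  mu <- pop$rating_link * sweep(tau, 1, rowMeans(tau))
  out <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    E = E,
    tau_1 = tau[, 1], tau_2 = tau[, 2], tau_3 = tau[, 3], tau_4 = tau[, 4],
    beta = pmax(rnorm(n, pop$beta_mean, pop$beta_sd), 0.05),
    gamma = pop$gamma0 + pop$gamma_E * E,
    eta = pop$eta,
    mu_1 = mu[, 1], mu_2 = mu[, 2], mu_3 = mu[, 3], mu_4 = mu[, 4],
    rate_a = pop$rate_a, rate_b = pop$rate_b, rate_c = pop$rate_c,
    sigma_r = pop$sigma_r,
    cut_1 = pop$cutpoints[1], cut_2 = pop$cutpoints[2], cut_3 = pop$cutpoints[3],
    alpha0 = rnorm(n, pop$alpha0_mean, pop$alpha0_sd),
    delta = pop$delta,
    sigma_rt = pop$sigma_rt,
    logk_delay = rnorm(n, pop$logk_delay_mean, pop$logk_delay_sd),
    logk_prob = rnorm(n, pop$logk_prob_mean, pop$logk_prob_sd),
    choice_sharpness = pop$choice_sharpness,
    F_disinhibition = rnorm(n),
    F_substance = rnorm(n),
    F_aggression = rnorm(n),
    age = round(pmax(rnorm(n, 20.2, 1.5), 18), 1),
    sex = ifelse(runif(n) < 0.81, "female", "male"),
    ethnicity = sample(c("white", "asian", "other"), n, replace = TRUE,
                       prob = c(0.63, 0.26, 0.11))
  )
  attr(out, "config") <- pop
  out
}

# internal: normalize an agent (tibble row or list) to the flat list the
# simulator consumes
as_agent <- function(agent, config = NULL) {
  if (is.data.frame(agent)) {
    stopifnot(nrow(agent) == 1)
    agent <- as.list(agent)
  }
  if (!is.null(agent$tau) && length(agent$tau) == 4) {
    tau <- agent$tau
    mu <- agent$mu %||% rep(0, 4)
    cutpoints <- agent$cutpoints %||% c(-1, 0, 1)
  } else {
    tau <- c(agent$tau_1, agent$tau_2, agent$tau_3, agent$tau_4)
    mu <- c(agent$mu_1, agent$mu_2, agent$mu_3, agent$mu_4)
    cutpoints <- c(agent$cut_1, agent$cut_2, agent$cut_3)
  }
  list(
    subject_id = agent$subject_id %||% "S001",
    tau = tau,
    beta = agent$beta,
    gamma = agent$gamma %||% 0,
    eta = agent$eta %||% 0,
    mu = mu,
    rate_a = agent$rate_a %||% 0,
    rate_b = agent$rate_b %||% 0,
    rate_c = agent$rate_c %||% 0,
    sigma_r = agent$sigma_r %||% 1,
    cutpoints = cutpoints,
    alpha0 = agent$alpha0 %||% log(1.2),
    delta = agent$delta %||% 0,
    sigma_rt = agent$sigma_rt %||% 0.35
  )
}

#' One stay/skip decision of a synthetic agent
#'
#' The agent evaluates the presented delay (the mid value of the offer)
#' against its gallery threshold on a logistic scale; if the immediately
#' preceding trial was a risky stay that realized the bad (high-delay)
#' outcome, the framing term `gamma + eta * V_prev` is added to the stay
#' logit, where `V_prev` is the previous trial's actual value (threshold
#' minus realized delay under the agent's own thresholds).
#'
#' @param agent Agent row or list (see [sample_population()]).
#' @param offer One-row offer (gallery, low/mid/high, is_risky).
#' @param prev The immediately preceding trial record, or `NULL`.
#' @param galleries Gallery labels defining the gallery -> threshold map.
#' @return List with `stay_probability`, `choice` and `decision_rt`.
#' @export
agent_decide <- function(agent, offer, prev = NULL,
                         galleries = session_config()$galleries) {
  ag <- as_agent(agent)
  g <- match(offer$gallery, galleries)
  assert_that(!is.na(g), "Offer gallery not found among `galleries`.")
  prev_bad <- !is.null(prev) && isTRUE(prev$is_risky) &&
    identical(prev$choice, .STAY) && identical(prev$outcome_class, "bad")
  lp <- ag$beta * (ag$tau[g] - offer$mid)
  if (prev_bad) {
    gp <- match(prev$gallery, galleries)
    v_prev <- ag$tau[gp] - prev$realized_delay
    lp <- lp + ag$gamma + ag$eta * v_prev
  }
  p <- plogis(lp)
  list(
    stay_probability = p,
    choice = if (runif(1) < p) .STAY else .SKIP,
    decision_rt = exp(ag$alpha0 + (if (prev_bad) ag$delta else 0) +
                        ag$sigma_rt * rnorm(1))
  )
}

#' Rate a consumed video
#'
#' Ordered-latent rating rule: the latent appreciation is the gallery mean
#' plus a slope on the trial's actual value, a bad-outcome offset and a
#' value-by-bad interaction plus Gaussian noise; the 1-4 rating counts the
#' cutpoints below the latent value.
#'
#' @inheritParams agent_decide
#' @param trial A stay trial record with `gallery`, `realized_delay`,
#'   `outcome_class` and `choice`.
#' @return Integer rating in 1..4.
#' @export
agent_rate <- function(agent, trial, galleries = session_config()$galleries) {
  if (!identical(trial$choice, .STAY)) {
    abort("Ratings are only defined for stay trials.")
  }
  ag <- as_agent(agent)
  g <- match(trial$gallery, galleries)
  v <- ag$tau[g] - trial$realized_delay
  bad <- identical(trial$outcome_class, "bad")
  latent <- ag$mu[g] + ag$rate_a * v +
    (if (bad) ag$rate_b + ag$rate_c * v else 0) + ag$sigma_r * rnorm(1)
  1L + sum(ag$cutpoints < latent)
}

#' Simulate a full study
#'
#' Draws a population, runs one session per subject, and produces the
#' post-task gallery rankings (rank 1 = most preferred, derived from the
#' subject's true thresholds plus ranking noise). All randomness flows from
#' `seed`.
#'
#' @param pop An [population_config()] object, or a pre-drawn agents tibble
#'   from [sample_population()].
#' @param config An [session_config()] object.
#' @param seed Integer seed for the sessions (the population uses the seed
#'   stored in `pop`).
#' @return A list of class `rf_study` with elements `trials` (all session
#'   logs stacked), `agents` (ground truth), `rankings` and `config`.
#' @examples
#' study <- simulate_study(population_config(n_subjects = 2, seed = 3),
#'                         session_config(session_minutes = 5), seed = 3)
#' dplyr::count(study$trials, subject_id)
#' @export
simulate_study <- function(pop = population_config(),
                           config = session_config(),
                           seed = 1L) {
  agents <- if (inherits(pop, "rf_population_config")) sample_population(pop) else pop
  pc <- attr(agents, "config")
  ranking_sd <- if (!is.null(pc)) pc$ranking_sd else 2
  set.seed(seed)
  trials <- purrr::map(seq_len(nrow(agents)), function(i) {
    run_session(agents[i, ], config)
  }) |> list_rbind()
  tau <- as.matrix(agents[, c("tau_1", "tau_2", "tau_3", "tau_4")])
  rankings <- purrr::map(seq_len(nrow(agents)), function(i) {
    noisy <- tau[i, ] + rnorm(4, 0, ranking_sd)
    tibble(subject_id = agents$subject_id[i],
           gallery = config$galleries,
           ranking = rank(-noisy, ties.method = "first"))
  }) |> list_rbind()
  structure(list(trials = trials, agents = agents, rankings = rankings,
                 config = config),
            class = "rf_study")
}

#' Ground-truth thresholds in long form
#'
#' Expands the `tau_1..tau_4` columns of an agents (ground truth) tibble
#' into one row per subject and gallery, using the session's gallery cycle
#' order (`tau_i` belongs to the i-th gallery of the cycle). Convenient
#' for joining against [subject_thresholds()] when scoring recovery.
#'
#' @param agents Agents tibble (or ground-truth CSV read back).
#' @param galleries Gallery labels in cycle order.
#' @return Tibble (`subject_id`, `gallery`, `tau`).
#' @export
true_thresholds_long <- function(agents, galleries = session_config()$galleries) {
  agents |>
    select("subject_id", "tau_1", "tau_2", "tau_3", "tau_4") |>
    tidyr::pivot_longer(-"subject_id", names_to = "idx", values_to = "tau",
                        names_prefix = "tau_") |>
    mutate(gallery = galleries[as.integer(.data$idx)]) |>
    select("subject_id", "gallery", "tau")
}

#' @export
print.rf_study <- function(x, ...) {
  cat("<rf_study>", nrow(x$agents), "subjects,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
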