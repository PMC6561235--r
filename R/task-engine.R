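#' Session configuration for the risky foraging task
#'
#' Builds and validates the configuration of a simulated session of the
#' risk variant of the Web-Surf stay/skip foraging task. Subjects cycle
#' through four video galleries in a fixed order under a session clock;
#' each encounter presents either a non-risky offer (one known delay) or a
#' risky offer (three possible delays of which only the range is shown, the
#' realization being revealed only on a stay).
#'
#' @param session_minutes Session length in minutes.
#' @param galleries Character vector of exactly 4 gallery labels, visited
#'   cyclically in this order.
#' @param delay_min,delay_max Integer bounds (seconds) on all offered delays.
#' @param risky_fraction Probability that an offer is risky.
#' @param spread_choices Allowed values of `high - low` for risky offers.
#'   Must be even (mid delays are constrained to integers) and feasible
#'   within `[delay_min, delay_max]`.
#' @param travel_clicks Number of clicks in the inter-trial travel task.
#' @param click_latency_meanlog,click_latency_sdlog Log-normal parameters
#'   of the per-click travel latency in seconds.
#' @param video_seconds Video playback time charged to the clock on a stay.
#' @param rating_seconds Time charged for entering the 1-4 rating.
#' @param outcome_probs Probabilities of realizing the low, mid and high
#'   delay on a risky stay. The task never discloses these to the subject;
#'   uniform thirds is the default and matches the expected-value
#'   convention used downstream.
#' @return A list of class `rf_session_config`.
#' @examples
#' cfg <- session_config()
#' cfg$galleries
#' @export
session_config <- function(session_minutes = 40,
                           galleries = c("kittens", "dance", "landscapes", "bike_accidents"),
                           delay_min = 3,
                           delay_max = 30,
                           risky_fraction = 0.8,
                           spread_choices = c(4, 8, 12, 16, 20),
                           travel_clicks = 5,
                           click_latency_meanlog = log(0.6),
                           click_latency_sdlog = 0.3,
                           video_seconds = 4,
                           rating_seconds = 1,
                           outcome_probs = c(1, 1, 1) / 3) {
  assert_that(delay_min >= 1, "`delay_min` must be >= 1 second.")
  assert_that(delay_max > delay_min, "`delay_max` must exceed `delay_min`.")
  assert_that(risky_fraction >= 0 && risky_fraction <= 1,
              "`risky_fraction` must lie in [0, 1].")
  assert_that(travel_clicks >= 1, "`travel_clicks` must be >= 1.")
  assert_that(length(galleries) == 4 && !anyDuplicated(galleries),
              "`galleries` must be 4 distinct labels (fixed cycle order).")
  if (any(spread_choices %% 2 != 0)) {
    abort("`spread_choices` must be even: mid delays must be integers.")
  }
  if (any(spread_choices <= 0) || any(spread_choices > delay_max - delay_min)) {
    abort("Each spread must be positive and leave a feasible low delay in [delay_min, delay_max].")
  }
  assert_that(length(outcome_probs) == 3 && all(outcome_probs >= 0) &&
                abs(sum(outcome_probs) - 1) < 1e-8,
              "`outcome_probs` must be 3 non-negative probabilities summing to 1.")
  structure(
    list(session_minutes = session_minutes, galleries = galleries,
         delay_min = as.integer(delay_min), delay_max = as.integer(delay_max),
         risky_fraction = risky_fraction,
         spread_choices = as.integer(spread_choices),
         travel_clicks = as.integer(travel_clicks),
         click_latency_meanlog = click_latency_meanlog,
         click_latency_sdlog = click_latency_sdlog,
         video_seconds = video_seconds, rating_seconds = rating_seconds,
         outcome_probs = outcome_probs),
    class = "rf_session_config"
  )
}

#' Draw serial offers for a gallery
#'
#' Samples offers from the task's generative law using R's global random
#' number stream. A risky offer draws a spread from `spread_choices` and a
#' low delay uniformly over the integers for which `low + spread` stays
#' within range; the mid delay is the arithmetic midpoint. A non-risky
#' offer draws one integer delay uniformly and repeats it three times.
#'
#' @param config An [session_config()] object.
#' @param gallery Gallery label for the offers.
#' @param n Number of offers to draw.
#' @return A tibble with columns `gallery`, `low`, `mid`, `high`,
#'   `is_risky`, `spread`, one row per offer.
#' @examples
#' set.seed(1)
#' generate_offer(session_config(), "kittens", n = 3)
#' @export
generate_offer <- function(config, gallery, n = 1) {
  stopifnot(inherits(config, "rf_session_config"))
  risky <- runif(n) < config$risky_fraction
  spread <- integer(n)
  low <- integer(n)
  n_risky <- sum(risky)
  if (n_risky > 0) {
    spread[risky] <- sample(config$spread_choices, n_risky, replace = TRUE)
    # low uniform on [delay_min, delay_max - spread]
    span <- config$delay_max - spread[risky] - config$delay_min + 1L
    low[risky] <- config$delay_min +
      as.integer(floor(runif(n_risky) * span))
  }
  if (any(!risky)) {
    span <- config$delay_max - config$delay_min + 1L
    low[!risky] <- config$delay_min +
      as.integer(floor(runif(sum(!risky)) * span))
  }
  tibble(
    gallery = gallery,
    low = low,
    mid = low + spread %/% 2L,
    high = low + spread,
    is_risky = risky,
    spread = spread
  )
}

#' Realize the outcome of a stayed offer
#'
#' Called once the agent commits to staying. On a risky offer the delay is
#' drawn from \{low, mid, high\} with the configured probabilities and
#' classed by its position: the low delay is a `good` outcome, the high
#' delay a `bad` one, the middle `mid`. Non-risky offers realize their
#' known delay and are classed `nonrisk`.
#'
#' @param offer A one-row offer tibble (or list) with `low`, `mid`, `high`,
#'   `is_risky`.
#' @param outcome_probs Probabilities for low/mid/high on risky offers.
#' @return A list with `realized_delay` (integer seconds) and
#'   `outcome_class` (one of `"good"`, `"mid"`, `"bad"`, `"nonrisk"`).
#' @export
realize_outcome <- function(offer, outcome_probs = c(1, 1, 1) / 3) {
  if (!isTRUE(offer$is_risky)) {
    return(list(realized_delay = as.integer(offer$mid), outcome_class = "nonrisk"))
  }
  idx <- sample.int(3L, 1L, prob = outcome_probs)
  list(
    realized_delay = as.integer(c(offer$low, offer$mid, offer$high)[idx]),
    outcome_class = c("good", "mid", "bad")[idx]
  )
}

#' Classify the outcome of a completed trial
#'
#' Prospect-theoretic framing by outcome *type*, never value: on a risky
#' stay, receipt of the low delay is `good`, the high delay `bad`, the
#' middle `mid` -- regardless of how the delay compares with the subject's
#' threshold. Non-risky stays are `nonrisk`; skips are `none`.
#'
#' @param low,high Offered low/high delays (equal on non-risky offers).
#' @param is_risky Logical.
#' @param choice `"stay"` or `"skip"`.
#' @param realized_delay Realized delay (NA on skips).
#' @return Character vector of outcome classes.
#' @export
classify_outcome <- function(low, high, is_risky, choice, realized_delay) {
  n <- length(low)
  out <- character(n)
  skip <- choice != .STAY
  out[skip] <- "none"
  stay <- !skip
  out[stay & !is_risky] <- "nonrisk"
  rs <- stay & is_risky
  if (any(rs)) {
    mid_delay <- (low + high) / 2
    valid <- realized_delay == low | realized_delay == high |
      realized_delay == mid_delay
    if (anyNA(realized_delay[rs]) || !all(valid[rs], na.rm = TRUE)) {
      abort("Realized delay on a risky stay must be one of the offered delays.")
    }
    out[rs & realized_delay == low] <- "good"
    out[rs & realized_delay == high] <- "bad"
    out[rs & realized_delay == mid_delay & realized_delay != low &
          realized_delay != high] <- "mid"
  }
  out
}

#' Simulate one subject's session
#'
#' Runs a full session of serial stay/skip encounters for one synthetic
#' agent: the agent cycles through the four galleries in fixed order,
#' receives offers from [generate_offer()]'s law, decides by its logistic
#' choice rule with framing carry-over from the previous trial, realizes
#' outcomes, rates consumed videos on the ordered 1-4 scale, and pays the
#' travel cost after every trial. The session ends once the clock passes
#' `session_minutes`; the final trial may overrun.
#'
#' @param agent An agent as returned by [sample_population()] (one row) or
#'   a list of agent parameters.
#' @param config An [session_config()] object.
#' @param seed Optional integer; if given, the session is reproducible.
#' @return A tibble of trial records: `subject_id`, `trial_index`,
#'   `gallery`, `low`, `mid`, `high`, `is_risky`, `choice`,
#'   `realized_delay` (NA on skips), `outcome_class` (`"none"` on skips),
#'   `rating` (NA on skips), `decision_rt`, `clock_start`, `clock_end`
#'   (seconds).
#' @examples
#' pop <- sample_population(population_config(n_subjects = 1, seed = 7))
#' log1 <- run_session(pop$agents[1, ], session_config(), seed = 7)
#' head(log1)
#' @export
run_session <- function(agent, config = session_config(), seed = NULL) {
  stopifnot(inherits(config, "rf_session_config"))
  if (!is.null(seed)) set.seed(seed)
  ag <- as_agent(agent, config)
  total <- config$session_minutes * 60
  gal <- config$galleries
  probs <- cumsum(config$outcome_probs)

  cap <- 2048L
  v_gallery <- character(cap); v_low <- integer(cap); v_mid <- integer(cap)
  v_high <- integer(cap); v_risky <- logical(cap); v_choice <- character(cap)
  v_realized <- rep(NA_integer_, cap); v_class <- character(cap)
  v_rating <- rep(NA_integer_, cap); v_rt <- numeric(cap)
  v_cs <- numeric(cap); v_ce <- numeric(cap)

  clock <- 0
  t <- 0L
  prev_bad <- FALSE
  prev_value <- 0
  block <- 0L
  bsize <- 64L
  while (clock < total) {
    if (block == 0L) {
      # pre-draw randomness for a block of trials to keep the loop tight
      off <- generate_offer(config, gallery = "pending", n = bsize)
      b_low <- off$low; b_mid <- off$mid; b_high <- off$high
      b_risky <- off$is_risky
      b_uchoice <- runif(bsize)
      b_uout <- runif(bsize)
      b_rtn <- rnorm(bsize)
      b_raten <- rnorm(bsize)
      b_travel <- config$travel_clicks *
        rlnorm(bsize, config$click_latency_meanlog, config$click_latency_sdlog)
      block <- bsize
    }
    i <- bsize - block + 1L
    block <- block - 1L
    t <- t + 1L
    if (t > cap) {
      cap <- cap * 2L
      grow <- function(x) { length(x) <- cap; x }
      v_gallery <- grow(v_gallery); v_low <- grow(v_low); v_mid <- grow(v_mid)
      v_high <- grow(v_high); v_risky <- grow(v_risky); v_choice <- grow(v_choice)
      v_realized <- grow(v_realized); v_class <- grow(v_class)
      v_rating <- grow(v_rating); v_rt <- grow(v_rt)
      v_cs <- grow(v_cs); v_ce <- grow(v_ce)
    }
    g <- ((t - 1L) %% 4L) + 1L
    d <- b_mid[i]
    lp <- ag$beta * (ag$tau[g] - d) +
      (if (prev_bad) ag$gamma + ag$eta * prev_value else 0)
    p_stay <- plogis(lp)
    stay <- b_uchoice[i] < p_stay
    rt <- exp(ag$alpha0 + (if (prev_bad) ag$delta else 0) + ag$sigma_rt * b_rtn[i])
    elapsed <- rt
    if (stay) {
      if (b_risky[i]) {
        idx <- findInterval(b_uout[i], probs) + 1L
        realized <- c(b_low[i], b_mid[i], b_high[i])[idx]
        cls <- c("good", "mid", "bad")[idx]
      } else {
        realized <- b_mid[i]
        cls <- "nonrisk"
      }
      value_now <- ag$tau[g] - realized
      latent <- ag$mu[g] + ag$rate_a * value_now +
        (if (cls == "bad") ag$rate_b + ag$rate_c * value_now else 0) +
        ag$sigma_r * b_raten[i]
      rating <- 1L + sum(ag$cutpoints < latent)
      elapsed <- elapsed + realized + config$video_seconds + config$rating_seconds
      prev_bad <- b_risky[i] && cls == "bad"
      prev_value <- value_now
      v_realized[t] <- realized
      v_class[t] <- cls
      v_rating[t] <- rating
      v_choice[t] <- .STAY
    } else {
      prev_bad <- FALSE
      prev_value <- 0
      v_class[t] <- "none"
      v_choice[t] <- .SKIP
    }
    elapsed <- elapsed + b_travel[i]
    v_gallery[t] <- gal[g]
    v_low[t] <- b_low[i]; v_mid[t] <- b_mid[i]; v_high[t] <- b_high[i]
    v_risky[t] <- b_risky[i]
    v_rt[t] <- round(rt, 4)
    v_cs[t] <- round(clock, 4)
    clock <- clock + elapsed
    v_ce[t] <- round(clock, 4)
  }
  idx <- seq_len(t)
  tibble(
    subject_id = ag$subject_id,
    trial_index = idx,
    gallery = v_gallery[idx],
    low = v_low[idx], mid = v_mid[idx], high = v_high[idx],
    is_risky = v_risky[idx],
    choice = v_choice[idx],
    realized_delay = v_realized[idx],
    outcome_class = v_class[idx],
    rating = v_rating[idx],
    decision_rt = v_rt[idx],
    clock_start = v_cs[idx],
    clock_end = v_ce[idx]
  )
}
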