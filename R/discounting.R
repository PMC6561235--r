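#' Binary-choice menu for the discounting tasks
#'
#' Builds the adjusting-amount menu for hypothetical monetary choices:
#' each delay (or probability) condition pairs the full larger-later
#' (risky) amount against a titration grid of smaller-sooner (certain)
#' amounts. Amounts span $0.50 to $10.
#'
#' @param amount Larger-later / risky amount in dollars.
#' @param delays_days Delay conditions in days.
#' @param probs Probability conditions in (0, 1\].
#' @param sooner_grid Grid of smaller-sooner amounts in dollars.
#' @return A tibble: `mode` (delay/probability), `condition` (days or
#'   probability), `amount_later`, `amount_sooner`.
#' @export
discounting_menu <- function(amount = 10,
                             delays_days = c(1, 7, 14, 30, 90, 180, 365),
                             probs = c(0.95, 0.9, 0.75, 0.5, 0.25, 0.1),
                             sooner_grid = seq(0.5, 10, by = 0.5)) {
  if (any(c(amount, sooner_grid) < 0.5) || any(c(amount, sooner_grid) > 10)) {
    abort("All menu amounts must lie in [$0.50, $10].")
  }
  bind_rows(
    tidyr::crossing(mode = "delay", condition = delays_days,
                    amount_later = amount, amount_sooner = sooner_grid),
    tidyr::crossing(mode = "probability", condition = probs,
                    amount_later = amount, amount_sooner = sooner_grid)
  )
}

#' Odds against a probabilistic reward
#'
#' The transform `theta = (1 - p) / p` that places probability discounting
#' in the same hyperbolic form as delay discounting
#' (`V = A / (1 + h * theta)`): `theta(0.5) = 1`, `theta(1) = 0`.
#'
#' @param p Probability of winning, in (0, 1\].
#' @return Odds against winning.
#' @export
odds_against <- function(p) {
  assert_that(all(p > 0 & p <= 1), "`p` must lie in (0, 1].")
  (1 - p) / p
}

# hyperbolic present value over delay D (days) or odds-against theta
hyperbolic_value <- function(amount, condition, k, mode) {
  if (mode == "delay") amount / (1 + k * condition)
  else amount / (1 + k * odds_against(condition))
}

#' Generate discounting choices for synthetic agents
#'
#' Each agent chooses the later (or risky) option with probability
#' `logistic(sharpness * (discounted value - sooner amount))`, where the
#' discounted value is hyperbolic: `A / (1 + k D)` for delays and
#' `A / (1 + h theta)` with odds-against `theta = (1 - p) / p` for
#' probabilities. `sharpness = Inf` gives the deterministic
#' value-maximizing agent.
#'
#' @param agents Agents tibble from [sample_population()] (uses
#'   `logk_delay`, `logk_prob`, `choice_sharpness`).
#' @param menu Menu from [discounting_menu()].
#' @param seed Optional seed.
#' @return The menu crossed with subjects, plus a `choice` column
#'   (`"later"` / `"sooner"`).
#' @export
generate_discounting_responses <- function(agents, menu = discounting_menu(),
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::crossing(subject_id = agents$subject_id, menu) |>
    left_join(agents |> select("subject_id", "logk_delay", "logk_prob",
                               "choice_sharpness"),
              by = "subject_id")
  k <- ifelse(grid$mode == "delay", exp(grid$logk_delay), exp(grid$logk_prob))
  v <- ifelse(grid$mode == "delay",
              grid$amount_later / (1 + k * grid$condition),
              grid$amount_later / (1 + k * (1 - grid$condition) / grid$condition))
  diffv <- v - grid$amount_sooner
  p_later <- ifelse(is.infinite(grid$choice_sharpness),
                    as.numeric(diffv > 0),
                    plogis(grid$choice_sharpness * diffv))
  grid |>
    mutate(choice = ifelse(runif(dplyr::n()) < p_later, "later", "sooner")) |>
    select("subject_id", "mode", "condition", "amount_later", "amount_sooner",
           "choice")
}

#' Indifference points from titration choices
#'
#' For each condition, the indifference point is the midpoint between the
#' largest smaller-sooner amount the subject rejected (chose the
#' later/risky option) and the smallest amount accepted. Censored runs
#' (all later, or all sooner) return the grid maximum or minimum,
#' flagged. A response run without a unique switch point is flagged
#' `nonmonotone` and the midpoint of the enclosing bracket is used.
#'
#' @param choices Choice table as from [generate_discounting_responses()]
#'   for one subject (columns `mode`, `condition`, `amount_sooner`,
#'   `choice`).
#' @return Tibble per condition: `mode`, `condition`, `indifference`
#'   (dollars), `flag`.
#' @export
compute_indifference_points <- function(choices) {
  need <- c("mode", "condition", "amount_sooner", "choice")
  assert_that(all(need %in% names(choices)), "`choices` is missing required columns.")
  choices |>
    group_by(.data$mode, .data$condition) |>
    group_modify(function(d, key) {
      d <- d |> arrange(.data$amount_sooner)
      later <- d$choice == "later"
      if (all(later)) {
        return(tibble(indifference = max(d$amount_sooner), flag = "censored_high"))
      }
      if (!any(later)) {
        return(tibble(indifference = min(d$amount_sooner), flag = "censored_low"))
      }
      hi_rejected <- max(d$amount_sooner[later])    # largest sooner rejected
      lo_accepted <- min(d$amount_sooner[!later])   # smallest sooner accepted
      flag <- if (hi_rejected > lo_accepted) "nonmonotone" else NA_character_
      tibble(indifference = (hi_rejected + lo_accepted) / 2, flag = flag)
    }) |>
    ungroup()
}

#' Fit a hyperbolic discounting function
#'
#' Least-squares fit of `V = A / (1 + k D)` (delay, D in days) or
#' `V = A / (1 + h theta)` with `theta = (1 - p) / p` (probability) to
#' indifference points. The rate is constrained positive by optimizing
#' over log k. R-squared is `1 - SSE/SST` over the indifference points.
#' Degenerate data driving the rate to the search boundary are flagged.
#'
#' @param indifference Indifference points in dollars.
#' @param conditions Delay in days, or probability, per point.
#' @param mode `"delay"` or `"probability"`.
#' @param amount Larger-later / risky amount.
#' @param logk_bounds Search interval for log k.
#' @return An object of class `rf_discount_fit`: `k`, `log_k`,
#'   `r_squared`, `n_points`, `mode`, `flags`, plus the data.
#' @examples
#' d <- c(1, 7, 30, 180)
#' v <- 10 / (1 + exp(-5.26) * d)
#' fit_hyperbolic(v, d, "delay")
#' @export
fit_hyperbolic <- function(indifference, conditions,
                           mode = c("delay", "probability"),
                           amount = 10, logk_bounds = c(-20, 5)) {
  mode <- match.arg(mode)
  assert_that(length(indifference) >= 3, "Need at least 3 conditions to fit.")
  assert_that(length(indifference) == length(conditions),
              "`indifference` and `conditions` lengths differ.")
  sse <- function(logk) {
    sum((indifference - hyperbolic_value(amount, conditions, exp(logk), mode))^2)
  }
  opt <- optimize(sse, interval = logk_bounds, tol = 1e-10)
  logk <- opt$minimum
  flags <- character(0)
  if (logk < logk_bounds[1] + 0.05 || logk > logk_bounds[2] - 0.05) {
    flags <- c(flags, "rate_at_boundary")
  }
  sst <- sum((indifference - mean(indifference))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  if (sst == 0) flags <- c(flags, "degenerate_points")
  structure(list(k = exp(logk), log_k = logk, r_squared = r2,
                 n_points = length(indifference), mode = mode,
                 amount = amount, conditions = conditions,
                 indifference = indifference, flags = flags),
            class = "rf_discount_fit")
}

#' @export
print.rf_discount_fit <- function(x, ...) {
  cat("<rf_discount_fit>", x$mode, ": k =", signif(x$k, 4),
      "(ln k =", round(x$log_k, 3), "), R^2 =", round(x$r_squared, 3), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.rf_discount_fit <- function(x, ...) {
  tibble(term = c("k", "log_k"), estimate = c(x$k, x$log_k))
}

#' @export
glance.rf_discount_fit <- function(x, ...) {
  tibble(k = x$k, log_k = x$log_k, r_squared = x$r_squared,
         n_points = x$n_points, mode = x$mode,
         flagged = length(x$flags) > 0)
}

#' Johnson-Bickel checks for nonsystematic discounting data
#'
#' Applied to indifference points ordered by increasing delay (or
#' increasing odds against): criterion 1 flags any point exceeding its
#' predecessor by more than 20% of the larger-later amount (a bounce);
#' criterion 2 flags curves whose last point is not at least 10% of the
#' larger-later amount below the first (no overall discounting).
#'
#' @param indifference Indifference points ordered by condition severity.
#' @param amount Larger-later amount.
#' @param bounce_tol Criterion-1 threshold as a fraction of `amount`.
#' @param drop_tol Criterion-2 minimum first-to-last drop as a fraction
#'   of `amount`.
#' @return A list with logical `c1` and `c2`.
#' @export
johnson_bickel_flags <- function(indifference, amount = 10,
                                 bounce_tol = 0.2, drop_tol = 0.1) {
  assert_that(length(indifference) >= 2,
              "Johnson-Bickel checks need at least 2 points.")
  inc <- diff(indifference)
  list(
    c1 = any(inc > bounce_tol * amount),
    c2 = (indifference[1] - indifference[length(indifference)]) < drop_tol * amount
  )
}

#' Fit discounting rates for every subject
#'
#' Convenience pipeline: indifference points, hyperbolic fits and
#' Johnson-Bickel flags per subject for both modes.
#'
#' @param choices Choice table for many subjects
#'   (see [generate_discounting_responses()]).
#' @param amount Larger-later amount.
#' @return Tibble per subject and mode: `logk`, `k`, `r_squared`, `jb_c1`,
#'   `jb_c2`, `n_flagged_points`.
#' @export
fit_discounting_subjects <- function(choices, amount = 10) {
  choices |>
    group_by(.data$subject_id, .data$mode) |>
    group_modify(function(d, key) {
      ip <- compute_indifference_points(d |> mutate(mode = key$mode))
      ip <- ip |> arrange(if (key$mode == "delay") .data$condition
                          else -.data$condition)
      fit <- fit_hyperbolic(ip$indifference, ip$condition, key$mode, amount)
      jb <- johnson_bickel_flags(ip$indifference, amount)
      tibble(logk = fit$log_k, k = fit$k, r_squared = fit$r_squared,
             jb_c1 = jb$c1, jb_c2 = jb$c2,
             n_flagged_points = sum(!is.na(ip$flag)))
    }) |>
    ungroup()
}
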