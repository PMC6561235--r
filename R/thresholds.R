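#' Fit a Heaviside step threshold to stay/skip data
#'
#' Finds the delay threshold T minimizing the sum of squared residuals
#' between the observed choices (stay = 1, skip = 0) and the step
#' predictor `1 - H(delay - T)`, where [heaviside()] takes the value 1/2
#' at zero. Unlike a logistic fit, the step fit stays finite in the
#' extreme cases: all-stay data return the maximum offered delay and
#' all-skip data the minimum. Candidate thresholds are the range bounds
#' and the midpoints between adjacent distinct delays; if several
#' candidates tie, the midpoint of the tied range is returned.
#'
#' @param delay Presented delays (seconds). For risky offers this is the
#'   mid value.
#' @param choice Choices as `"stay"`/`"skip"` or 1/0.
#' @param delay_range Delay bounds of the task.
#' @return Threshold in seconds.
#' @examples
#' fit_heaviside_threshold(c(4, 6, 8, 10, 12), c(1, 1, 1, 0, 0))  # 9
#' @export
fit_heaviside_threshold <- function(delay, choice, delay_range = c(3, 30)) {
  if (length(delay) == 0) abort("Need at least one trial to fit a threshold.")
  y <- normalize_choice(choice)
  assert_that(length(delay) == length(y), "`delay` and `choice` lengths differ.")
  if (all(y == 1)) return(max(delay))
  if (all(y == 0)) return(min(delay))
  cands <- threshold_candidates(delay, delay_range)
  sse <- vapply(cands, function(tt) step_sse(tt, delay, y), 0)
  best <- cands[sse == min(sse)]
  (min(best) + max(best)) / 2
}

# stay=1 predictor: 1 - H(d - T)
step_sse <- function(tt, delay, y) {
  pred <- 1 - heaviside(delay - tt)
  sum((y - pred)^2)
}

threshold_candidates <- function(delay, delay_range) {
  u <- sort(unique(delay))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  unique(c(delay_range[1], mids, delay_range[2]))
}

normalize_choice <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    choice <- as.character(choice)
    bad <- !choice %in% c(.STAY, .SKIP)
    if (any(bad)) abort("Choices must be 'stay'/'skip' or 1/0.")
    return(as.numeric(choice == .STAY))
  }
  if (!all(choice %in% c(0, 1))) abort("Choices must be 'stay'/'skip' or 1/0.")
  as.numeric(choice)
}

#' Leave-one-out threshold vector for one gallery
#'
#' For each risky trial i in a gallery, fits the Heaviside threshold to
#' all of the gallery's risky trials excluding trial i (risky trials are
#' represented by their mid delay), so a trial never influences its own
#' covariate. The result has one threshold per risky trial.
#'
#' @param delay Presented (mid) delays of the gallery's risky trials.
#' @param choice Corresponding choices.
#' @inheritParams fit_heaviside_threshold
#' @return Numeric vector of thresholds, one per input trial.
#' @export
loo_threshold_vector <- function(delay, choice, delay_range = c(3, 30)) {
  n <- length(delay)
  if (n < 2) abort("Leave-one-out thresholds need at least 2 trials in the gallery.")
  y <- normalize_choice(choice)
  vapply(seq_len(n), function(i) {
    fit_heaviside_threshold(delay[-i], y[-i], delay_range)
  }, 0)
}

#' Assign per-trial thresholds and expected values
#'
#' Computes the full revealed-preference threshold set for a study: for
#' every subject and gallery, the leave-one-out threshold vector over the
#' gallery's risky trials; each risky trial is assigned its own
#' leave-one-out threshold, and every non-risky trial the mean of the
#' gallery's threshold vector. Per-trial expected value is the threshold
#' minus the mean offered delay (the offered delay itself on non-risky
#' trials). Galleries with fewer than two risky trials cannot support the
#' leave-one-out fit; their trials are flagged and their thresholds left
#' missing.
#'
#' @param trials Trial tibble as produced by [run_session()] /
#'   [simulate_study()] (or read back from a session log).
#' @param delay_range Delay bounds of the task.
#' @return An object of class `rf_threshold_set`: a tibble keyed by
#'   (`subject_id`, `trial_index`) with columns `gallery`, `is_risky`,
#'   `assigned_threshold`, `expected_value` and `flag`, with the
#'   per-subject-per-gallery mean thresholds in attribute
#'   `"gallery_thresholds"` (see [subject_thresholds()]).
#' @export
assign_trial_thresholds <- function(trials, delay_range = c(3, 30)) {
  need <- c("subject_id", "trial_index", "gallery", "low", "mid", "high",
            "is_risky", "choice")
  assert_that(all(need %in% names(trials)), "`trials` is missing required columns.")
  per_gallery <- trials |>
    group_by(.data$subject_id, .data$gallery) |>
    group_modify(function(df, key) {
      risky <- df$is_risky
      out <- tibble(trial_index = df$trial_index,
                    is_risky = risky,
                    assigned_threshold = NA_real_,
                    flag = NA_character_)
      if (sum(risky) < 2) {
        out$flag <- "insufficient_risky_trials"
        return(out)
      }
      loo <- loo_threshold_vector(df$mid[risky], df$choice[risky], delay_range)
      out$assigned_threshold[risky] <- loo
      out$assigned_threshold[!risky] <- mean(loo)
      out
    }) |>
    ungroup()
  res <- trials |>
    select(all_of(need)) |>
    left_join(per_gallery, by = c("subject_id", "gallery", "trial_index", "is_risky")) |>
    mutate(expected_value = .data$assigned_threshold -
             (.data$low + .data$mid + .data$high) / 3) |>
    arrange(.data$subject_id, .data$trial_index)
  gal <- res |>
    group_by(.data$subject_id, .data$gallery) |>
    summarise(threshold = mean(.data$assigned_threshold[.data$is_risky]),
              n_risky = sum(.data$is_risky), .groups = "drop")
  structure(res, gallery_thresholds = gal,
            class = c("rf_threshold_set", class(res)))
}

#' Per-subject gallery thresholds
#'
#' The four subject-level thresholds: for each gallery, the mean of the
#' leave-one-out threshold vector.
#'
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @return Tibble (`subject_id`, `gallery`, `threshold`, `n_risky`).
#' @export
subject_thresholds <- function(threshold_set) {
  attr(threshold_set, "gallery_thresholds")
}

#' Expected value of an offer against a threshold
#'
#' Linear value convention: threshold minus the offered delay for
#' non-risky offers, and the average of the three delay-specific values
#' (equivalently threshold minus the mean of low/mid/high, assuming equal
#' likelihood) for risky offers. With delays and thresholds confined to
#' \[3, 30\] s, expected value spans \[-27, 27\]; zero means the offer
#' equals the revealed threshold.
#'
#' @param low,mid,high Offered delays (equal for non-risky offers).
#' @param threshold Assigned threshold (seconds).
#' @return Expected value in seconds (positive = better than the
#'   subject's revealed price).
#' @examples
#' expected_value(5, 10, 15, threshold = 20)  # 10
#' @export
expected_value <- function(low, mid, high, threshold) {
  if (anyNA(threshold)) abort("`threshold` must be present to compute expected value.")
  threshold - (low + mid + high) / 3
}

#' Validity correlations between thresholds and stated preferences
#'
#' External validity of the revealed thresholds: per subject, the Pearson
#' correlation across the four galleries between the gallery thresholds
#' and (a) the subject's mean video ratings and (b) the post-task gallery
#' rankings. Rankings use rank 1 = most preferred and are negated before
#' correlating so that a positive r means consistency in both columns.
#'
#' @param trials Trial tibble (for the mean ratings on stay trials).
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param rankings Tibble (`subject_id`, `gallery`, `ranking`).
#' @return Tibble per subject: `r_rating`, `r_ranking`, and flags naming
#'   any degenerate (zero-variance) input that made a correlation
#'   undefined.
#' @export
validity_correlations <- function(trials, threshold_set, rankings) {
  thr <- subject_thresholds(threshold_set)
  mean_ratings <- trials |>
    filter(.data$choice == .STAY) |>
    group_by(.data$subject_id, .data$gallery) |>
    summarise(mean_rating = mean(.data$rating), .groups = "drop")
  joined <- thr |>
    left_join(mean_ratings, by = c("subject_id", "gallery")) |>
    left_join(rankings, by = c("subject_id", "gallery"))
  joined |>
    group_by(.data$subject_id) |>
    group_modify(function(df, key) {
      r1 <- safe_cor(df$threshold, df$mean_rating)
      r2 <- safe_cor(df$threshold, -df$ranking)
      flag <- paste(c(
        if (is.na(r1)) "rating_correlation_undefined",
        if (is.na(r2)) "ranking_correlation_undefined"
      ), collapse = ";")
      tibble(r_rating = r1, r_ranking = r2,
             flag = if (flag == "") NA_character_ else flag)
    }) |>
    ungroup()
}

safe_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Threshold-aligned psychophysics curve
#'
#' Aligns every trial at (presented delay - assigned threshold), bins the
#' aligned delays, computes each subject's stay proportion per bin, and
#' averages across subjects, separately for risky and non-risky trials.
#' Bins no subject contributes to are simply absent.
#'
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param bin_width Bin width in seconds.
#' @return A tibble of class `rf_psych_curve`: `condition`
#'   (risky/non-risky), `bin` (center of the aligned-delay bin),
#'   `stay_rate` and `n_subjects`.
#' @export
psychophysics_curve <- function(threshold_set, bin_width = 1) {
  df <- threshold_set |>
    filter(!is.na(.data$assigned_threshold)) |>
    mutate(
      aligned = .data$mid - .data$assigned_threshold,
      bin = (floor(.data$aligned / bin_width) + 0.5) * bin_width,
      stay = as.numeric(.data$choice == .STAY),
      condition = ifelse(.data$is_risky, "risky", "non-risky")
    )
  out <- df |>
    group_by(.data$condition, .data$subject_id, .data$bin) |>
    summarise(stay = mean(.data$stay), .groups = "drop") |>
    group_by(.data$condition, .data$bin) |>
    summarise(stay_rate = mean(.data$stay), n_subjects = dplyr::n(),
              .groups = "drop")
  class(out) <- c("rf_psych_curve", class(out))
  out
}
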