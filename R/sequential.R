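#' Build the trial-level dataset for a sequential model family
#'
#' Derives the lagged covariates the framing analyses need and applies the
#' row filter of the requested model family. Derived columns:
#' * `value_now` / `value_prev`: actual value, i.e. the trial's assigned
#'   threshold minus its realized delay (defined on stays only);
#' * `class_now` / `class_prev`: framing class (good/mid/bad/nonrisk/none);
#' * `rating_centered`: rating minus the subject's mean rating for that
#'   gallery (over stay trials);
#' * `videos_consumed`: number of videos consumed before trial t;
#' * `ev_now`: expected value of the current offer; `spread`: its risk
#'   level (high - low, in seconds);
#' * `log_rt`: log decision reaction time.
#'
#' Row filters: `"choice"` keeps trials whose previous trial was a risky
#' stay and whose current offer is risky; `"rating"` keeps risky stays;
#' `"rt"` keeps trials preceded by a risky stay; `"global_choice"` keeps
#' all trials; `"global_rating"` keeps stays (ratings only exist there);
#' `"control"` uses the `"choice"` filter (its extra covariates are
#' consumption and risk level); `"secondary"` keeps risky-offer trials
#' whose previous trial was a stay with a good, bad or non-risky outcome
#' (three-level framing-and-risk coding).
#'
#' Rows whose required thresholds are missing are dropped; the count is in
#' attribute `"dropped"`.
#'
#' @param trials Trial tibble.
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param target Model family (see above).
#' @param rating_lag If `TRUE`, the rating families use the previous
#'   trial's value/outcome instead of the current trial's.
#' @return A tibble with the columns listed above, filtered for `target`.
#' @export
prepare_sequential_dataset <- function(trials, threshold_set,
                                       target = c("choice", "rating", "rt",
                                                  "global_choice", "global_rating",
                                                  "control", "secondary"),
                                       rating_lag = FALSE) {
  target <- match.arg(target)
  thr <- threshold_set |>
    select("subject_id", "trial_index", "assigned_threshold", "expected_value")
  df <- trials |>
    left_join(thr, by = c("subject_id", "trial_index")) |>
    group_by(.data$subject_id) |>
    arrange(.data$trial_index, .by_group = TRUE) |>
    mutate(
      stay = as.numeric(.data$choice == .STAY),
      value_now = .data$assigned_threshold - .data$realized_delay,
      class_now = .data$outcome_class,
      log_rt = log(.data$decision_rt),
      videos_consumed = dplyr::lag(cumsum(.data$stay), default = 0),
      spread = .data$high - .data$low,
      ev_now = .data$expected_value,
      value_prev = dplyr::lag(.data$value_now),
      class_prev = dplyr::lag(.data$outcome_class),
      risky_prev = dplyr::lag(.data$is_risky),
      stay_prev = dplyr::lag(.data$stay)
    ) |>
    group_by(.data$subject_id, .data$gallery) |>
    mutate(rating_centered = .data$rating -
             mean(.data$rating[.data$choice == .STAY])) |>
    group_by(.data$subject_id) |>
    arrange(.data$trial_index, .by_group = TRUE) |>
    mutate(rating_prev_centered = dplyr::lag(.data$rating_centered)) |>
    ungroup()

  out <- switch(
    target,
    choice = ,
    control = df |>
      filter(.data$risky_prev, .data$stay_prev == 1, .data$is_risky,
             .data$class_prev %in% c("good", "mid", "bad")) |>
      mutate(class_prev = factor(.data$class_prev, levels = c("good", "bad", "mid"))),
    rating = {
      d <- df |> filter(.data$is_risky, .data$stay == 1)
      if (rating_lag) {
        d <- d |>
          filter(.data$risky_prev, .data$stay_prev == 1,
                 .data$class_prev %in% c("good", "mid", "bad")) |>
          mutate(value_now = .data$value_prev,
                 class_now = .data$class_prev)
      }
      d |> mutate(class_now = factor(.data$class_now, levels = c("good", "bad", "mid")))
    },
    rt = df |>
      filter(.data$risky_prev, .data$stay_prev == 1,
             .data$class_prev %in% c("good", "mid", "bad")) |>
      mutate(class_prev = factor(.data$class_prev, levels = c("good", "bad", "mid"))),
    global_choice = df,
    global_rating = df |> filter(.data$stay == 1),
    secondary = df |>
      filter(.data$is_risky, .data$stay_prev == 1,
             .data$class_prev %in% c("good", "bad", "nonrisk")) |>
      mutate(class_prev = factor(.data$class_prev,
                                 levels = c("bad", "good", "nonrisk")))
  )
  needed <- switch(
    target,
    choice = , control = , rt = "value_prev",
    secondary = c("value_prev", "rating_prev_centered"),
    rating = "value_now",
    global_choice = , global_rating = "ev_now"
  )
  keep <- complete.cases(out[, needed, drop = FALSE])
  dropped <- sum(!keep)
  out <- out[keep, ]
  if (dropped > 0) {
    rlang::inform(paste0("prepare_sequential_dataset: dropped ", dropped,
                         " row(s) with missing thresholds (target = ", target, ")."))
  }
  attr(out, "dropped") <- dropped
  attr(out, "target") <- target
  out
}

#' Greedy value-matched subsets for follow-up contrasts
#'
#' Pairs each trial of the focal class with an unused trial of the
#' comparison class from the same subject whose matching value lies within
#' the tolerance, taking nearest values first. Unmatched trials are
#' dropped; subjects contributing no pair contribute nothing. Matching is
#' done subject by subject and the pairs are then pooled for the group
#' analysis.
#'
#' @param data A prepared dataset (see [prepare_sequential_dataset()]).
#' @param class_col Name of the class column to contrast.
#' @param value_col Name of the value column to match on.
#' @param levels Length-2 character: focal level first (e.g. `"bad"`),
#'   comparison level second.
#' @param tolerance Maximum absolute value difference within a pair
#'   (seconds).
#' @return The matched rows with a `pair_id` column; the number of dropped
#'   rows is attached as attribute `"dropped"`.
#' @export
build_matched_subsets <- function(data, class_col = "class_prev",
                                  value_col = "value_prev",
                                  levels = c("bad", "good"),
                                  tolerance = 0.5) {
  assert_that(length(levels) == 2, "`levels` must name the two classes to match.")
  df <- data |>
    filter(as.character(.data[[class_col]]) %in% levels)
  matched <- df |>
    group_by(.data$subject_id) |>
    group_modify(function(d, key) {
      cls <- as.character(d[[class_col]])
      v <- d[[value_col]]
      foc <- which(cls == levels[1])
      comp <- which(cls == levels[2])
      if (length(foc) == 0 || length(comp) == 0) {
        return(d[0, ] |> mutate(pair_id = integer(0)))
      }
      used <- logical(length(comp))
      pairs <- list()
      pid <- 0L
      # nearest pairs first: consider all feasible pairs by distance
      cand <- expand.grid(f = seq_along(foc), c = seq_along(comp))
      cand$dist <- abs(v[foc[cand$f]] - v[comp[cand$c]])
      cand <- cand[cand$dist <= tolerance, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_f <- logical(length(foc))
      for (r in seq_len(nrow(cand))) {
        fi <- cand$f[r]; ci <- cand$c[r]
        if (used_f[fi] || used[ci]) next
        used_f[fi] <- TRUE; used[ci] <- TRUE
        pid <- pid + 1L
        pairs[[pid]] <- d[c(foc[fi], comp[ci]), ] |> mutate(pair_id = pid)
      }
      if (pid == 0) return(d[0, ] |> mutate(pair_id = integer(0)))
      bind_rows(pairs)
    }) |>
    ungroup() |>
    mutate(pair_id = paste(.data$subject_id, .data$pair_id, sep = "_"))
  attr(matched, "dropped") <- nrow(df) - nrow(matched)
  matched
}
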