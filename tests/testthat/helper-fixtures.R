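# Shared fixtures, built in code at test time.

# Small simulated study used by several files; built once per test run.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        population_config(n_subjects = 8, seed = 101),
        session_config(session_minutes = 20),
        seed = 101
      )
    }
    cache
  }
})

small_thresholds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- assign_trial_thresholds(small_study()$trials)
    }
    cache
  }
})

# Independent brute-force oracle for the Heaviside threshold fit: direct
# enumeration of candidate thresholds with explicit step-function SSE and
# the midpoint tie rule.
oracle_step_threshold <- function(delay, stay, delay_range = c(3, 30)) {
  if (all(stay == 1)) return(max(delay))
  if (all(stay == 0)) return(min(delay))
  u <- sort(unique(delay))
  cands <- unique(c(delay_range[1],
                    if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                    delay_range[2]))
  sse <- sapply(cands, function(tt) {
    pred <- ifelse(delay < tt, 1, ifelse(delay > tt, 0, 0.5))
    sum((stay - pred)^2)
  })
  best <- cands[sse == min(sse)]
  (min(best) + max(best)) / 2
}

# Hand-computed Benjamini-Hochberg step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) ranked[i] <- min(ranked[i], ranked[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(ranked, 1)
  out
}

# A hand-built minimal trial tibble (one subject, one gallery block)
make_trials <- function(df) {
  defaults <- tibble::tibble(
    subject_id = "S001", trial_index = seq_len(nrow(df)), gallery = "kittens",
    low = 10L, mid = 10L, high = 10L, is_risky = FALSE, choice = "stay",
    realized_delay = NA_integer_, outcome_class = "none", rating = NA_integer_,
    decision_rt = 1, clock_start = as.numeric(seq_len(nrow(df))),
    clock_end = as.numeric(seq_len(nrow(df))) + 0.5
  )
  for (nm in names(df)) defaults[[nm]] <- df[[nm]]
  defaults
}
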