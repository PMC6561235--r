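#' Fit a group-level mixed-effects model
#'
#' Thin contract over `lme4`/`lmerTest`: binary outcomes are fit with a
#' logistic mixed model, continuous outcomes with a linear mixed model
#' (Satterthwaite p-values). Random-effect terms are written in the
#' formula as usual (`(1 | subject_id)` or `(value_prev | subject_id)`,
#' the latter fitted as correlated random intercept + slope). The result
#' carries a tidy coefficient table with 95% Wald intervals and
#' within-model Benjamini-Hochberg adjusted p-values over the
#' non-intercept fixed effects. Non-convergence and likely separation are
#' flagged, never silently ignored.
#'
#' @param data Model dataset (see [prepare_sequential_dataset()]).
#' @param formula Model formula including random-effect terms.
#' @param outcome_kind `"binary"` or `"continuous"`.
#' @return An object of class `rf_mixed` with elements `fit`, `table`
#'   (tibble: term, estimate, ci_lo, ci_hi, p, p_adj), `converged`,
#'   `flags`, `n_obs`, `n_subjects`.
#' @export
fit_mixed_model <- function(data, formula, outcome_kind = c("binary", "continuous")) {
  outcome_kind <- match.arg(outcome_kind)
  assert_that(nrow(data) > 0, "Model dataset is empty.")
  n_subj <- length(unique(data$subject_id))
  flags <- character(0)
  has_ranef <- length(lme4::findbars(formula)) > 0
  if (n_subj < 2 || !has_ranef) {
    if (n_subj < 2) flags <- c(flags, "single_group_fixed_effects")
    fixed <- if (has_ranef) lme4::nobars(formula) else formula
    fit <- if (outcome_kind == "binary") {
      glm(fixed, data = data, family = binomial())
    } else {
      lm(fixed, data = data)
    }
    tab <- coef_table_fixed(fit)
    return(new_rf_mixed(fit, tab, TRUE, flags, nrow(data), n_subj))
  }
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch({
      if (outcome_kind == "binary") {
        lme4::glmer(formula, data = data, family = binomial())
      } else {
        lmerTest::lmer(formula, data = data)
      }
    }, error = function(e) e),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (inherits(fit, "error")) {
    return(new_rf_mixed(NULL, empty_coef_table(), FALSE,
                        c(flags, paste0("fit_error: ", conditionMessage(fit))),
                        nrow(data), n_subj))
  }
  converged <- !any(grepl("converge|Hessian|singular", warn_msgs, ignore.case = TRUE))
  if (!converged) flags <- c(flags, paste0("convergence: ", unique(warn_msgs)))
  tab <- withCallingHandlers(
    coef_table_mixed(fit, outcome_kind),
    warning = function(w) {
      flags <<- c(flags, paste0("vcov: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  if (any(abs(tab$estimate) > 10 & (tab$ci_hi - tab$ci_lo) > 40, na.rm = TRUE)) {
    flags <- c(flags, "possible_separation")
  }
  new_rf_mixed(fit, tab, converged, flags, nrow(data), n_subj)
}

new_rf_mixed <- function(fit, table, converged, flags, n_obs, n_subjects) {
  structure(list(fit = fit, table = table, converged = converged,
                 flags = flags, n_obs = n_obs, n_subjects = n_subjects),
            class = "rf_mixed")
}

empty_coef_table <- function() {
  tibble(term = character(0), estimate = numeric(0), ci_lo = numeric(0),
         ci_hi = numeric(0), p = numeric(0), p_adj = numeric(0))
}

coef_table_mixed <- function(fit, outcome_kind) {
  cm <- as.data.frame(coef(summary(fit)))
  est <- cm[, "Estimate"]
  se <- cm[, "Std. Error"]
  if (outcome_kind == "binary") {
    p <- cm[, "Pr(>|z|)"]
    lo <- est - qnorm(0.975) * se
    hi <- est + qnorm(0.975) * se
  } else {
    p <- cm[, "Pr(>|t|)"]
    dfree <- cm[, "df"]
    lo <- est - qt(0.975, dfree) * se
    hi <- est + qt(0.975, dfree) * se
  }
  finalize_coef_table(rownames(cm), est, lo, hi, p)
}

coef_table_fixed <- function(fit) {
  cm <- coef(summary(fit))
  est <- cm[, 1]
  se <- cm[, 2]
  p <- cm[, 4]
  finalize_coef_table(rownames(cm), est, est - qnorm(0.975) * se,
                      est + qnorm(0.975) * se, p)
}

finalize_coef_table <- function(term, est, lo, hi, p) {
  tab <- tibble(term = term, estimate = est, ci_lo = lo, ci_hi = hi, p = p)
  adjustable <- tab$term != "(Intercept)" & is.finite(tab$p)
  tab$p_adj <- NA_real_
  if (any(adjustable)) {
    tab$p_adj[adjustable] <- bh_adjust(pmin(pmax(tab$p[adjustable], 0), 1))
  }
  tab
}

#' @export
print.rf_mixed <- function(x, ...) {
  cat("<rf_mixed>", x$n_obs, "obs,", x$n_subjects, "subjects;",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rf_mixed <- function(x, ...) x$table

#' @export
glance.rf_mixed <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_subjects = x$n_subjects,
         converged = x$converged,
         logLik = tryCatch(as.numeric(logLik(x$fit)), error = function(e) NA_real_),
         n_flags = length(x$flags))
}

#' Run the full sequential model suite
#'
#' Fits the seven families of group-level models on one study's logs:
#'
#' 1. primary choice: `stay ~ value_prev + class_prev + (1|subject)` on
#'    risky stays followed by a risky offer (framing classes good/bad/mid,
#'    reference good);
#' 2. primary rating: `rating_centered ~ value_now + class_now +
#'    (1|subject)` on risky stays;
#' 3. reaction time: `log_rt ~ value_prev + class_prev + (1|subject)`;
#' 4. matched follow-ups for choice (bad vs good, bad vs non-risk) with
#'    value-by-class interaction and a correlated random value slope per
#'    subject, on greedily value-matched subsets;
#' 5. matched follow-ups for rating (same two contrasts, current-trial
#'    framing);
#' 6. global trends: choice and rating against videos consumed, expected
#'    value, risk indicator and consumption-by-risk interaction, on all
#'    trials / all stays respectively;
#' 7. control: primary choice terms plus videos consumed and continuous
#'    risk level; and the secondary integrated model with three-level
#'    framing-and-risk coding (reference bad) and rating interactions.
#'
#' Benjamini-Hochberg adjustment is applied within each model's fixed
#' effects. Simple-slope follow-ups (the value-to-response association
#' within each framing class of the matched subsets) are returned
#' alongside. Empty model datasets are skipped with a recorded reason.
#'
#' @param trials Trial tibble.
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param matching_tolerance Seconds of slack for value matching.
#' @return A list of class `rf_model_suite`: `models` (named list of
#'   `rf_mixed`), `simple_slopes` (tibble), `skipped` (named reasons).
#' @export
run_model_suite <- function(trials, threshold_set, matching_tolerance = 0.5) {
  models <- list()
  skipped <- list()
  slopes <- list()

  add_model <- function(name, data, formula, kind) {
    if (is.null(data) || nrow(data) == 0) {
      skipped[[name]] <<- "empty model dataset"
      return(invisible(NULL))
    }
    models[[name]] <<- fit_mixed_model(data, formula, kind)
  }

  d_choice <- prepare_sequential_dataset(trials, threshold_set, "choice")
  add_model("choice_primary", d_choice,
            stay ~ value_prev + class_prev + (1 | subject_id), "binary")

  d_rating <- prepare_sequential_dataset(trials, threshold_set, "rating")
  add_model("rating_primary", d_rating,
            rating_centered ~ value_now + class_now + (1 | subject_id), "continuous")

  d_rt <- prepare_sequential_dataset(trials, threshold_set, "rt")
  add_model("rt_framing", d_rt,
            log_rt ~ value_prev + class_prev + (1 | subject_id), "continuous")

  # matched follow-ups: choice (previous-trial framing)
  for (lv in list(c("bad", "good"), c("bad", "nonrisk"))) {
    nm <- paste0("choice_matched_bad_", lv[2])
    src <- if (lv[2] == "nonrisk") {
      prepare_sequential_dataset(trials, threshold_set, "secondary") |>
        mutate(class_prev = droplevels(.data$class_prev))
    } else d_choice
    m <- build_matched_subsets(src, "class_prev", "value_prev", lv,
                               matching_tolerance)
    if (nrow(m) == 0) { skipped[[nm]] <- "no value-matched pairs"; next }
    m <- m |> mutate(class_prev = factor(as.character(.data$class_prev),
                                         levels = rev(lv)))
    add_model(nm, m,
              stay ~ value_prev * class_prev + (value_prev | subject_id), "binary")
    slopes[[nm]] <- simple_slopes(m, "stay", "value_prev", "class_prev", "binary")
  }

  # matched follow-ups: rating (current-trial framing)
  d_rate_all <- prepare_sequential_dataset(trials, threshold_set, "global_rating") |>
    filter(.data$class_now %in% c("good", "bad", "nonrisk"))
  for (lv in list(c("bad", "good"), c("bad", "nonrisk"))) {
    nm <- paste0("rating_matched_bad_", lv[2])
    m <- build_matched_subsets(d_rate_all, "class_now", "value_now", lv,
                               matching_tolerance)
    if (nrow(m) == 0) { skipped[[nm]] <- "no value-matched pairs"; next }
    m <- m |> mutate(class_now = factor(as.character(.data$class_now),
                                        levels = rev(lv)))
    add_model(nm, m,
              rating_centered ~ value_now * class_now + (value_now | subject_id),
              "continuous")
    slopes[[nm]] <- simple_slopes(m, "rating_centered", "value_now", "class_now",
                                  "continuous")
  }

  d_global <- prepare_sequential_dataset(trials, threshold_set, "global_choice")
  add_model("global_choice", d_global,
            stay ~ videos_consumed * is_risky + ev_now + (1 | subject_id), "binary")
  d_grate <- prepare_sequential_dataset(trials, threshold_set, "global_rating")
  add_model("global_rating", d_grate,
            rating_centered ~ videos_consumed * is_risky + ev_now + (1 | subject_id),
            "continuous")

  d_control <- prepare_sequential_dataset(trials, threshold_set, "control")
  add_model("control_choice", d_control,
            stay ~ value_prev + class_prev + videos_consumed + spread +
              (1 | subject_id), "binary")

  d_sec <- prepare_sequential_dataset(trials, threshold_set, "secondary")
  add_model("secondary_integrated", d_sec,
            stay ~ value_prev + rating_prev_centered + class_prev +
              value_prev:rating_prev_centered + value_prev:class_prev +
              (1 | subject_id), "binary")

  structure(list(models = models,
                 simple_slopes = if (length(slopes)) bind_rows(slopes, .id = "model")
                                 else tibble(),
                 skipped = skipped),
            class = "rf_model_suite")
}

# per-class value slope with random intercept (follow-up to an interaction)
simple_slopes <- function(data, response, value_col, class_col, kind) {
  data |>
    group_by(cls = as.character(.data[[class_col]])) |>
    group_modify(function(d, key) {
      if (nrow(d) < 10 || length(unique(d$subject_id)) < 2) {
        return(tibble(term = value_col, estimate = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p = NA_real_, p_adj = NA_real_))
      }
      f <- as.formula(paste(response, "~", value_col, "+ (1 | subject_id)"))
      fit <- fit_mixed_model(d, f, kind)
      fit$table |> filter(.data$term == value_col)
    }) |>
    ungroup() |>
    rename(class = "cls")
}

#' Tidy all coefficient tables of a model suite
#'
#' @param x An `rf_model_suite`.
#' @param ... Unused.
#' @return One tibble with a `model` column stacked over all fitted
#'   models' coefficient tables.
#' @export
tidy.rf_model_suite <- function(x, ...) {
  purrr::map(x$models, "table") |> bind_rows(.id = "model")
}

#' @export
print.rf_model_suite <- function(x, ...) {
  cat("<rf_model_suite>", length(x$models), "fitted model(s)")
  if (length(x$skipped)) {
    cat(";", length(x$skipped), "skipped:",
        paste(names(x$skipped), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
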