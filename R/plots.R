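#' Plot a threshold-aligned psychophysics curve
#'
#' Stay proportion against (presented delay - threshold), averaged within
#' subject then across subjects, for risky and non-risky trials. The
#' curve should cross 0.5 near zero if thresholds are well estimated.
#'
#' @param object An `rf_psych_curve` from [psychophysics_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_psych_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$stay_rate,
                     color = .data$condition)) +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    geom_hline(yintercept = 0.5, linetype = "dotted", color = "grey60") +
    geom_line() +
    geom_point(aes(size = .data$n_subjects), alpha = 0.6) +
    scale_size_continuous(range = c(0.5, 2.5), guide = "none") +
    labs(x = "presented delay - threshold (s)", y = "P(stay)",
         color = NULL) +
    theme_minimal()
}

#' Plot one subject's stay/skip pattern and threshold
#'
#' Choices against the presented (mid) delay per gallery, with the
#' fitted gallery threshold marked, mirroring the usual single-subject
#' threshold display (open points risky, filled non-risky).
#'
#' @param trials Trial tibble.
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param subject Subject id to display.
#' @return A ggplot object.
#' @export
plot_subject_thresholds <- function(trials, threshold_set, subject) {
  df <- trials |> filter(.data$subject_id == subject)
  thr <- subject_thresholds(threshold_set) |>
    filter(.data$subject_id == subject)
  ggplot(df, aes(x = .data$mid, y = as.numeric(.data$choice == "stay"))) +
    geom_jitter(aes(shape = .data$is_risky), width = 0, height = 0.04,
                alpha = 0.7) +
    scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 16),
                       labels = c(`TRUE` = "risky", `FALSE` = "non-risky"),
                       name = NULL) +
    geom_vline(data = thr, aes(xintercept = .data$threshold)) +
    facet_wrap(~gallery) +
    labs(x = "presented delay (s)", y = "choice (1 = stay)") +
    theme_minimal()
}

#' Forest plot of a fitted coefficient table
#'
#' Estimates with 95% intervals for the fixed effects of one fitted
#' model (intercept omitted).
#'
#' @param object An `rf_mixed` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_mixed <- function(object, ...) {
  tab <- object$table |> filter(.data$term != "(Intercept)")
  ggplot(tab, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    geom_pointrange(aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    labs(x = "estimate (95% CI)", y = NULL) +
    theme_minimal()
}

#' Plot a hyperbolic discounting fit
#'
#' Indifference points with the fitted hyperbolic present-value curve.
#'
#' @param object An `rf_discount_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_discount_fit <- function(object, ...) {
  xvar <- if (object$mode == "delay") object$conditions
          else (1 - object$conditions) / object$conditions
  xx <- seq(min(xvar), max(xvar), length.out = 200)
  curve_df <- tibble(x = xx, v = object$amount / (1 + object$k * xx))
  ggplot(tibble(x = xvar, v = object$indifference), aes(.data$x, .data$v)) +
    geom_line(data = curve_df, color = "steelblue") +
    geom_point() +
    labs(x = if (object$mode == "delay") "delay (days)" else "odds against",
         y = "indifference value ($)",
         title = sprintf("%s discounting: ln k = %.2f, R² = %.2f",
                         object$mode, object$log_k, object$r_squared)) +
    theme_minimal()
}
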