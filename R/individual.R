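#' Subject-specific choice and rating coefficients
#'
#' Fits, per subject and without random effects, the subject-specific
#' analogues of the primary group models: a logistic regression
#' `stay ~ value_prev + class_prev` on risky stays followed by risky
#' offers, and a linear regression `rating_centered ~ value + class` on
#' risky stays. The extracted quantity is each model's unstandardized
#' bad-vs-good contrast: for choice, higher values mean a greater
#' tendency to stay after a risky loss; for rating, higher values mean
#' better ratings after the bad than the good outcome. Subjects without
#' both outcome classes in the relevant filter, or with separated /
#' rank-deficient fits, are flagged and excluded from correlations.
#'
#' @param trials Trial tibble.
#' @param threshold_set Result of [assign_trial_thresholds()].
#' @param rating_lag Passed to [prepare_sequential_dataset()] for the
#'   rating filter (default: current-trial framing).
#' @return A tibble per subject: `choice_outcome_coeff`,
#'   `rating_outcome_coeff`, `n_choice`, `n_rating`, `choice_flag`,
#'   `rating_flag` (NA flags mean a clean fit).
#' @export
fit_subject_models <- function(trials, threshold_set, rating_lag = FALSE) {
  d_choice <- prepare_sequential_dataset(trials, threshold_set, "choice")
  d_rating <- prepare_sequential_dataset(trials, threshold_set, "rating",
                                         rating_lag = rating_lag)
  subjects <- sort(unique(trials$subject_id))
  purrr::map(subjects, function(s) {
    ch <- d_choice |> filter(.data$subject_id == s)
    ra <- d_rating |> filter(.data$subject_id == s)
    cc <- subject_contrast(ch, "stay", "value_prev", "class_prev", binomial())
    rc <- subject_contrast(ra, "rating_centered", "value_now", "class_now",
                           gaussian())
    tibble(subject_id = s,
           choice_outcome_coeff = cc$coef, choice_flag = cc$flag,
           n_choice = nrow(ch),
           rating_outcome_coeff = rc$coef, rating_flag = rc$flag,
           n_rating = nrow(ra))
  }) |> list_rbind()
}

# per-subject fixed-effects fit; extracts the bad-vs-good contrast of the
# outcome-type factor (reference level "good")
subject_contrast <- function(d, response, value_col, class_col, family) {
  cls <- as.character(d[[class_col]])
  if (nrow(d) < 6 || sum(cls == "bad") < 1 || sum(cls == "good") < 1) {
    return(list(coef = NA_real_, flag = "insufficient_trials"))
  }
  d$outcome <- factor(cls, levels = intersect(c("good", "bad", "mid"), cls))
  f <- as.formula(paste(response, "~", value_col, "+ outcome"))
  fit <- tryCatch(
    suppressWarnings(glm(f, data = d, family = family)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(coef = NA_real_, flag = "fit_error"))
  est <- coef(fit)[["outcomebad"]]
  if (is.na(est)) return(list(coef = NA_real_, flag = "rank_deficient"))
  se <- sqrt(diag(vcov(fit)))[["outcomebad"]]
  if (family$family == "binomial" && (abs(est) > 10 || se > 10)) {
    return(list(coef = NA_real_, flag = "separation"))
  }
  list(coef = est, flag = NA_character_)
}

#' Robust partial correlation (percentage-bend)
#'
#' Residualizes `x` and `y` on the covariates by ordinary least squares,
#' then computes Wilcox's percentage-bend correlation (bend constant 0.2
#' by default) between the residuals, which downweights marginal
#' outliers. The p-value uses the t approximation
#' `T = r * sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom; one-tailed
#' tests halve the p-value when the observed sign matches
#' `direction`, and report `1 - p/2` otherwise.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame of covariates (numeric or
#'   factor/character; categorical columns are dummy-coded).
#' @param tails `"two"` or `"one"`.
#' @param direction Expected sign (`1` or `-1`) for one-tailed tests.
#' @param beta Bend constant in (0, 0.5).
#' @return A list with `r`, `p`, `n`, and `flag` (non-NA when undefined,
#'   e.g. constant residuals or too few complete cases).
#' @export
robust_partial_correlation <- function(x, y, covariates = NULL,
                                       tails = c("two", "one"),
                                       direction = 1, beta = 0.2) {
  tails <- match.arg(tails)
  keep <- complete.cases(x, y)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 8) return(list(r = NA_real_, p = NA_real_, n = n, flag = "too_few_cases"))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    mm <- model.matrix(~ ., data = cv)
    x <- lm.fit(mm, x)$residuals
    y <- lm.fit(mm, y)$residuals
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "constant_residuals"))
  }
  r <- pb_cor(x, y, beta)
  if (is.na(r)) return(list(r = NA_real_, p = NA_real_, n = n, flag = "undefined"))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p2 <- 2 * pt(-abs(tt), df = n - 2)
  p <- if (tails == "two") p2 else if (sign(r) == sign(direction)) p2 / 2 else 1 - p2 / 2
  list(r = r, p = p, n = n, flag = NA_character_)
}

# percentage-bend measure of location (Wilcox)
pb_location <- function(x, beta) {
  n <- length(x)
  med <- median(x)
  w <- sort(abs(x - med))
  m <- floor((1 - beta) * n + 0.5)
  omega <- w[m]
  if (omega <= 0) return(list(loc = med, omega = 0))
  z <- (x - med) / omega
  i1 <- sum(z < -1)
  i2 <- sum(z > 1)
  sx <- sum(x[z >= -1 & z <= 1])
  list(loc = (omega * (i2 - i1) + sx) / (n - i1 - i2), omega = omega)
}

pb_cor <- function(x, y, beta = 0.2) {
  lx <- pb_location(x, beta)
  ly <- pb_location(y, beta)
  if (lx$omega == 0 || ly$omega == 0) return(NA_real_)
  a <- pmin(pmax((x - lx$loc) / lx$omega, -1), 1)
  b <- pmin(pmax((y - ly$loc) / ly$omega, -1), 1)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Trait-level correlation report
#'
#' Relates the subject-specific choice and rating outcome coefficients to
#' externalizing trait scores with robust partial correlations
#' (controlling age, sex and ethnicity throughout):
#'
#' * primary (two-tailed): choice and rating coefficients vs the
#'   log-transformed total score;
#' * follow-ups (one-tailed, expecting more risk seeking after losses at
#'   higher trait levels): the choice coefficient vs the three subfactors
#'   and the three problem subscales, the latter restricted to subjects
#'   retained by the at-least-one-item rule; Benjamini-Hochberg
#'   adjustment over these six;
#' * unique contribution: choice coefficient vs substance abuse,
#'   additionally partialling the other two subfactors;
#' * discounting-adjusted (if log k values are supplied): choice
#'   coefficient vs the total score, additionally controlling both
#'   discounting rates.
#'
#' Correlations whose retained-subject count falls below 8 are skipped
#' with a recorded reason.
#'
#' @param coeffs Output of [fit_subject_models()].
#' @param profiles Output of [score_esi()], joined per subject, plus
#'   demographic covariate columns `age`, `sex`, `ethnicity` (either in
#'   `profiles` or supplied via `demographics`).
#' @param demographics Optional tibble (`subject_id`, `age`, `sex`,
#'   `ethnicity`).
#' @param discounting Optional tibble (`subject_id`, `logk_delay`,
#'   `logk_prob`) of fitted log discounting rates.
#' @return A tibble: `family`, `pair`, `tails`, `n`, `r`, `p`, `p_adj`
#'   (adjusted within the six follow-ups), `note`.
#' @export
run_trait_correlations <- function(coeffs, profiles, demographics = NULL,
                                   discounting = NULL) {
  df <- coeffs |> left_join(profiles, by = "subject_id")
  if (!is.null(demographics)) df <- df |> left_join(demographics, by = "subject_id")
  assert_that(all(c("age", "sex", "ethnicity") %in% names(df)),
              "Demographic covariates (age, sex, ethnicity) are required.")
  if (!is.null(discounting)) df <- df |> left_join(discounting, by = "subject_id")
  cov_base <- df[, c("age", "sex", "ethnicity")]

  row_from <- function(res, family, pair, tails, note = NA_character_) {
    tibble(family = family, pair = pair, tails = tails,
           n = res$n, r = res$r, p = res$p, p_adj = NA_real_,
           note = if (!is.na(res$flag)) res$flag else note)
  }
  rows <- list()
  rows$prim_choice <- row_from(
    robust_partial_correlation(df$choice_outcome_coeff, df$esi_total_log,
                               cov_base, "two"),
    "primary", "choice_coeff~esi_total_log", "two")
  rows$prim_rating <- row_from(
    robust_partial_correlation(df$rating_outcome_coeff, df$esi_total_log,
                               cov_base, "two"),
    "primary", "rating_coeff~esi_total_log", "two")

  followups <- list(
    disinhibition = NULL, substance = NULL, aggression = NULL,
    alcohol = "alcohol_retained", marijuana = "marijuana_retained",
    drug = "drug_retained"
  )
  for (nm in names(followups)) {
    keepcol <- followups[[nm]]
    sub <- if (is.null(keepcol)) df else df[isTRUE_vec(df[[keepcol]]), ]
    pair <- paste0("choice_coeff~", nm)
    if (nrow(sub) < 8) {
      rows[[pair]] <- tibble(family = "followup", pair = pair, tails = "one",
                             n = nrow(sub), r = NA_real_, p = NA_real_,
                             p_adj = NA_real_, note = "fewer_than_8_retained")
      next
    }
    res <- robust_partial_correlation(sub$choice_outcome_coeff, sub[[nm]],
                                      sub[, c("age", "sex", "ethnicity")],
                                      "one", direction = 1)
    rows[[pair]] <- row_from(res, "followup", pair, "one")
  }

  rows$unique <- row_from(
    robust_partial_correlation(
      df$choice_outcome_coeff, df$substance,
      cbind(cov_base, df[, c("disinhibition", "aggression")]), "one",
      direction = 1),
    "unique_contribution", "choice_coeff~substance|other_subfactors", "one")

  if (!is.null(discounting)) {
    rows$disc <- row_from(
      robust_partial_correlation(
        df$choice_outcome_coeff, df$esi_total_log,
        cbind(cov_base, df[, c("logk_delay", "logk_prob")]), "two"),
      "discounting_adjusted", "choice_coeff~esi_total_log|logk", "two")
  }

  out <- bind_rows(rows)
  fu <- out$family == "followup" & !is.na(out$p)
  if (any(fu)) out$p_adj[fu] <- bh_adjust(out$p[fu])
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
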