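#' Item design for the synthetic externalizing inventory
#'
#' Layout of a 100-item externalizing spectrum inventory: every item loads
#' on exactly one of the three subfactors (general disinhibition,
#' substance abuse, callous aggression), and the substance-abuse subfactor
#' contains three problem subscales (alcohol, marijuana, drug). Problem
#' items carry a high difficulty so that most synthetic subjects endorse
#' none of them, reproducing the zero inflation that the retention rule
#' downstream is designed for. The wording of the real instrument is not
#' emulated; the design is purely structural and synthetic.
#'
#' @param problem_difficulty Difficulty of problem-subscale items on the
#'   logit scale (larger = rarer endorsement).
#' @return A tibble with columns `item`, `subfactor`, `subscale` (NA for
#'   items outside the problem subscales) and `difficulty`.
#' @export
esi_item_design <- function(problem_difficulty = 3.5) {
  design <- tibble(
    item = 1:100,
    subfactor = c(rep("disinhibition", 40), rep("substance", 35),
                  rep("aggression", 25)),
    subscale = NA_character_,
    difficulty = NA_real_
  )
  design$subscale[41:50] <- "alcohol"
  design$subscale[51:58] <- "marijuana"
  design$subscale[59:66] <- "drug"
  regular <- is.na(design$subscale)
  design$difficulty[regular] <- rep_len(seq(-1, 1.5, length.out = 10), sum(regular))
  design$difficulty[!regular] <- problem_difficulty
  design
}

#' Generate synthetic externalizing inventory responses
#'
#' Two-parameter binary item-response model: the probability that subject
#' i endorses item j is `logistic(a_E * E_i + b_F * F_{f(j),i} - c_j)`,
#' where `E` is the latent externalizing score, `F` the subject's
#' subfactor-specific factor, and `c_j` the item difficulty from the
#' design.
#'
#' @param agents Agents tibble from [sample_population()] (columns `E`,
#'   `F_disinhibition`, `F_substance`, `F_aggression`).
#' @param design Item design from [esi_item_design()].
#' @param a_E Loading of the shared externalizing factor.
#' @param b_F Loading of the subfactor-specific factor.
#' @param seed Optional seed.
#' @return A long tibble (`subject_id`, `item`, `subfactor`, `subscale`,
#'   `response`) with binary responses.
#' @export
generate_esi_responses <- function(agents, design = esi_item_design(),
                                   a_E = 1, b_F = 0.8, seed = NULL) {
  if (!all(c("item", "subfactor", "difficulty") %in% names(design))) {
    abort("`design` must assign every item a subfactor and difficulty.")
  }
  if (anyNA(design$subfactor)) abort("Every item needs a subfactor assignment.")
  if (!is.null(seed)) set.seed(seed)
  fcol <- c(disinhibition = "F_disinhibition", substance = "F_substance",
            aggression = "F_aggression")
  grid <- tidyr::crossing(subject_id = agents$subject_id, item = design$item) |>
    left_join(design, by = "item") |>
    left_join(agents |> select("subject_id", "E", all_of(unname(fcol))),
              by = "subject_id")
  Fval <- as.matrix(grid[, unname(fcol)])[cbind(seq_len(nrow(grid)),
                                                match(grid$subfactor, names(fcol)))]
  p <- plogis(a_E * grid$E + b_F * Fval - grid$difficulty)
  grid |>
    mutate(response = as.integer(runif(dplyr::n()) < p)) |>
    select("subject_id", "item", "subfactor", "subscale", "response")
}

#' Score the externalizing inventory
#'
#' Total score is the sum across all 100 items, log-transformed as
#' `ln(total + 1)` to improve normality while remaining defined at zero.
#' Subfactor scores are sums over each subfactor's items; problem
#' subscales get a `retained` flag that is `TRUE` exactly when the subject
#' endorsed at least one item on that subscale (the zero-inflation
#' retention rule).
#'
#' @param responses Long response tibble from [generate_esi_responses()]
#'   (or real data in the same layout).
#' @param n_items Expected number of items per subject.
#' @return A tibble with one row per subject: `esi_total`,
#'   `esi_total_log`, `disinhibition`, `substance`, `aggression`,
#'   `alcohol`, `marijuana`, `drug`, and `alcohol_retained`,
#'   `marijuana_retained`, `drug_retained`.
#' @export
score_esi <- function(responses, n_items = 100) {
  need <- c("subject_id", "item", "subfactor", "subscale", "response")
  assert_that(all(need %in% names(responses)),
              "`responses` must have columns subject_id, item, subfactor, subscale, response.")
  counts <- responses |> count(.data$subject_id) |> pull(n)
  if (any(counts != n_items) || anyNA(responses$response)) {
    abort("Incomplete response sets: every subject must answer every item.")
  }
  totals <- responses |>
    group_by(.data$subject_id) |>
    summarise(esi_total = sum(.data$response), .groups = "drop") |>
    mutate(esi_total_log = log(.data$esi_total + 1))
  subf <- responses |>
    group_by(.data$subject_id, .data$subfactor) |>
    summarise(score = sum(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "subfactor", values_from = "score")
  subs <- responses |>
    filter(!is.na(.data$subscale)) |>
    group_by(.data$subject_id, .data$subscale) |>
    summarise(score = sum(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "subscale", values_from = "score")
  totals |>
    left_join(subf, by = "subject_id") |>
    left_join(subs, by = "subject_id") |>
    mutate(
      alcohol_retained = .data$alcohol >= 1,
      marijuana_retained = .data$marijuana >= 1,
      drug_retained = .data$drug >= 1
    )
}
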