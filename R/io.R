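#' Write a session log to CSV
#'
#' One row per offer encounter with the standard header (`subject_id`,
#' `trial_index`, `gallery`, `low`, `mid`, `high`, `is_risky`, `choice`,
#' `realized_delay`, `outcome_class`, `rating`, `decision_rt`,
#' `clock_start`, `clock_end`). Absent values (e.g. ratings on skips) are
#' written as empty fields, never 0.
#'
#' @param trials Trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(trials, path) {
  assert_that(all(session_log_columns() %in% names(trials)),
              "`trials` is missing required session-log columns.")
  readr::write_csv(trials[, session_log_columns()], path, na = "")
  invisible(path)
}

session_log_columns <- function() {
  c("subject_id", "trial_index", "gallery", "low", "mid", "high", "is_risky",
    "choice", "realized_delay", "outcome_class", "rating", "decision_rt",
    "clock_start", "clock_end")
}

#' Read and validate a session log
#'
#' Reads a CSV written by [write_session_log()] and checks every
#' trial-record invariant: ratings and realized delays present exactly on
#' stays, outcome class `none` exactly on skips, realized delays drawn
#' from the offered set, ordered delays inside the task range, strictly
#' increasing trial indices per subject. In strict mode any violation is
#' an error listing the offending rows; in lenient mode offending rows
#' are dropped with a warning.
#'
#' @param path CSV path.
#' @param strict Error on invariant violations (default) or drop them.
#' @return A validated trial tibble.
#' @export
read_session_log <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("No such session log: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, session_log_columns())) {
    abort("Malformed session log header.")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = "c", trial_index = "i", gallery = "c",
      low = "i", mid = "i", high = "i", is_risky = "l",
      choice = "c", realized_delay = "i", outcome_class = "c",
      rating = "i", decision_rt = "d", clock_start = "d", clock_end = "d"
    ),
    na = ""
  )
  if (nrow(df) == 0) {
    warn("Session log is empty (valid header, no rows).")
    return(df)
  }
  bad <- validate_session_rows(df)
  if (length(bad$rows)) {
    msg <- paste0("Invalid session rows: ",
                  paste(utils::head(bad$messages, 10), collapse = "; "))
    if (strict) abort(msg)
    warn(paste0(msg, " -- dropped in lenient mode."))
    df <- df[-bad$rows, ]
  }
  df
}

validate_session_rows <- function(df) {
  stay <- df$choice == .STAY
  checks <- list(
    "rating present iff stay" = is.na(df$rating) == stay,
    "realized delay present iff stay" = is.na(df$realized_delay) == stay,
    "outcome 'none' iff skip" = (df$outcome_class == "none") == stay,
    "delays ordered" = !(df$low <= df$mid & df$mid <= df$high),
    "risky iff low < high" = df$is_risky != (df$low < df$high),
    "realized delay in offer set" = stay & !is.na(df$realized_delay) &
      !(df$realized_delay == df$low | df$realized_delay == df$mid |
          df$realized_delay == df$high)
  )
  rows <- integer(0)
  messages <- character(0)
  for (nm in names(checks)) {
    viol <- which(isTRUE_vec(checks[[nm]]))
    if (length(viol)) {
      rows <- union(rows, viol)
      messages <- c(messages,
                    paste0(nm, " violated at row(s) ",
                           paste(utils::head(viol, 5), collapse = ",")))
    }
  }
  dup <- df |>
    group_by(.data$subject_id) |>
    summarise(ok = all(diff(.data$trial_index) > 0), .groups = "drop")
  if (!all(dup$ok)) {
    messages <- c(messages, "trial_index not strictly increasing within subject")
    rows <- union(rows, which(df$subject_id %in% dup$subject_id[!dup$ok]))
  }
  list(rows = sort(rows), messages = messages)
}

#' Write / read a flat key-value configuration file
#'
#' Plain-text configuration with one `section.key = value` pair per line,
#' sections mirroring the configuration constructors (`task.*` for
#' [session_config()], `population.*` for [population_config()]).
#' Numeric vectors are comma-separated.
#'
#' @param config A list with elements `task` and/or `population`.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a list with
#'   `task` and `population` configuration objects (defaults where a
#'   section is absent).
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    obj <- config[[section]]
    for (key in names(obj)) {
      val <- obj[[key]]
      if (!is.atomic(val)) next
      lines <- c(lines, paste0(section, ".", key, " = ",
                               paste(val, collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (item in kv) {
    if (length(item) != 2) abort(paste0("Malformed config line: ", paste(item, collapse = "=")))
    keyparts <- strsplit(item[1], ".", fixed = TRUE)[[1]]
    assert_that(length(keyparts) == 2, "Config keys must look like section.key.")
    vals <- strsplit(item[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[keyparts[1]]][[keyparts[2]]] <- if (anyNA(num)) vals else num
  }
  task <- do.call(session_config, out$task %||% list())
  population <- do.call(population_config, out$population %||% list())
  list(task = task, population = population)
}

#' Command-line style pipeline driver
#'
#' Dispatches the pipeline's four stages from an argument vector, so the
#' same entry point works from `Rscript` wrappers and from R:
#'
#' * `simulate --config C --seed S --out DIR`: writes `session_log.csv`,
#'   `ground_truth.csv`, `rankings.csv` and `run_info.txt`;
#' * `analyze --in DIR --out DIR`: thresholds, model coefficient tables,
#'   validity and trait-correlation reports as tidy CSVs;
#' * `recover --in DIR --truth FILE --out DIR`: recovery metrics
#'   (threshold MAE, framing-coefficient correlation) against ground
#'   truth;
#' * `report --in DIR`: prints a plain-text summary of the fitted model
#'   tables.
#'
#' @param argv Character vector of arguments (defaults to the process
#'   command line).
#' @return Exit status, invisibly: 0 on success, 2 on usage errors.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: riskforage <simulate|analyze|recover|report> [options]",
    "  simulate --config FILE --seed INT --out DIR [--n-subjects N]",
    "  analyze  --in DIR --out DIR",
    "  recover  --in DIR --truth FILE --out DIR",
    "  report   --in DIR", sep = "\n")
  if (length(argv) == 0) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  if (inherits(opts, "cli_error")) { message(opts); message(usage); return(invisible(2L)) }
  status <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      analyze = cli_analyze(opts),
      recover = cli_recover(opts),
      report = cli_report(opts),
      { message("Unknown subcommand: ", cmd); message(usage); return(invisible(2L)) }
    )
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      return(structure(paste0("Unexpected argument: ", a), class = "cli_error"))
    }
    key <- gsub("^--", "", a)
    if (i + 1 > length(args)) {
      return(structure(paste0("Missing value for --", key), class = "cli_error"))
    }
    opts[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_require <- function(opts, keys) {
  missing <- setdiff(keys, names(opts))
  if (length(missing)) {
    abort(paste0("Missing required option(s): --",
                 paste(gsub("_", "-", missing), collapse = ", --")))
  }
}

cli_simulate <- function(opts) {
  cli_require(opts, c("seed", "out"))
  seed <- as.integer(opts$seed)
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    list(task = session_config(), population = population_config(seed = seed))
  if (!is.null(opts$n_subjects)) cfg$population$n_subjects <- as.integer(opts$n_subjects)
  cfg$population$seed <- seed
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(cfg$population, cfg$task, seed = seed)
  write_session_log(study$trials, file.path(opts$out, "session_log.csv"))
  readr::write_csv(study$agents, file.path(opts$out, "ground_truth.csv"))
  readr::write_csv(study$rankings, file.path(opts$out, "rankings.csv"))
  writeLines(c(paste0("seed = ", seed),
               paste0("n_subjects = ", nrow(study$agents)),
               paste0("config_hash = ",
                      sum(utf8ToInt(paste(unlist(cfg$task), collapse = ""))))),
             file.path(opts$out, "run_info.txt"))
  message("simulate: wrote ", nrow(study$trials), " trials for ",
          nrow(study$agents), " subjects to ", opts$out)
}

cli_analyze <- function(opts) {
  cli_require(opts, c("in", "out"))
  log_path <- file.path(opts[["in"]], "session_log.csv")
  if (!file.exists(log_path)) {
    abort("analyze requires session_log.csv from the simulate stage.")
  }
  trials <- read_session_log(log_path)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  thr <- assign_trial_thresholds(trials)
  readr::write_csv(as_tibble(thr), file.path(opts$out, "thresholds.csv"))
  readr::write_csv(subject_thresholds(thr),
                   file.path(opts$out, "gallery_thresholds.csv"))
  readr::write_csv(psychophysics_curve(thr),
                   file.path(opts$out, "psychophysics_curve.csv"))
  rank_path <- file.path(opts[["in"]], "rankings.csv")
  if (file.exists(rank_path)) {
    rankings <- readr::read_csv(rank_path, show_col_types = FALSE)
    readr::write_csv(validity_correlations(trials, thr, rankings),
                     file.path(opts$out, "validity.csv"))
  }
  suite <- run_model_suite(trials, thr)
  readr::write_csv(tidy(suite), file.path(opts$out, "model_tables.csv"))
  readr::write_csv(suite$simple_slopes, file.path(opts$out, "simple_slopes.csv"))
  readr::write_csv(fit_subject_models(trials, thr),
                   file.path(opts$out, "subject_coefficients.csv"))
  message("analyze: wrote threshold, model and coefficient tables to ", opts$out)
}

cli_recover <- function(opts) {
  cli_require(opts, c("in", "truth", "out"))
  trials <- read_session_log(file.path(opts[["in"]], "session_log.csv"))
  truth <- readr::read_csv(opts$truth, show_col_types = FALSE)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  thr <- assign_trial_thresholds(trials)
  est <- subject_thresholds(thr)
  galleries <- if (!is.null(opts$galleries)) strsplit(opts$galleries, ",")[[1]]
               else session_config()$galleries
  joined <- est |> left_join(true_thresholds_long(truth, galleries),
                             by = c("subject_id", "gallery"))
  coeffs <- fit_subject_models(trials, thr)
  with_truth <- coeffs |> left_join(truth, by = "subject_id")
  metrics <- tibble(
    metric = c("threshold_mae_seconds", "threshold_median_ae_seconds",
               "choice_coeff_gamma_correlation"),
    value = c(mean(abs(joined$threshold - joined$tau), na.rm = TRUE),
              median(abs(joined$threshold - joined$tau), na.rm = TRUE),
              safe_cor(with_truth$choice_outcome_coeff, with_truth$gamma))
  )
  readr::write_csv(metrics, file.path(opts$out, "recovery_metrics.csv"))
  message("recover: wrote recovery metrics to ", opts$out)
}

cli_report <- function(opts) {
  cli_require(opts, "in")
  path <- file.path(opts[["in"]], "model_tables.csv")
  if (!file.exists(path)) abort("report requires model_tables.csv from the analyze stage.")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  for (m in unique(tab$model)) {
    cat("==", m, "==\n")
    sub <- tab[tab$model == m, c("term", "estimate", "ci_lo", "ci_hi", "p", "p_adj")]
    print(as.data.frame(sub), row.names = FALSE, digits = 3)
    cat("\n")
  }
}
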