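BLOCK_LEVELS <- c("baseline_action", "operant_action", "baseline_tone", "operant_tone")

trial_log_cols <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    block = readr::col_character(),
    trial_index = readr::col_integer(),
    actual_event_ms = readr::col_double(),
    reported_units = readr::col_double(),
    period_ms = readr::col_double()
  )
}

#' Read or write a trial-level clock-judgment log
#'
#' The trial log is a plain CSV with a header and one row per trial:
#' `participant_id`, `condition`, `block` (one of `baseline_action`,
#' `operant_action`, `baseline_tone`, `operant_tone`), `trial_index`,
#' `actual_event_ms`, `reported_units`, `period_ms`.
#'
#' @param path File path.
#' @param trials A trial tibble as produced by [simulate_trials()] or read
#'   from disk.
#' @return `read_trial_log()` returns a validated tibble;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
read_trial_log <- function(path) {
  trials <- readr::read_csv(path, col_types = trial_log_cols(), progress = FALSE)
  validate_trials(trials)
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Validate a trial table
#'
#' Checks the trial-log schema: required columns, block labels, non-negative
#' event times, positive periods, reported positions inside `[0, 60)` units
#' (the unit count is taken from the matching clock config at error-computation
#' time; here only finiteness and sign are enforced), and uniqueness of
#' `trial_index` within participant x condition x block. Problems are reported
#' with the offending row numbers.
#'
#' @param trials A data frame of trials.
#' @return The validated trials as a tibble (invisibly usable in a pipe).
#' @export
validate_trials <- function(trials) {
  required <- c("participant_id", "condition", "block", "trial_index",
                "actual_event_ms", "reported_units", "period_ms")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) {
    stop("trial log contains no trials.", call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  bad_block <- which(!trials$block %in% BLOCK_LEVELS)
  if (length(bad_block)) {
    stop(sprintf("unknown block label at row(s) %s (expected one of %s)",
                 paste(utils::head(bad_block, 5L), collapse = ", "),
                 paste(BLOCK_LEVELS, collapse = ", ")), call. = FALSE)
  }
  bad_time <- which(!is.finite(trials$actual_event_ms) | trials$actual_event_ms < 0)
  if (length(bad_time)) {
    stop("non-finite or negative actual_event_ms at row(s) ",
         paste(utils::head(bad_time, 5L), collapse = ", "), call. = FALSE)
  }
  bad_period <- which(!is.finite(trials$period_ms) | trials$period_ms <= 0)
  if (length(bad_period)) {
    stop("non-positive period_ms at row(s) ",
         paste(utils::head(bad_period, 5L), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(trials[c("participant_id", "condition", "block", "trial_index")])
  if (any(dup)) {
    stop("duplicated trial_index within participant/condition/block at row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  trials
}

#' Annotate trials with signed judgment errors
#'
#' Computes, for every trial, the signed circular judgment error in ms:
#' the reported clock position is converted to a phase time with the
#' condition's clock configuration and compared with the true event time via
#' [wrap_error()]. Negative errors are anticipatory reports.
#'
#' @param trials A validated trial table (see [read_trial_log()]).
#' @param configs Named list of [clock_config()] objects, one per condition
#'   appearing in `trials`. If `NULL`, a config is built from each trial's
#'   own `period_ms` column with the default 60 units.
#' @return The trial tibble with an added `error_ms` column.
#' @examples
#' cfg <- list(std = clock_config(2560))
#' trials <- tibble::tibble(
#'   participant_id = "p1", condition = "std", block = "baseline_action",
#'   trial_index = 1L, actual_event_ms = 2000, reported_units = 50,
#'   period_ms = 2560
#' )
#' compute_judgment_errors(trials, cfg)$error_ms  # +133.33 ms
#' @export
compute_judgment_errors <- function(trials, configs = NULL) {
  trials <- validate_trials(trials)
  conds <- unique(trials$condition)
  if (is.null(configs)) {
    configs <- lapply(conds, function(cn) {
      p <- unique(trials$period_ms[trials$condition == cn])
      if (length(p) != 1L) {
        stop("condition ", cn, " has multiple period_ms values; supply `configs`.",
             call. = FALSE)
      }
      clock_config(p)
    })
    names(configs) <- conds
  }
  missing_cfg <- setdiff(conds, names(configs))
  if (length(missing_cfg)) {
    stop("no clock config supplied for condition(s): ",
         paste(missing_cfg, collapse = ", "), call. = FALSE)
  }
  err <- numeric(nrow(trials))
  for (cn in conds) {
    idx <- which(trials$condition == cn)
    cfg <- configs[[cn]]
    phase <- position_to_ms(trials$reported_units[idx], cfg)
    err[idx] <- wrap_error(phase, trials$actual_event_ms[idx], cfg)
  }
  trials$error_ms <- err
  trials
}
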