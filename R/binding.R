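#' Trim outlying judgment errors within one cell
#'
#' Single-pass mean +/- k SD trimming for one cell (one participant x
#' condition x block). The mean and sample SD (denominator n - 1) are computed
#' once over all trials in the cell; trials with `|error - mean| <= k * SD`
#' are kept (the boundary is kept). The rule is deliberately not iterated.
#'
#' @param errors Numeric vector of judgment errors (ms) for one cell.
#' @param k SD multiplier (default 2.5).
#' @return A list with `kept` (the retained errors), `keep` (logical mask),
#'   `exclusion_fraction`, and `flag` (`"too_few_trials"` when the cell has
#'   fewer than 2 trials and the SD is undefined, in which case everything is
#'   kept).
#' @examples
#' trim_trials(c(rep(0, 9), 100))$exclusion_fraction  # 0.1
#' @export
trim_trials <- function(errors, k = 2.5) {
  stopifnot(is.numeric(errors), k > 0)
  n <- length(errors)
  if (n < 2L) {
    return(list(kept = errors, keep = rep(TRUE, n),
                exclusion_fraction = 0, flag = "too_few_trials"))
  }
  m <- mean(errors)
  s <- stats::sd(errors)
  keep <- abs(errors - m) <= k * s
  list(kept = errors[keep], keep = keep,
       exclusion_fraction = sum(!keep) / n, flag = NA_character_)
}

#' Trim a full trial table cell-by-cell
#'
#' Applies [trim_trials()] within every participant x condition x block cell
#' and returns the table annotated with a `keep` flag, plus per-condition
#' exclusion percentages pooled across the four block types (the resolution at
#' which clock studies conventionally report trial loss).
#'
#' @param trials Trial tibble carrying `error_ms` (see
#'   [compute_judgment_errors()]).
#' @param k SD multiplier of the trimming rule (default 2.5).
#' @return A list: `trials` (input plus `keep`), `by_condition` (tibble of
#'   pooled exclusion percentages), `cells` (per-cell means, SDs and
#'   exclusion fractions, so alternative pooling choices can be audited),
#'   `policy`.
#' @export
trim_judgment_errors <- function(trials, k = 2.5) {
  if (!"error_ms" %in% names(trials)) {
    stop("`trials` must carry `error_ms`; run compute_judgment_errors() first.",
         call. = FALSE)
  }
  trials <- dplyr::group_by(trials, .data$participant_id, .data$condition, .data$block)
  trials <- dplyr::mutate(
    trials,
    .cell_n = dplyr::n(),
    .cell_mean = mean(.data$error_ms),
    .cell_sd = stats::sd(.data$error_ms),
    keep = .data$.cell_n < 2L |
      abs(.data$error_ms - .data$.cell_mean) <= k * .data$.cell_sd
  )
  cells <- dplyr::summarise(
    trials,
    n_trials = dplyr::n()[1L],
    cell_mean = .data$.cell_mean[1L],
    cell_sd = .data$.cell_sd[1L],
    n_kept = sum(.data$keep),
    exclusion_fraction = 1 - sum(.data$keep) / dplyr::n(),
    flag = ifelse(dplyr::n() < 2L, "too_few_trials", NA_character_),
    .groups = "drop"
  )
  if (any(!is.na(cells$flag))) {
    warning(sum(!is.na(cells$flag)),
            " cell(s) had fewer than 2 trials; kept untrimmed.", call. = FALSE)
  }
  trials <- dplyr::ungroup(trials)
  trials <- dplyr::select(trials, -dplyr::starts_with(".cell_"))
  by_condition <- dplyr::summarise(
    dplyr::group_by(trials, .data$condition),
    n_trials = dplyr::n(),
    n_excluded = sum(!.data$keep),
    exclusion_pct = 100 * sum(!.data$keep) / dplyr::n(),
    .groups = "drop"
  )
  list(trials = trials, by_condition = by_condition, cells = cells,
       policy = list(k = k, scope = "participant x condition x block"))
}

#' Participant-level binding scores
#'
#' Turns trimmed trial-level errors into the two binding measures: action
#' binding is the mean operant-action minus mean baseline-action judgment
#' error, tone binding the mean operant-tone minus mean baseline-tone error,
#' computed per participant and condition. Positive action binding means the
#' action is reported later when it causes a tone; negative tone binding means
#' the tone is pulled back toward the action.
#'
#' @param trials Trial tibble with `error_ms` and optionally a logical `keep`
#'   column (rows with `keep == FALSE` are ignored).
#' @return A `binding_table` tibble with one row per participant x condition:
#'   the four per-block mean raw errors and trial counts, `action_binding_ms`
#'   and `tone_binding_ms`. Participants missing any of the four blocks for a
#'   condition are dropped with a message; the dropped pairs are recorded in
#'   the `dropped` attribute.
#' @export
binding_scores <- function(trials) {
  if (!"error_ms" %in% names(trials)) {
    stop("`trials` must carry `error_ms`; run compute_judgment_errors() first.",
         call. = FALSE)
  }
  if ("keep" %in% names(trials)) trials <- dplyr::filter(trials, .data$keep)
  cell <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$condition, .data$block),
    mean_error = mean(.data$error_ms), n_kept = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    cell,
    id_cols = c("participant_id", "condition"),
    names_from = "block",
    values_from = c("mean_error", "n_kept")
  )
  needed <- paste0("mean_error_", BLOCK_LEVELS)
  for (nm in c(needed, paste0("n_kept_", BLOCK_LEVELS))) {
    if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  }
  complete <- stats::complete.cases(wide[needed])
  dropped <- wide[!complete, c("participant_id", "condition")]
  if (nrow(dropped)) {
    message("dropping ", nrow(dropped),
            " participant/condition pair(s) missing one or more blocks: ",
            paste(paste0(dropped$participant_id, "/", dropped$condition),
                  collapse = ", "))
  }
  wide <- wide[complete, , drop = FALSE]
  wide$action_binding_ms <- wide$mean_error_operant_action - wide$mean_error_baseline_action
  wide$tone_binding_ms <- wide$mean_error_operant_tone - wide$mean_error_baseline_tone
  out <- dplyr::arrange(wide, .data$participant_id, .data$condition)
  attr(out, "dropped") <- dropped
  class(out) <- c("binding_table", class(out))
  out
}

#' Group summary of binding data in the conventional table layout
#'
#' Summarises a [binding_scores()] table into the layout used to report
#' Libet-clock experiments: per condition and judged event, the mean (SD) raw
#' judgment error in the baseline and operant blocks and the mean (SD) shift
#' from baseline.
#'
#' @param binding A `binding_table`.
#' @return A tibble with columns `condition`, `event`, `baseline_mean`,
#'   `baseline_sd`, `operant_mean`, `operant_sd`, `shift_mean`, `shift_sd`,
#'   `n_participants`.
#' @export
binding_summary <- function(binding) {
  long <- tibble::tibble(
    condition = rep(binding$condition, 2L),
    event = rep(c("action", "tone"), each = nrow(binding)),
    baseline = c(binding$mean_error_baseline_action, binding$mean_error_baseline_tone),
    operant = c(binding$mean_error_operant_action, binding$mean_error_operant_tone),
    shift = c(binding$action_binding_ms, binding$tone_binding_ms)
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$event),
    baseline_mean = mean(.data$baseline), baseline_sd = stats::sd(.data$baseline),
    operant_mean = mean(.data$operant), operant_sd = stats::sd(.data$operant),
    shift_mean = mean(.data$shift), shift_sd = stats::sd(.data$shift),
    n_participants = dplyr::n(),
    .groups = "drop"
  )
}

#' Binding shifts implied by printed block means
#'
#' Reconstructs the "mean shift from baseline" column from group-level block
#' means alone (shift = operant mean - baseline mean). Because the group mean
#' of per-participant differences equals the difference of group means when
#' every participant contributes to both blocks, this reproduces the published
#' shift columns up to table rounding.
#'
#' @param block_means Tibble with columns `condition`, `event`,
#'   `baseline_mean`, `operant_mean` (e.g. a subset of
#'   [reference_block_summaries()]).
#' @return The input with an added `shift_mean` column.
#' @export
shift_from_block_means <- function(block_means) {
  stopifnot(all(c("baseline_mean", "operant_mean") %in% names(block_means)))
  block_means$shift_mean <- block_means$operant_mean - block_means$baseline_mean
  block_means
}

#' Published block-level summaries bundled with the package
#'
#' Group-level means and SDs of raw judgment errors and baseline-corrected
#' shifts for the five clock-parameter experiments (three clock speeds, two
#' marking manipulations, three hand lengths). These calibrate the synthetic
#' generator and serve as donor effects for prior derivation.
#'
#' @param experiment Optional experiment number (1-5) to filter to.
#' @return Tibble with one row per experiment x condition x event.
#' @export
reference_block_summaries <- function(experiment = NULL) {
  path <- system.file("extdata", "block_summaries.csv", package = "libetbind",
                      mustWork = TRUE)
  out <- readr::read_csv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  if (!is.null(experiment)) out <- out[out$experiment %in% experiment, , drop = FALSE]
  out
}
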