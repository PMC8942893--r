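#' Group-level participant screening
#'
#' Operationalises the usual group-level outlier screen for binding studies as
#' a deterministic rule. For each condition x binding measure the group
#' skewness and excess kurtosis (bias-corrected, small-sample formulas, the
#' ones mainstream statistics packages print) are computed, and participants
#' are compared against Tukey fences on that measure:
#'
#' * beyond 3 x IQR from the quartiles: flagged `extreme` and always excluded;
#' * beyond 1.5 x IQR: flagged `outlier`, excluded only when the measure they
#'   are extreme on is itself distorted, i.e. has |skewness| > 2 or
#'   |excess kurtosis| > 2 before any exclusion;
#' * otherwise not flagged.
#'
#' This replaces "visual inspection of boxplots and histograms" with the
#' boxplot rule it draws, so the same data always yield the same exclusions.
#'
#' @param binding A `binding_table` from [binding_scores()].
#' @param fence_flag,fence_exclude IQR multipliers for the flag and
#'   auto-exclude fences (defaults 1.5 and 3).
#' @param moment_cutoff Absolute skewness/kurtosis beyond which a distribution
#'   counts as distorted (default 2).
#' @return A list of class `screening_report`: `moments` (per condition x
#'   measure skewness/kurtosis), `flags` (per participant x condition x
#'   measure flag level and values), `excluded` (participant ids with
#'   reasons), `kept` (binding table without excluded participants).
#' @export
screen_participants <- function(binding, fence_flag = 1.5, fence_exclude = 3,
                                moment_cutoff = 2) {
  if (dplyr::n_distinct(binding$participant_id) < 5L) {
    stop("participant screening needs at least 5 participants.", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    binding[c("participant_id", "condition", "action_binding_ms", "tone_binding_ms")],
    cols = c("action_binding_ms", "tone_binding_ms"),
    names_to = "measure", values_to = "value"
  )
  moments <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$measure),
    skewness = e1071::skewness(.data$value, type = 2),
    kurtosis = e1071::kurtosis(.data$value, type = 2),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    .groups = "drop"
  )
  moments$iqr <- moments$q3 - moments$q1
  moments$distorted <- abs(moments$skewness) > moment_cutoff |
    abs(moments$kurtosis) > moment_cutoff

  flags <- dplyr::left_join(long, moments, by = c("condition", "measure"))
  flags$flag <- dplyr::case_when(
    flags$value < flags$q1 - fence_exclude * flags$iqr |
      flags$value > flags$q3 + fence_exclude * flags$iqr ~ "extreme",
    flags$value < flags$q1 - fence_flag * flags$iqr |
      flags$value > flags$q3 + fence_flag * flags$iqr ~ "outlier",
    TRUE ~ "none"
  )
  flags$exclude <- flags$flag == "extreme" |
    (flags$flag == "outlier" & flags$distorted)
  flags <- flags[c("participant_id", "condition", "measure", "value",
                   "skewness", "kurtosis", "flag", "exclude")]

  hits <- flags[flags$exclude, , drop = FALSE]
  excluded <- if (nrow(hits)) {
    dplyr::summarise(
      dplyr::group_by(hits, .data$participant_id),
      reason = paste(
        sprintf("%s/%s: %s (%.1f ms, skew %.2f, kurt %.2f)",
                .data$condition, .data$measure, .data$flag, .data$value,
                .data$skewness, .data$kurtosis),
        collapse = "; "),
      .groups = "drop"
    )
  } else {
    tibble::tibble(participant_id = character(), reason = character())
  }
  kept <- binding[!binding$participant_id %in% excluded$participant_id, , drop = FALSE]
  structure(
    list(moments = moments[c("condition", "measure", "skewness", "kurtosis", "distorted")],
         flags = flags, excluded = excluded, kept = kept),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d participant(s) excluded of %d\n",
              nrow(x$excluded),
              nrow(x$excluded) + dplyr::n_distinct(x$kept$participant_id)))
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded))) {
      cat("  -", x$excluded$participant_id[i], "—", x$excluded$reason[i], "\n")
    }
  }
  invisible(x)
}
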