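#' Libet clock configuration
#'
#' Describes the rotating clock stimulus used to timestamp subjective events.
#' Only `period_ms` and `n_units` enter any computation; markings, hand length
#' and diameter are carried as metadata because manipulating them does not
#' change the position-to-time mapping.
#'
#' @param period_ms Duration of one full revolution in milliseconds. The
#'   classic paradigm uses 2560 ms; fast and slow variants use 1280 and
#'   5120 ms. Any positive value is accepted.
#' @param n_units Number of clock positions per revolution (default 60, the
#'   conventional "minute" scale participants read off).
#' @param markings Marking-scheme label (e.g. `"5'"`, `"5'+1'"`, `"none"`,
#'   `"30'"`, `"15'"`). Metadata only.
#' @param hand_length_mm,diameter_mm Physical dimensions of the clock face.
#'   Metadata only.
#'
#' @return An object of class `clock_config`.
#' @examples
#' clock_config(2560)
#' clock_config(1280, markings = "5'")
#' @export
clock_config <- function(period_ms, n_units = 60, markings = "5'",
                         hand_length_mm = 9, diameter_mm = 21) {
  if (!is.numeric(period_ms) || length(period_ms) != 1L || !is.finite(period_ms) ||
      period_ms <= 0) {
    stop("`period_ms` must be a single positive number, got ",
         deparse(period_ms), call. = FALSE)
  }
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 2) {
    stop("`n_units` must be a single number >= 2.", call. = FALSE)
  }
  structure(
    list(period_ms = as.numeric(period_ms), n_units = as.numeric(n_units),
         markings = markings, hand_length_mm = hand_length_mm,
         diameter_mm = diameter_mm),
    class = "clock_config"
  )
}

#' @export
print.clock_config <- function(x, ...) {
  cat(sprintf("<clock_config> period %g ms, %g units (%.4g ms/unit), markings %s\n",
              x$period_ms, x$n_units, x$period_ms / x$n_units, x$markings))
  invisible(x)
}

#' Convert a reported clock position to a phase time
#'
#' Maps a clock-face position (in clock units, fractional allowed) to the
#' corresponding time within one revolution. Positions are reported by
#' participants as numbers read off the face; sub-unit values are accepted so
#' that no convention about rounding is forced at this stage.
#'
#' @param position_units Numeric vector of positions in `[0, n_units)`.
#' @param config A [clock_config()].
#' @return Numeric vector of phase times in milliseconds, in
#'   `[0, period_ms)`.
#' @examples
#' position_to_ms(15, clock_config(2560))  # quarter revolution -> 640 ms
#' @export
position_to_ms <- function(position_units, config) {
  stopifnot(inherits(config, "clock_config"))
  bad <- which(!is.finite(position_units) | position_units < 0 |
                 position_units >= config$n_units)
  if (length(bad)) {
    stop(sprintf(
      "reported position out of range [0, %g) at element(s) %s (values: %s)",
      config$n_units, paste(utils::head(bad, 5L), collapse = ", "),
      paste(signif(position_units[utils::head(bad, 5L)], 6), collapse = ", ")),
      call. = FALSE)
  }
  position_units * config$period_ms / config$n_units
}

#' Signed circular judgment error
#'
#' Computes reported-minus-actual event time on the clock circle: the raw
#' difference is reduced modulo the period and mapped to the symmetric
#' representative interval `(-period/2, +period/2]`, with a boundary tie
#' assigned to the positive side. Negative errors mean the report was
#' anticipatory. At the error magnitudes typical of clock timing data
#' (well under a quarter revolution) the representative is unambiguous.
#'
#' @param reported_phase_ms Reported event time within a revolution (ms), as
#'   returned by [position_to_ms()].
#' @param actual_event_ms True event time since trial onset (ms, `>= 0`); may
#'   exceed one period, only its phase matters.
#' @param config A [clock_config()].
#' @return Numeric vector of signed errors in `(-period/2, period/2]` ms.
#' @examples
#' cfg <- clock_config(2560)
#' wrap_error(2133.33, 2500, cfg)   # -366.67: anticipatory
#' wrap_error(42.67, 2550, cfg)     # +52.67: wraps past 12 o'clock
#' @export
wrap_error <- function(reported_phase_ms, actual_event_ms, config) {
  stopifnot(inherits(config, "clock_config"))
  if (any(actual_event_ms < 0, na.rm = TRUE)) {
    stop("`actual_event_ms` must be non-negative.", call. = FALSE)
  }
  p <- config$period_ms
  d <- (reported_phase_ms - actual_event_ms) %% p  # in [0, p)
  ifelse(d > p / 2, d - p, d)
}
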