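#' Omnibus clock-speed effect on binding between two speeds
#'
#' Collapses the 1-df speed x event contrast into a single magnitude: the
#' change in action binding plus the change in tone-binding *magnitude*
#' between a faster and a slower clock. Tone binding is negative (the tone is
#' pulled toward the action), so its magnitude is its absolute value;
#' equivalently the omnibus effect is
#' `[action(fast) - action(slow)] - [tone(fast) - tone(slow)]` on signed
#' shifts. This is the decomposition used to turn a donor experiment's 2-df
#' speed-by-event interaction into three 1-df directional effects that can
#' serve as half-normal prior scales.
#'
#' @param summary Condition-level binding summary with columns `condition`,
#'   `event` (`"action"`/`"tone"`) and `shift_mean` (ms), e.g. from
#'   [binding_summary()] or [reference_block_summaries()].
#' @param fast,slow Condition labels of the faster and slower clock.
#' @return The omnibus effect magnitude in ms.
#' @export
omnibus_speed_effect <- function(summary, fast, slow) {
  g <- function(cond, ev) {
    v <- summary$shift_mean[summary$condition == cond & summary$event == ev]
    if (length(v) != 1L || !is.finite(v)) {
      stop("missing ", ev, " shift for condition ", cond, call. = FALSE)
    }
    v
  }
  (g(fast, "action") - g(slow, "action")) +
    (abs(g(fast, "tone")) - abs(g(slow, "tone")))
}

#' Half-normal prior from a donor tone-binding effect
#'
#' The difference in tone-binding magnitude between two clock speeds in a
#' donor experiment, used as the SD of a half-normal prior (mean 0, all mass
#' on the predicted direction) for the same contrast in a new experiment.
#'
#' @inheritParams omnibus_speed_effect
#' @return A `prior_spec`: list with `sd` (ms) and `source` label.
#' @export
tone_effect_prior <- function(summary, fast, slow) {
  g <- function(cond) {
    v <- summary$shift_mean[summary$condition == cond & summary$event == "tone"]
    if (length(v) != 1L || !is.finite(v)) {
      stop("missing tone shift for condition ", cond, call. = FALSE)
    }
    v
  }
  sd <- abs(g(fast)) - abs(g(slow))
  if (!is.finite(sd) || sd <= 0) {
    stop("tone-binding magnitude does not increase from ", slow, " to ", fast,
         " (difference ", signif(sd, 4), " ms); half-normal prior undefined.",
         call. = FALSE)
  }
  prior_spec(sd, source = paste0("tone binding, ", fast, " vs ", slow))
}

#' @rdname dienes_bf
#' @param sd Half-normal scale in ms (> 0).
#' @param source Free-text provenance of the scale (donor contrast label).
#' @export
prior_spec <- function(sd, source = "explicit") {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("prior `sd` must be a single positive number.", call. = FALSE)
  }
  structure(list(sd = as.numeric(sd), source = source), class = "prior_spec")
}

#' Prior ledger: donor-experiment effects as half-normal scales
#'
#' Derives the full set of directional prior scales from a donor experiment's
#' condition-level binding summary: the three pairwise omnibus speed effects
#' (every two-level comparison of the three speeds) and the tone-only effect
#' between the extreme speeds. Each entry records the four shift means it was
#' computed from, so every prior is reproducible from the binding table.
#'
#' @param summary Condition-level summary with `condition`, `event`,
#'   `shift_mean` for the three speed conditions.
#' @param speeds Condition labels ordered fast to slow (default the three
#'   standard speeds).
#' @return Tibble with `label`, `type` (`omnibus`/`tone_only`), `fast`,
#'   `slow`, `prior_sd`, and the four donor means
#'   (`action_fast`, `action_slow`, `tone_fast`, `tone_slow`).
#' @export
prior_ledger <- function(summary,
                         speeds = c("speed_1280", "speed_2560", "speed_5120")) {
  stopifnot(length(speeds) == 3L)
  g <- function(cond, ev) summary$shift_mean[summary$condition == cond &
                                               summary$event == ev]
  pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  rows <- purrr::map_dfr(pairs, function(pr) {
    fast <- speeds[pr[1L]]; slow <- speeds[pr[2L]]
    tibble::tibble(
      label = paste0("omnibus ", fast, " vs ", slow),
      type = "omnibus", fast = fast, slow = slow,
      prior_sd = omnibus_speed_effect(summary, fast, slow),
      action_fast = g(fast, "action"), action_slow = g(slow, "action"),
      tone_fast = g(fast, "tone"), tone_slow = g(slow, "tone")
    )
  })
  tone <- tone_effect_prior(summary, speeds[1L], speeds[3L])
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    label = paste0("tone-only ", speeds[1L], " vs ", speeds[3L]),
    type = "tone_only", fast = speeds[1L], slow = speeds[3L],
    prior_sd = tone$sd,
    action_fast = NA_real_, action_slow = NA_real_,
    tone_fast = g(speeds[1L], "tone"), tone_slow = g(speeds[3L], "tone")
  ))
  rows
}

#' Dienes half-normal Bayes factor
#'
#' Evidence for a directional alternative against a point null, for data
#' summarised as a mean difference `M` with standard error `SE` (normal
#' likelihood). The alternative predicts a positive effect whose plausible
#' size is described by a half-normal prior with mean 0 and scale `sd`:
#'
#' \deqn{BF = \frac{\int_0^\infty N(M; \theta, SE)\, 2N(\theta; 0, sd)\,
#'   d\theta}{N(M; 0, SE)}}
#'
#' `dienes_bf()` evaluates the closed form (Gaussian product plus a normal
#' CDF); `dienes_bf_quadrature()` evaluates the same integral by adaptive
#' quadrature over `[0, 8 max(SE, sd)]` and exists as an independent numerical
#' cross-check. Pass `M` with its observed sign: an effect opposite to the
#' predicted direction lowers the BF, and the result records
#' `opposes_prediction` accordingly.
#'
#' @param M Observed mean difference (ms), signed, positive = predicted
#'   direction.
#' @param SE Standard error of `M` (> 0).
#' @param prior A `prior_spec` or a single positive number (the half-normal
#'   scale in ms).
#' @return A `bf_result`: list with `bf`, `verdict` (see [interpret_bf()]),
#'   `M`, `SE`, `prior`, `opposes_prediction`.
#' @examples
#' dienes_bf(48.11, 48.11 / sqrt(10.18), 30.9)  # ~53.4: strong evidence
#' @export
dienes_bf <- function(M, SE, prior) {
  if (is.numeric(prior)) prior <- prior_spec(prior)
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.finite(M) || !is.finite(SE) || SE <= 0) {
    stop("`M` must be finite and `SE` positive.", call. = FALSE)
  }
  s2 <- SE^2
  t2 <- prior$sd^2
  mu_post <- M * t2 / (s2 + t2)
  sd_post <- sqrt(s2 * t2 / (s2 + t2))
  num <- 2 * stats::dnorm(M, 0, sqrt(s2 + t2)) * stats::pnorm(mu_post / sd_post)
  bf <- num / stats::dnorm(M, 0, SE)
  structure(
    list(bf = bf, verdict = interpret_bf(bf), M = M, SE = SE, prior = prior,
         opposes_prediction = M < 0),
    class = "bf_result"
  )
}

#' @rdname dienes_bf
#' @param rel_tol Relative tolerance of the quadrature.
#' @export
dienes_bf_quadrature <- function(M, SE, prior, rel_tol = 1e-8) {
  if (is.numeric(prior)) prior <- prior_spec(prior)
  stopifnot(inherits(prior, "prior_spec"), is.finite(M), SE > 0)
  upper <- 8 * max(SE, prior$sd)
  num <- stats::integrate(
    function(theta) stats::dnorm(M, theta, SE) * 2 * stats::dnorm(theta, 0, prior$sd),
    lower = 0, upper = upper, rel.tol = rel_tol
  )$value
  num / stats::dnorm(M, 0, SE)
}

#' Interpret a Bayes factor
#'
#' Conventional evidence thresholds: above 3 the data provide moderate (or
#' stronger) evidence for the directional alternative, below 0.33 moderate
#' evidence for the null, and anything in `[0.33, 3]` (boundaries included)
#' is insensitive.
#'
#' @param bf Bayes factor (> 0).
#' @return One of `"supports_H1"`, `"supports_H0"`, `"insensitive"`.
#' @export
interpret_bf <- function(bf) {
  stopifnot(is.numeric(bf), all(bf > 0))
  dplyr::case_when(bf > 3 ~ "supports_H1",
                   bf < 0.33 ~ "supports_H0",
                   TRUE ~ "insensitive")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF[0, %.4g] = %.4g (%s)%s\n  M = %.4g ms, SE = %.4g ms; prior: %s\n",
              x$prior$sd, x$bf, x$verdict,
              if (x$opposes_prediction) " [effect opposes predicted direction]" else "",
              x$M, x$SE, x$prior$source))
  invisible(x)
}

#' Effect summary from a reported 1-df contrast
#'
#' Recovers the `(M, SE)` pair a Bayes factor needs from a published 1-df
#' within-subject contrast: `SE = |M| / sqrt(F)` (since `|t| = sqrt(F)` for a
#' 1-df contrast). The companion route, when participant-level differences
#' are available, is `SE = sd(diff) / sqrt(n)`; both are exposed so the
#' calculator works from either a table or raw scores.
#'
#' @param M Mean difference (ms).
#' @param f_value Reported F of the 1-df contrast (> 0).
#' @return List with `M` and `SE`.
#' @export
effect_from_contrast_f <- function(M, f_value) {
  stopifnot(is.finite(M), is.finite(f_value), f_value > 0)
  list(M = M, SE = abs(M) / sqrt(f_value))
}

#' @rdname effect_from_contrast_f
#' @param diffs Participant-level paired differences (ms).
#' @export
effect_from_differences <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) >= 2L)
  list(M = mean(diffs), SE = stats::sd(diffs) / sqrt(length(diffs)))
}
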