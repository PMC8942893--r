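# Independent oracles coded from first principles, kept separate from the
# package implementation so agreement is informative.

# Brute-force sums-of-squares decomposition for a fully within-subject
# two-factor design. y: response; s, a, b: factors (one row per s x a x b).
ss_oracle_two_way <- function(y, s, a, b) {
  s <- factor(s); a <- factor(a); b <- factor(b)
  m <- mean(y)
  ms <- tapply(y, s, mean)[s]
  ma <- tapply(y, a, mean)[a]
  mb <- tapply(y, b, mean)[b]
  mab <- tapply(y, interaction(a, b), mean)[interaction(a, b)]
  msa <- tapply(y, interaction(s, a), mean)[interaction(s, a)]
  msb <- tapply(y, interaction(s, b), mean)[interaction(s, b)]
  n <- nlevels(s); ka <- nlevels(a); kb <- nlevels(b)

  ss_a <- sum((ma - m)^2)
  ss_b <- sum((mb - m)^2)
  ss_ab <- sum((mab - ma - mb + m)^2)
  ss_as <- sum((msa - ms - ma + m)^2)
  ss_bs <- sum((msb - ms - mb + m)^2)
  ss_abs <- sum((y - msa - msb - mab + ms + ma + mb - m)^2)

  mk <- function(ss_eff, df_eff, ss_err, df_err) {
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    list(F = F, df1 = df_eff, df2 = df_err,
         p = stats::pf(F, df_eff, df_err, lower.tail = FALSE))
  }
  list(
    a = mk(ss_a, ka - 1, ss_as, (ka - 1) * (n - 1)),
    b = mk(ss_b, kb - 1, ss_bs, (kb - 1) * (n - 1)),
    ab = mk(ss_ab, (ka - 1) * (kb - 1), ss_abs, (ka - 1) * (kb - 1) * (n - 1))
  )
}

# Random complete within-subject dataset for property tests.
random_within_data <- function(seed, n = 5, ka = 3, kb = 2) {
  set.seed(seed)
  d <- expand.grid(participant_id = sprintf("s%d", seq_len(n)),
                   A = sprintf("a%d", seq_len(ka)),
                   B = sprintf("b%d", seq_len(kb)),
                   stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d), sd = 10) +
    stats::rnorm(n, sd = 5)[match(d$participant_id, unique(d$participant_id))]
  d
}

# Minimal well-formed trial table builder: one participant/condition with the
# given per-block judgment errors realised exactly (period large enough that
# no wrap occurs and quantization is off).
toy_trials <- function(errors_by_block, participant = "p1", condition = "std",
                       period = 2560, actual = 600) {
  rows <- purrr::imap_dfr(errors_by_block, function(errs, blk) {
    tibble::tibble(
      participant_id = participant, condition = condition, block = blk,
      trial_index = seq_along(errs), actual_event_ms = actual,
      reported_units = ((actual + errs) %% period) * 60 / period,
      period_ms = period
    )
  })
  rows
}

# Condition-level shift summary in the shape prior derivation expects.
shift_summary <- function(conditions, action, tone) {
  tibble::tibble(
    condition = rep(conditions, 2L),
    event = rep(c("action", "tone"), each = length(conditions)),
    shift_mean = c(action, tone)
  )
}
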