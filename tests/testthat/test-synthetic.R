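two_cond_summary <- function(sd = 0) {
  tibble::tibble(
    condition = rep(c("fast", "slow"), each = 2L),
    period_ms = rep(c(1280, 5120), each = 2L),
    event = rep(c("action", "tone"), 2L),
    baseline_mean = c(-20, 25, -10, 20),
    baseline_sd = sd, operant_mean = c(10, -50, 5, -20), operant_sd = sd,
    n_participants = 6
  )
}

test_that("the noiseless generator reproduces programmed errors exactly", {
  p <- generative_params(two_cond_summary(0), sigma_trial = 0,
                         n_trials = 4, quantize = FALSE)
  tr <- simulate_trials(p, seed = 5)
  tr <- compute_judgment_errors(tr, configs_from_params(p))
  by_cell <- dplyr::distinct(tr[c("condition", "block", "error_ms")])
  expected <- p$cells[c("condition", "block", "mean")]
  joined <- dplyr::left_join(by_cell, expected, by = c("condition", "block"))
  expect_equal(joined$error_ms, joined$mean, tolerance = 1e-9)
  # every trial, not just every cell, carries the programmed error
  expect_equal(nrow(by_cell), nrow(expected))
})

test_that("simulation is byte-identical under the same seed", {
  p <- generative_params(two_cond_summary(40), n_participants = 4, n_trials = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_log(simulate_trials(p, seed = 99), f1)
  write_trial_log(simulate_trials(p, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and differs under another seed
  write_trial_log(simulate_trials(p, seed = 100), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("trial timelines respect the procedure windows", {
  p <- generative_params(reference_block_summaries(2), n_participants = 6,
                         n_trials = 20)
  tr <- simulate_trials(p, seed = 17)
  tl <- p$timeline
  bt <- tr$actual_event_ms[tr$block == "baseline_tone"]
  expect_true(all(bt >= tl$baseline_tone_window_ms[1] &
                    bt <= tl$baseline_tone_window_ms[2]))
  act <- tr$actual_event_ms[tr$block %in% c("baseline_action", "operant_action")]
  expect_true(all(act >= tl$action_window_ms[1] & act <= tl$action_window_ms[2]))
  ot <- tr$actual_event_ms[tr$block == "operant_tone"]
  expect_true(all(ot >= tl$action_window_ms[1] + tl$outcome_delay_ms &
                    ot <= tl$action_window_ms[2] + tl$outcome_delay_ms))
})

test_that("pipeline-recovered block means sit within 3 SE of the programmed values", {
  summ <- reference_block_summaries(1)
  p <- generative_params(summ, n_participants = 39)
  tr <- simulate_trials(p, seed = 2024)
  tr <- compute_judgment_errors(tr, configs_from_params(p))
  got <- dplyr::summarise(dplyr::group_by(tr, .data$condition, .data$block),
                          m = mean(.data$error_ms), .groups = "drop")
  want <- p$cells[c("condition", "block", "mean", "sd")]
  joined <- dplyr::left_join(got, want, by = c("condition", "block"))
  se <- joined$sd / sqrt(39)
  expect_true(all(abs(joined$m - joined$mean) <= 3 * se))
})

test_that("quantization to whole units biases cell means by at most half a unit", {
  summ <- two_cond_summary(0)
  for (q in c(FALSE, TRUE)) {
    p <- generative_params(summ, sigma_trial = 0, n_participants = 3,
                           n_trials = 50, quantize = q)
    tr <- compute_judgment_errors(simulate_trials(p, seed = 8),
                                  configs_from_params(p))
    got <- dplyr::summarise(dplyr::group_by(tr, .data$condition, .data$block),
                            m = mean(.data$error_ms), .groups = "drop")
    joined <- dplyr::left_join(got, p$cells[c("condition", "block", "mean", "period_ms")],
                               by = c("condition", "block"))
    bound <- if (q) joined$period_ms / 120 else 1e-9
    expect_true(all(abs(joined$m - joined$mean) <= bound + 1e-9))
  }
})

test_that("operant-baseline difference converges to the programmed shift", {
  summ <- two_cond_summary(0)
  summ <- summ[summ$condition == "fast", ]
  p <- generative_params(summ, sigma_trial = 100, n_participants = 1,
                         n_trials = 1e4, quantize = FALSE)
  p$cells$tau <- 0
  p$cells$sigma <- 100
  tr <- compute_judgment_errors(simulate_trials(p, seed = 55),
                                configs_from_params(p))
  bt <- binding_scores(tr)
  se_diff <- sqrt(2) * 100 / sqrt(1e4)
  expect_lt(abs(bt$action_binding_ms - 30), 5 * se_diff)
  expect_lt(abs(bt$tone_binding_ms - (-75)), 5 * se_diff)
})

test_that("a programmed speed effect on tone binding is detected in most replicates", {
  p <- generative_params(reference_block_summaries(2))
  rec <- recovery_experiment(p, n_replicates = 20, seed = 310)
  rate <- rec$rates$rate_significant[rec$rates$effect == "extreme_tone"]
  expect_gt(rate, 0.6)
  # recovered shifts track the programmed ones
  expect_true(all(abs(rec$programmed$recovered_shift - rec$programmed$programmed_shift) <=
                    3 * rec$programmed$recovered_shift_se +
                    p$cells$period_ms[1] / 120))
})

test_that("null_condition_params removes condition effects but keeps binding", {
  p0 <- null_condition_params(generative_params(reference_block_summaries(2)))
  by_cond <- split(p0$cells$mean, paste(p0$cells$event, p0$cells$block_type))
  for (v in by_cond) expect_equal(diff(range(v)), 0)
  shift <- p0$cells$mean[p0$cells$block == "operant_tone"][1] -
    p0$cells$mean[p0$cells$block == "baseline_tone"][1]
  expect_lt(shift, 0)
})
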