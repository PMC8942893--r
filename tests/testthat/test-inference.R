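test_that("partial eta-squared reproduces published effect sizes and is monotone", {
  expect_equal(round(partial_eta_squared(10.18, 1, 39), 3), 0.207)
  expect_equal(round(partial_eta_squared(6.08, 2, 78), 3), 0.135)
  expect_equal(round(partial_eta_squared(55.66, 1, 38), 3), 0.594)
  expect_equal(partial_eta_squared(0, 2, 40), 0)
  fs <- seq(0, 50, by = 0.5)
  es <- partial_eta_squared(fs, 2, 40)
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 0 & es < 1))
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  for (seed in 1:10) {
    d <- random_within_data(seed, n = 5, ka = 3, kb = 2)
    got <- rm_anova(d, dv = "y", within = c("A", "B"))
    want <- ss_oracle_two_way(d$y, d$participant_id, d$A, d$B)
    for (pair in list(c("A", "a"), c("B", "b"), c("A:B", "ab"))) {
      g <- got[got$effect == pair[1L], ]
      w <- want[[pair[2L]]]
      expect_equal(g$F, w$F, tolerance = 1e-10)
      expect_equal(g$p, w$p, tolerance = 1e-10)
      expect_equal(c(g$df_effect, g$df_error), c(w$df1, w$df2))
    }
  }
})

test_that("for a two-level factor F equals the squared paired t", {
  set.seed(21)
  d <- expand.grid(participant_id = sprintf("s%d", 1:9),
                   cond = c("x", "y"), stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d)) + rep(c(0, 0.8), each = 9)
  an <- rm_anova(d, dv = "y", within = "cond")
  wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
  tt <- stats::t.test(wide$x, wide$y, paired = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(an$p, tt$p.value, tolerance = 1e-12)
})

test_that("rm_anova is invariant to row order and response shifts; flat profiles give no effect", {
  d <- random_within_data(99)
  a1 <- rm_anova(d, dv = "y", within = c("A", "B"))
  d2 <- d[sample(nrow(d)), ]
  d2$y <- d2$y + 1234.5
  a2 <- rm_anova(d2, dv = "y", within = c("A", "B"))
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  # every participant flat across cells: zero variance between conditions,
  # so every effect is zero and its test undefined
  d$y <- c(1, 2, 5, 9, 14)[match(d$participant_id, unique(d$participant_id))]
  flat <- rm_anova(d, dv = "y", within = c("A", "B"))
  expect_equal(flat$F, rep(0, 3))
  expect_true(all(is.na(flat$p)))
})

test_that("incomplete designs are rejected with the missing cells listed", {
  d <- random_within_data(7)
  d <- d[!(d$participant_id == "s2" & d$A == "a3" & d$B == "b1"), ]
  expect_error(rm_anova(d, dv = "y", within = c("A", "B")), "s2/a3/b1")
})

test_that("sphericity diagnostics match the multivariate-route reference", {
  skip_if_not_installed("car")
  d <- random_within_data(123, n = 12, ka = 3, kb = 2)
  got <- rm_anova(d, dv = "y", within = c("A", "B"))
  wide <- tidyr::pivot_wider(d, names_from = c("A", "B"), values_from = "y",
                             names_sort = TRUE)
  Y <- as.matrix(wide[-1])
  idata <- expand.grid(B = factor(c("b1", "b2")), A = factor(c("a1", "a2", "a3")))
  idata <- idata[order(idata$A, idata$B), ]
  fit <- stats::lm(Y ~ 1)
  ref <- suppressWarnings(  # car warns about its own HF eps > 1
    summary(car::Anova(fit, idata = idata, idesign = ~ A * B, type = 3),
            multivariate = FALSE))
  sph <- ref$sphericity.tests
  pva <- ref$pval.adjustments
  for (eff in c("A", "A:B")) {
    mine <- got[got$effect == sub(":", ":", ifelse(eff == "A", "A", "A:B")), ]
    expect_equal(mine$mauchly_W, unname(sph[eff, "Test statistic"]), tolerance = 1e-6)
    expect_equal(mine$mauchly_p, unname(sph[eff, "p-value"]), tolerance = 1e-6)
    expect_equal(mine$gg_epsilon, unname(pva[eff, "GG eps"]), tolerance = 1e-6)
    expect_equal(mine$p_gg, unname(pva[eff, "Pr(>F[GG])"]), tolerance = 1e-6)
  }
})

test_that("Greenhouse-Geisser correction never lowers the p-value and epsilon is bounded", {
  for (seed in 1:6) {
    d <- random_within_data(seed + 40, n = 8, ka = 4, kb = 2)
    an <- rm_anova(d, dv = "y", within = c("A", "B"))
    three <- an[!is.na(an$gg_epsilon), ]
    # the correction is conservative in the upper tail (where it matters);
    # for F below ~1 shrinking both dfs can lower a large p slightly
    sig <- three[three$F >= 1.5, ]
    expect_true(all(sig$p_gg >= sig$p - 1e-12))
    expect_true(all(three$gg_epsilon >= 1 / three$df_effect - 1e-12 &
                      three$gg_epsilon <= 1 + 1e-12))
  }
  # epsilon exactly 1 reproduces the uncorrected p: force a spherical
  # covariance by construction (independent equal-variance contrasts would
  # give eps ~ 1; instead verify the formula at eps = 1 analytically)
  F <- 4.2; df1 <- 2; df2 <- 20
  expect_equal(stats::pf(F, df1 * 1, df2 * 1, lower.tail = FALSE),
               stats::pf(F, df1, df2, lower.tail = FALSE))
})

test_that("bonferroni_pairwise multiplies by the number of pairs and caps at 1", {
  set.seed(31)
  d <- expand.grid(participant_id = sprintf("s%d", 1:10),
                   cond = c("a", "b", "c"), stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d))
  res <- bonferroni_pairwise(d, dv = "y", factor = "cond")
  expect_equal(nrow(res), 3)
  expect_equal(unique(res$n_comparisons), 3)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 3))
  expect_equal(res$p_bonferroni,
               stats::p.adjust(res$p, "bonferroni", n = 3), tolerance = 1e-12)
  # identical levels: zero difference, p_bonferroni 1
  d2 <- d[d$cond != "c", ]
  d2$y[d2$cond == "b"] <- d2$y[d2$cond == "a"]
  res2 <- bonferroni_pairwise(d2, dv = "y", factor = "cond")
  expect_equal(res2$mean_diff, 0)
  expect_equal(res2$p_bonferroni, 1)
})

test_that("a planted 30 ms difference (n = 40, sd 60) is usually detected", {
  hits <- vapply(1:200, function(r) {
    set.seed(5000 + r)
    base <- stats::rnorm(40, 0, 50)
    d <- tibble::tibble(
      participant_id = rep(sprintf("s%d", 1:40), 2L),
      cond = rep(c("slow", "fast"), each = 40),
      y = c(base, base + 30 + stats::rnorm(40, 0, 60))
    )
    bonferroni_pairwise(d, dv = "y", factor = "cond")$p_bonferroni < 0.05
  }, logical(1L))
  expect_gt(mean(hits), 0.5)
})

test_that("cousineau_ci removes pure between-participant variance", {
  # two participants with identical profiles shifted by a constant
  d <- tibble::tibble(
    participant_id = rep(c("s1", "s2"), each = 2L),
    cond = rep(c("c1", "c2"), 2L),
    y = c(0, 10, 20, 30)
  )
  ci <- cousineau_ci(d, dv = "y", conditions = "cond")
  expect_equal(ci$mean, c(10, 20))
  expect_equal(ci$ci_half_width, c(0, 0))
  # incomplete matrix is rejected
  expect_error(cousineau_ci(d[-1, ], dv = "y", conditions = "cond"), "incomplete")
})

test_that("cousineau_ci matches the analytic within-subject half-width on simulated data", {
  set.seed(61)
  n <- 40; J <- 3; sigma_w <- 25
  u <- stats::rnorm(n, 0, 80)  # large between-participant spread
  d <- tidyr::expand_grid(participant_id = sprintf("s%02d", 1:n),
                          cond = sprintf("c%d", 1:J))
  d$y <- u[match(d$participant_id, unique(d$participant_id))] +
    stats::rnorm(nrow(d), 0, sigma_w)
  ci <- cousineau_ci(d, dv = "y", conditions = "cond")
  analytic <- stats::qt(0.975, n - 1) * sigma_w / sqrt(n)
  # normalisation shrinks variances by (J-1)/J; the Morey-corrected width is
  # the unbiased estimate of the analytic within-subject half-width
  cim <- cousineau_ci(d, dv = "y", conditions = "cond", morey = TRUE)
  expect_true(all(abs(cim$ci_half_width - analytic) / analytic < 0.20))
  expect_equal(cim$ci_half_width, ci$ci_half_width * sqrt(J / (J - 1)))
  expect_true(all(abs(ci$ci_half_width - analytic * sqrt((J - 1) / J)) /
                    analytic < 0.20))
})
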