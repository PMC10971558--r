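test_that("caliper volume follows the modified-ellipsoid formula", {
  expect_equal(tumor_volume(6, 5), 75)
  expect_equal(tumor_volume(4, 4), 4^3 / 2)       # sphere-like L = W = d
  expect_equal(tumor_volume(10, 2), 20)
  expect_equal(tumor_volume(10, 4), 4 * tumor_volume(10, 2))
  # scale equivariance: (sL)(sW)^2/2 = s^3 V
  expect_equal(tumor_volume(3 * 6, 3 * 5), 27 * tumor_volume(6, 5))
  expect_error(tumor_volume(5, 6), "orientation")
  expect_error(tumor_volume(-1, -2), "positive")
})

test_that("percent reduction reproduces the dose-escalation contrasts", {
  expect_equal(round(percent_reduction(1160, 1657), 1), 30)
  expect_equal(round(percent_reduction(595, 1657), 1), 64.1)
  expect_equal(percent_reduction(1000, 1000), 0)
  expect_error(percent_reduction(100, 0), "positive")
})

test_that("one-way ANOVA matches its textbook special cases", {
  # identical constant groups: no variation at all
  res <- anova_oneway(list(a = rep(5, 4), b = rep(5, 4), c = rep(5, 4)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # two groups: F is the square of the pooled-variance t statistic
  set.seed(21)
  x <- rnorm(8, 10, 2); y <- rnorm(6, 12, 2)
  res2 <- anova_oneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-12)
  # F is invariant under adding a constant to every observation
  res3 <- anova_oneway(list(x = x + 100, y = y + 100))
  expect_equal(res3$statistic, res2$statistic, tolerance = 1e-9)
  expect_gt(res2$p_value, 0); expect_lte(res2$p_value, 1)
  expect_error(anova_oneway(list(a = 1:3)), "two groups")
  expect_error(anova_oneway(list(a = 1:3, b = 2)), "at least two obs")
})

test_that("Welch tests match a hand-evaluated Welch-Satterthwaite computation", {
  a <- c(10.1, 12.3, 11.0)
  b <- c(14.2, 13.1, 15.7)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a) / 3; v2 <- var(b) / 3
  t_manual <- (m1 - m2) / sqrt(v1 + v2)
  df_manual <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  res <- welch_pairwise(list(a = a, b = b), list(c("a", "b")))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$df, df_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, p_manual * 1))
})

test_that("Bonferroni adjustment never lowers p and caps at one", {
  set.seed(9)
  gl <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5) + 3)
  cmp <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  res <- welch_pairwise(gl, cmp)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
  expect_equal(res$p_adjusted,
               pmin(1, res$p_value * 3))
  expect_identical(res$significant, res$p_adjusted < 0.05)
  expect_error(welch_pairwise(gl, list(c("a", "zz"))), "unknown group")
  expect_error(welch_pairwise(list(a = 1, b = 1:3), list(c("a", "b"))),
               "n >= 2")
})

test_that("near-identical groups give a vanishing Welch statistic", {
  a <- c(5, 6, 7, 8)
  res <- welch_pairwise(list(g1 = a, g2 = a + 1e-12), list(c("g1", "g2")))
  expect_lt(abs(res$statistic), 1e-6)
  expect_gt(res$p_value, 0.999)
})

test_that("the analysis pipeline is deterministic from CSV to results", {
  cohort <- generate_cohort(cohort_preset("four-arm-day7")$specs, days = 7,
                            seed = 42)
  f <- tempfile(fileext = ".csv")
  write_caliper_csv(cohort, f)
  back <- read_caliper_csv(f)
  res1 <- analyze_growth(back)
  res2 <- analyze_growth(read_caliper_csv(f))
  expect_identical(res1, res2)
  expect_setequal(res1$summaries$group,
                  c("control", "RT2Gy", "FUS-HT", "FUS-HT+RT2Gy"))
  expect_equal(res1$summaries$n[res1$summaries$group == "FUS-HT"], 10)
  expect_equal(nrow(res1$welch), 3)
  unlink(f)
})

test_that("synthetic cohorts at the one-week group statistics separate decisively", {
  preset <- cohort_preset("four-arm-day7")
  set.seed(123)
  p_anova <- replicate(200, {
    cohort <- generate_cohort(preset$specs, days = 7)
    anova_oneway(volumes_by_group(cohort, 7))$p_value
  })
  expect_gt(mean(p_anova < 1e-5), 0.5)
  # combined arm vs control is significant in most draws
  set.seed(124)
  sig <- replicate(200, {
    cohort <- generate_cohort(preset$specs, days = 7)
    vols <- volumes_by_group(cohort, 7)
    res <- welch_pairwise(vols, list(c("FUS-HT+RT2Gy", "control")), m = 3)
    res$significant
  })
  expect_gt(mean(sig), 0.5)
})
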