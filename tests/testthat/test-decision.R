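test_that("findSteady picks the first qualifying window", {
  d <- findSteady(CountSeries(0:2, c(50, 50, 50)))
  expect_true(steadyFound(d))
  expect_identical(d@window_start_i, 1L)
  expect_identical(nStdy(d), 50L)
  expect_identical(criterionUsed(d), "small_n")

  # mixed series: the first window that satisfies the relative rule
  d2 <- findSteady(CountSeries(0:7, c(0, 10, 80, 120, 200, 201, 202, 202)))
  expect_identical(d2@window_start_i, 5L)  # counts[5] = 200 (1-based)
  expect_identical(nStdy(d2), 202L)
  expect_identical(criterionUsed(d2), "large_n")
  expect_equal(tStdy(d2), 6)

  d3 <- findSteady(CountSeries(0:4, c(5, 7, 8, 8, 8)))
  expect_identical(d3@window_start_i, 2L)
  expect_identical(nStdy(d3), 8L)
  expect_identical(criterionUsed(d3), "small_n")

  expect_error(findSteady(CountSeries(0:1, c(3, 3))), "at least 3")
  expect_false(steadyFound(findSteady(CountSeries(0:3, c(0, 5, 50, 500)))))
})

test_that("the criterion switches exactly at a window-opening count of 100", {
  at100 <- findSteady(CountSeries(0:2, c(100L, 101L, 101L)))
  expect_identical(criterionUsed(at100), "small_n")
  expect_identical(nStdy(at100), 101L)
  at101 <- findSteady(CountSeries(0:2, c(101L, 102L, 102L)))
  expect_identical(criterionUsed(at101), "large_n")
  # 101 -> 103 jumps by ~2%: large-count rule rejects what the absolute
  # rule would not have
  expect_false(steadyFound(findSteady(CountSeries(0:2, c(101L, 103L, 103L)))))
  # an all-zero prefix is never steady
  expect_false(steadyFound(findSteady(CountSeries(0:3, c(0L, 0L, 0L, 0L)))))
})

test_that("findSteady is invariant to frames appended after the decision", {
  base <- c(2L, 10L, 30L, 41L, 42L, 42L, 43L)
  d1 <- findSteady(CountSeries(seq_along(base) - 1, base))
  d2 <- findSteady(CountSeries(0:9, c(base, 60L, 80L, 90L)))
  expect_identical(d1@window_start_i, d2@window_start_i)
  expect_identical(nStdy(d1), nStdy(d2))
  expect_identical(tStdy(d1), tStdy(d2))
})

test_that("confirmCount returns the final count and time", {
  expect_identical(confirmCount(CountSeries(c(0, 8, 16, 24),
                                            c(0L, 6L, 7L, 7L)))$n_conf, 7L)
  cc <- confirmCount(CountSeries(c(0, 24, 48), c(0L, 2155L, 2240L)))
  expect_identical(cc$n_conf, 2240L)
  expect_identical(cc$t_conf_h, 48)
  expect_identical(confirmCount(CountSeries(0, 3L))$n_conf, 3L)
})

test_that("relativeDifference reports signed percent to one decimal", {
  expect_identical(relativeDifference(2155, 2240), 3.8)
  expect_identical(relativeDifference(7, 7), 0)
  expect_identical(relativeDifference(90, 100), 10)
  expect_identical(relativeDifference(110, 100), -10)
  expect_error(relativeDifference(5, 0), "n_conf")
})

test_that("classifyOutcome distinguishes the late-change scenarios", {
  s <- CountSeries(0:4, c(0L, 6L, 7L, 7L, 7L))
  d <- findSteady(s)
  expect_identical(classifyOutcome(s, d, confirmCount(s))$scenario,
                   "steady_unchanged")
  s_up <- CountSeries(0:5, c(0L, 2000L, 2155L, 2155L, 2155L, 2240L))
  d_up <- findSteady(s_up)
  expect_identical(classifyOutcome(s_up, d_up, confirmCount(s_up))$scenario,
                   "late_increase")
  s_dn <- CountSeries(0:5, c(0L, 9L, 10L, 10L, 10L, 8L))
  d_dn <- findSteady(s_dn)
  expect_identical(classifyOutcome(s_dn, d_dn, confirmCount(s_dn))$scenario,
                   "late_decrease")
  s_no <- CountSeries(0:3, c(0L, 2L, 20L, 200L))
  expect_identical(classifyOutcome(s_no, findSteady(s_no),
                                   confirmCount(s_no))$scenario, "no_steady")
})

test_that("loglogRegression matches the closed-form OLS oracle", {
  ident <- loglogRegression(c(10, 100, 1000, 5000), c(10, 100, 1000, 5000))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r, 1)

  ns <- c(4, 30, 210, 1800)
  nc <- c(5, 28, 230, 1750)
  x <- log10(ns); y <- log10(nc)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_hand <- mean(y) - slope_hand * mean(x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  fit <- loglogRegression(ns, nc)
  expect_equal(fit$slope, slope_hand)
  expect_equal(fit$intercept, int_hand)
  expect_equal(fit$r, r_hand)
  expect_identical(fit$r_squared, fit$r^2)
  expect_identical(fit$df, 2L)
  t_hand <- r_hand * sqrt(2) / sqrt(1 - r_hand^2)
  expect_equal(fit$t_stat, t_hand)
  expect_equal(fit$p_corr, 2 * pt(-abs(t_hand), 2))
  # the alternative df convention, as printed for 6 samples with df 5
  expect_identical(loglogRegression(ns, nc, "n_minus_1")$df, 3L)

  anti <- loglogRegression(c(10, 100, 1000), c(900, 80, 11))
  expect_lt(anti$r, 0)

  expect_error(loglogRegression(c(0, 10, 100), c(1, 10, 100)), ">= 1")
  expect_error(loglogRegression(c(10, 20), c(10, 20)), "at least 3")
  expect_error(loglogRegression(c(10, 10, 10), c(1, 5, 9)), "singular")
})

test_that("pairedTimeTest matches hand arithmetic and rejects degeneracy", {
  expect_error(pairedTimeTest(c(4, 6, 8), c(4, 6, 8)), "degenerate")
  res <- pairedTimeTest(c(0, 0), c(1, 3))   # d = {1, 3}
  expect_equal(res$t_stat, 2)               # mean 2 / (sd sqrt2 / sqrt 2)
  expect_identical(as.integer(res$df), 1L)
  # near-constant positive differences: overwhelming significance
  t_stdy <- c(10, 11, 12, 13, 14, 15)
  t_conf <- t_stdy + 8 + c(0.01, -0.01, 0.02, -0.02, 0.01, -0.01)
  res2 <- pairedTimeTest(t_stdy, t_conf)
  d <- t_conf - t_stdy
  expect_equal(res2$t_stat, mean(d) / (sd(d) / sqrt(6)))
  expect_lt(res2$p, 1e-3)
  expect_gt(abs(res2$t_stat), 100)
})
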