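test_that("month ranking is deterministic with earlier-month tie-breaks", {
  expect_equal(rank_months(1:12), 1:12)
  expect_equal(rank_months(rep(2, 12)), 1:12)
  expect_equal(rank_months(c(5, 5, 1, rep(10, 9)))[1:3], c(2L, 3L, 1L))
  expect_error(rank_months(1:11), "12")
})

test_that("the maximum circular rank sum matches known configurations", {
  # ranks 7..12 in six consecutive positions: T = 7+8+...+12 = 57
  r <- c(7:12, 1:6)
  ms <- max_rank_sum(r)
  expect_equal(ms$T, 57L)
  expect_equal(ms$window_start, 1L)
  # wrap-around window
  r2 <- c(10, 11, 12, 1:6, 7, 8, 9)   # high ranks straddle December
  expect_equal(max_rank_sum(r2)$T, 57L)
  expect_equal(max_rank_sum(r2)$window_start, 10L)
  alt <- c(1, 12, 2, 11, 3, 10, 4, 9, 5, 8, 6, 7)
  expect_equal(max_rank_sum(alt)$T, oracle_max_rank_sum(alt))
  expect_error(max_rank_sum(c(1:11, 11)), "permutation")
})

test_that("implementation agrees with the brute-force oracle and T >= 40", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      r <- sample(12)
      T <- max_rank_sum(r)$T
      expect_identical(T, as.integer(oracle_max_rank_sum(r)))
      expect_gte(T, 40L)
      expect_lte(T, 57L)
    }
  })
})

test_that("the statistic is invariant to rotation and reflection", {
  withr::with_seed(23, {
    for (i in 1:50) {
      means <- runif(12, 1, 10)
      T0 <- max_rank_sum(rank_months(means))$T
      k <- sample(0:11, 1)
      rot <- means[((0:11 + k) %% 12) + 1]
      expect_equal(max_rank_sum(rank_months(rot))$T, T0)
      expect_equal(max_rank_sum(rank_months(rev(means)))$T, T0)
    }
  })
})

test_that("the exact null distribution is a proper, monotone tail", {
  tab <- hewitt_null_table(method = "exact")
  expect_equal(tab$T, 40:57)
  expect_equal(tab$p[1], 1)                       # every permutation >= 40
  expect_true(all(diff(tab$p) < 0))               # strictly decreasing tail
  d <- diff(c(tab$p, 0))                          # -P(T = t)
  expect_equal(sum(-d), 1)                        # probabilities sum to 1
})

test_that("exact enumeration matches the analytic P(T = 57)", {
  p57 <- hewitt_pvalue(57, method = "exact")
  expect_equal(p57, 12 * factorial(6)^2 / factorial(12), tolerance = 1e-12)
})

test_that("Monte Carlo and exact p-values agree within sampling error", {
  n <- 2e5
  tab_mc <- hewitt_null_table(method = "montecarlo", n_sims = n, seed = 3)
  tab_ex <- hewitt_null_table(method = "exact")
  for (i in seq_len(nrow(tab_ex))) {
    se <- sqrt(tab_ex$p[i] * (1 - tab_ex$p[i]) / n)
    expect_lt(abs(tab_mc$p[i] - tab_ex$p[i]), 3 * se + 2 / n)
  }
})

test_that("p-value inputs are validated", {
  expect_error(hewitt_pvalue(39), "40..57")
  expect_error(hewitt_pvalue(58), "40..57")
  expect_error(hewitt_pvalue(50.5), "40..57")
})

test_that("hewitt_test flags flat input as degenerate", {
  expect_warning(r <- hewitt_test(rep(1, 12), method = "exact"), "flat")
  expect_true(r$degenerate)
  expect_equal(r$T, 57L)   # tie rule leaves consecutive ranks
  r2 <- hewitt_test(c(8, 9, 10, 7, 5, 3, 1, 2, 4, 6, 11, 12),
                    method = "exact")
  expect_false(r2$degenerate)
  expect_equal(r2$T, max_rank_sum(rank_months(c(8, 9, 10, 7, 5, 3, 1, 2,
                                                4, 6, 11, 12)))$T)
})
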