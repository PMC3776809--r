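test_that("the seasonal-range statistic is the spread of monthly means", {
  flat <- climatology(monthly_series(rep(3, 24), c(2000, 1)))
  expect_equal(climatology_range(flat), 0)
  step <- climatology(monthly_series(rep(c(2, 4), each = 6), c(2000, 1)))
  expect_equal(climatology_range(step), 2)
})

test_that("the statistic approaches its generator closed form on long spans", {
  # A = 0.4 on baseline 10: D -> 10 * ((1.4) - (0.6)) = 8
  s <- simulate_site(site_spec("x", n_months = 2400,
                               trend_coeffs = c(10, 0, 0),
                               amplitude = 0.4, peak_month = 1, seed = 21))
  expect_equal(climatology_range(climatology(s)), 8, tolerance = 0.12)
})

test_that("statistic pipeline agrees with a brute-force oracle", {
  for (seed in 41:70) {
    rs <- random_series(seed)
    expect_equal(climatology_range(climatology(rs)),
                 oracle_climatology_range(rs))
  }
})

test_that("an extreme series hits the add-one p-value floor", {
  # all cases in January: no reassignment can match the observed spread
  cnt <- rep(0, 120); cnt[seq(1, 120, by = 12)] <- 500
  s <- monthly_series(cnt, c(2000, 1))
  r <- site_mc_test(s, n_sims = 10000, seed = 2)
  expect_equal(r$p_value, 1 / 10001)
  expect_equal(r$p_printed, 0.0001)
})

test_that("degenerate Monte Carlo inputs are refused", {
  s <- monthly_series(rep(1, 24), c(2000, 1))
  expect_error(site_mc_test(s, n_sims = 0), "at least 1")
  expect_error(site_mc_test(monthly_series(rep(0, 24), c(2000, 1)),
                            n_sims = 10), "no cases")
  expect_error(site_mc_test(monthly_series(rep(1.5, 24), c(2000, 1)),
                            n_sims = 10), "integer")
})

test_that("the test is reproducible and the flag variant runs", {
  s <- simulate_site(site_spec("x", n_months = 120,
                               trend_coeffs = c(20, 0.2, 0),
                               amplitude = 0.3, peak_month = 5, seed = 6))
  a <- site_mc_test(s, n_sims = 500, seed = 9)
  b <- site_mc_test(s, n_sims = 500, seed = 9)
  expect_identical(a, b)
  d <- site_mc_test(s, n_sims = 500, seed = 9, on_detrended = TRUE)
  expect_true(d$p_value >= 1 / 501 && d$p_value <= 1)
})

test_that("null rejection rate sits near the nominal level", {
  rej <- vapply(1:200, function(r) {
    s <- simulate_site(site_spec("x", n_months = 120,
                                 trend_coeffs = c(20, 0, 0),
                                 amplitude = 0, seed = 20000 + r))
    site_mc_test(s, n_sims = 199, seed = 50000 + r)$p_value <= 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("a strong seasonal signal is detected in both record halves", {
  s <- simulate_site(site_spec("x", n_months = 240,
                               trend_coeffs = c(50, 0, 0),
                               amplitude = 0.5, peak_month = 2, seed = 13))
  hs <- half_split(s)
  expect_equal(length(hs$first$counts), 120)
  expect_equal(length(hs$second$counts), 120)
  expect_lte(site_mc_test(hs$first, n_sims = 999, seed = 1)$p_value, 0.05)
  expect_lte(site_mc_test(hs$second, n_sims = 999, seed = 2)$p_value, 0.05)
})

test_that("half-splitting follows the ceiling convention at month boundaries", {
  s25 <- monthly_series(rep(2, 25), c(2000, 4))
  hs <- half_split(s25)
  expect_equal(length(hs$first$counts), 13)
  expect_equal(length(hs$second$counts), 12)
  # second half starts the month after the first ends
  expect_equal(c(hs$second$start_year, hs$second$start_month), c(2001, 5))
  expect_error(half_split(monthly_series(rep(1, 23), c(2000, 1))),
               "at least 24")
})
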