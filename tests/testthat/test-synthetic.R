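test_that("simulated totals match the Poisson expectation for a flat site", {
  # expected total = 10 cases/month x 120 months = 1200
  totals <- vapply(1:25, function(s) {
    sum(simulate_site(site_spec("x", n_months = 120,
                                trend_coeffs = c(10, 0, 0),
                                amplitude = 0, seed = s))$counts)
  }, 0)
  expect_true(all(abs(totals - 1200) < 4 * sqrt(1200)))
  expect_lt(abs(mean(totals) - 1200), 3 * sqrt(1200 / 25))
})

test_that("seasonal peak lands on the requested calendar month", {
  # at 20 occurrences/month the peak month beats its two neighbours
  # (whose means differ by only ~1 SE) roughly 3 times in 4, and is
  # essentially never more than one month off
  peaks <- vapply(1:200, function(s) {
    cl <- climatology(simulate_site(site_spec("x", n_months = 240,
                                              trend_coeffs = c(50, 0, 0),
                                              amplitude = 0.4, peak_month = 2,
                                              seed = 1000 + s)))
    which.max(cl$means)
  }, 0L)
  expect_gte(mean(peaks == 2), 0.60)
  expect_gte(mean(peaks %in% 1:3), 0.95)
})

test_that("simulation is byte-identical under a fixed spec and seed", {
  sp <- site_spec("det", n_months = 60, trend_coeffs = c(5, 0.1, 0),
                  amplitude = 0.3, peak_month = 7, ramp_months = 12,
                  seed = 99)
  expect_identical(simulate_site(sp), simulate_site(sp))
  a <- simulate_sector(4, seed = 42)
  b <- simulate_sector(4, seed = 42)
  expect_identical(a, b)
})

test_that("per-site seeds are stable hashes: site output survives subsetting", {
  whole <- simulate_sector(6, seed = 7)
  specs <- attr(whole, "specs")
  # re-simulating any single site from its spec reproduces it exactly
  for (i in c(1, 4, 6))
    expect_identical(simulate_site(specs[[i]]), whole[[i]])
})

test_that("reporting ramp suppresses early counts", {
  s <- simulate_site(site_spec("r", n_months = 120,
                               trend_coeffs = c(100, 0, 0),
                               ramp_months = 36, seed = 5))
  expect_identical(s$counts[1], 0)  # r(0) = 0
  expect_lt(mean(s$counts[1:18]), mean(s$counts[101:120]) / 2)
})

test_that("invalid site specs are rejected before sampling", {
  expect_error(site_spec("x", n_months = 6), "at least 12")
  expect_error(site_spec("x", amplitude = 1), "amplitude")
  expect_error(site_spec("x", amplitude = -0.1), "amplitude")
  expect_error(site_spec("x", trend_coeffs = c(5, -1, 0), n_months = 120),
               "positive")
  expect_error(site_spec("x", peak_month = 13), "peak_month")
})

test_that("sector generation validates its arguments and wraps the jitter", {
  expect_error(simulate_sector(0), "at least 1")
  expect_error(simulate_sector(3, size_range = c(10, 5)), "min <= max")
  expect_length(simulate_sector(1, seed = 3), 1)
  peaks <- vapply(attr(simulate_sector(40, shared_peak = 1, peak_jitter = 2,
                                       seed = 8), "specs"),
                  `[[`, 0L, "peak_month")
  expect_true(all(peaks %in% c(11, 12, 1, 2, 3)))
})

test_that("case expansion inverts monthly aggregation exactly", {
  s <- monthly_series(c(2, 0, 1), start = c(2001, 1), site_id = "tiny")
  cs <- cases_from_counts(s)
  expect_equal(nrow(cs), 3)
  expect_equal(cs$month, c(1, 1, 3))
  expect_equal(nrow(cases_from_counts(
    monthly_series(rep(0, 14), c(2000, 1)))), 0)
  # round trip over random sites
  for (seed in 1:20) {
    rs <- random_series(seed)
    back <- aggregate_to_monthly(cases_from_counts(rs),
                                 start = c(rs$start_year, rs$start_month),
                                 n_months = length(rs$counts),
                                 site_id = rs$site_id)
    expect_equal(back$counts, rs$counts)
  }
  expect_error(cases_from_counts(monthly_series(c(1.5, 2), c(2000, 1))),
               "integer")
})
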