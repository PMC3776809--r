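test_that("latitude maps to sectors with the 23-degree band inclusive", {
  expect_equal(assign_sector(35.7), "NH-extratropics")
  expect_equal(assign_sector(23), "tropics")
  expect_equal(assign_sector(-23), "tropics")
  expect_equal(assign_sector(0), "tropics")
  expect_equal(assign_sector(-31.9), "SH-extratropics")
  expect_error(assign_sector(95), "latitude")
})

test_that("sector aggregation is an equal-weight mean of ratios", {
  x <- c(1.5, 1.2, 1.0, 0.9, 0.8, 0.7, 0.6, 0.7, 0.9, 1.0, 1.2, 1.5)
  one <- aggregate_sector(matrix(x, 1, 12))
  expect_equal(unname(one$aggregate), x)
  # mirror pair averages out flat
  two <- aggregate_sector(rbind(x, 2 - x))
  expect_equal(unname(two$aggregate), rep(1, 12))
  expect_equal(two$excess_pct, 0)
  expect_error(aggregate_sector(matrix(numeric(0), 0, 12)), "empty")
})

test_that("peak, trough and excess summarize the aggregate", {
  s1 <- simulate_site(site_spec("a", n_months = 240, latitude = 40,
                                trend_coeffs = c(80, 0, 0),
                                amplitude = 0.4, peak_month = 2, seed = 1))
  s2 <- simulate_site(site_spec("b", n_months = 240, latitude = 50,
                                trend_coeffs = c(40, 0, 0),
                                amplitude = 0.4, peak_month = 2, seed = 2))
  agg <- aggregate_sector(list(s1, s2), sector = "NH-extratropics")
  expect_equal(agg$peak_month, 2)
  expect_equal(((agg$trough_month - 2) %% 12), 6)  # trough opposite peak
  expect_gt(agg$excess_pct, 50)
  expect_equal(agg$n_sites, 2)
})

test_that("a single-site sector has rotation-invariant statistic and p = 1", {
  x <- matrix(runif(12, 0.5, 1.5), 1, 12)
  r <- sector_mc_test(x, n_sims = 500, seed = 4)
  expect_equal(r$p_value, 1)
})

test_that("the sector null is invariant under a common rotation of all sites", {
  withr::with_seed(31, {
    mat <- matrix(runif(60, 0.5, 1.5), 5, 12)
    k <- 4
    rot <- mat[, ((0:11 + k) %% 12) + 1]
    a <- sector_mc_test(mat, n_sims = 400, seed = 9)
    b <- sector_mc_test(rot, n_sims = 400, seed = 9)
    expect_equal(a$observed_stat, b$observed_stat)
    expect_equal(a$p_value, b$p_value)
  })
})

test_that("phase-aligned sites are significant, phase-null sites are not", {
  aligned <- simulate_sector(10, shared_peak = 2, peak_jitter = 0,
                             amplitude_range = c(0.4, 0.4),
                             size_range = c(50, 200),
                             span_range = c(120, 240), seed = 15)
  pa <- sector_mc_test(aligned, n_sims = 999, seed = 5)$p_value
  expect_lte(pa, 0.01)
  nullphase <- simulate_sector(8, shared_peak = 2, peak_jitter = 6,
                               amplitude_range = c(0.2, 0.4),
                               size_range = c(20, 100),
                               span_range = c(120, 240), seed = 16)
  pn <- sector_mc_test(nullphase, n_sims = 999, seed = 6)$p_value
  expect_gt(pn, 0.05)
})

test_that("sector null rejection rate is near nominal", {
  rej <- vapply(1:200, function(r) {
    sl <- lapply(1:6, function(i)
      simulate_site(site_spec(paste0("s", i), n_months = 120,
                              trend_coeffs = c(20, 0, 0), amplitude = 0,
                              seed = 900 * i + r)))
    sector_mc_test(sl, n_sims = 199, seed = 7000 + r)$p_value <= 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("Hewitt on a flat aggregate warns; on a peaked one it scores high", {
  flat <- aggregate_sector(matrix(1, 3, 12), sector = "tropics")
  expect_warning(hf <- hewitt_on_aggregate(flat, method = "exact"), "flat")
  expect_equal(hf$T, 57L)
  expect_true(hf$degenerate)
  peaked <- simulate_sector(8, shared_peak = 1, peak_jitter = 1,
                            amplitude_range = c(0.3, 0.5),
                            size_range = c(50, 200),
                            span_range = c(180, 300), seed = 19)
  hp <- hewitt_on_aggregate(aggregate_sector(peaked), method = "exact")
  expect_gte(hp$T, 50L)
})

test_that("half-split sector reporting excludes short sites and measures peaks", {
  long <- simulate_sector(6, shared_peak = 2, peak_jitter = 0,
                          amplitude_range = c(0.4, 0.5),
                          size_range = c(50, 150),
                          span_range = c(240, 300), seed = 25)
  short <- simulate_site(site_spec("stub", n_months = 18,
                                   trend_coeffs = c(30, 0, 0), seed = 3))
  expect_warning(
    rep <- half_split_sector(c(long, list(short)), n_sims = 499, seed = 8),
    "shorter than 24")
  expect_equal(rep$n_sites_used, 6)
  expect_equal(rep$excluded, "stub")
  expect_lte(rep$peak_distance, 1)
  expect_lte(rep$mc_first$p_value, 0.05)
  expect_lte(rep$mc_second$p_value, 0.05)
})

test_that("aggregate excess approaches its closed form 100*2A/(1-A)", {
  sec <- simulate_sector(8, shared_peak = 6, peak_jitter = 0,
                         amplitude_range = c(0.4, 0.4),
                         size_range = c(50, 50),
                         span_range = c(240, 240), seed = 33)
  agg <- aggregate_sector(sec)
  expect_equal(agg$excess_pct, 100 * 2 * 0.4 / (1 - 0.4), tolerance = 0.12)
})
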