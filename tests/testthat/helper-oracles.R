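# Independent brute-force oracles. These deliberately share no code
# with the package internals they check.

# maximum circular 6-month rank sum by direct double loop
oracle_max_rank_sum <- function(ranks) {
  best <- -Inf
  for (start in 1:12) {
    s <- 0
    for (off in 0:5) s <- s + ranks[(start - 1 + off) %% 12 + 1]
    if (s > best) best <- s
  }
  best
}

# largest monthly-mean difference computed by explicit loops over the
# (year, month) records of a series
oracle_climatology_range <- function(series) {
  yrs <- year_of(series)
  mons <- month_of(series)
  means <- numeric(12)
  for (m in 1:12) {
    sel <- mons == m
    means[m] <- sum(series$counts[sel]) / sum(sel)
  }
  max(means) - min(means)
}

# small random count series covering all 12 calendar months
random_series <- function(seed, n_months = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_months)) n_months <- sample(12:60, 1)
    monthly_series(rpois(n_months, sample(1:30, 1)),
                   start = c(2000, sample(1:12, 1)),
                   site_id = paste0("rs", seed))
  })
}
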