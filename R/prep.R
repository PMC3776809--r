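#' Minimum-case inclusion filter
#'
#' Sites whose whole record holds fewer than `threshold` cases are too
#' small to yield a stable estimate of any seasonal variation and are
#' excluded from analysis. The default of 30 reflects standard practice
#' for monthly climatologies of rare-disease counts.
#'
#' @param series a [monthly_series()].
#' @param threshold minimum total cases required to keep the site.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
filter_min_cases <- function(series, threshold = 30) {
  stopifnot(inherits(series, "monthly_series"))
  sum(series$counts) >= threshold
}

#' Trim sparse leading years from a series
#'
#' Surveillance records often open with years of very few (or zero)
#' reported cases before reporting is established. Whole calendar years
#' are dropped from the start of the series while the year's total
#' cases fall below `primary` (default 24, i.e. two cases per month on
#' average), stopping at the first year that meets the threshold. If
#' that rule would discard the entire series, it is reapplied with the
#' laxer `fallback` threshold (default 12), so genuinely small sites
#' remain analysable. Interior sparse years are never removed, and the
#' trimmed series never starts mid-year unless nothing was trimmed.
#'
#' @param series a [monthly_series()] of counts.
#' @param primary cases/year below which a leading year is dropped.
#' @param fallback laxer threshold used when `primary` would drop
#'   everything.
#' @return The trimmed [monthly_series()], with attributes
#'   `"years_trimmed"` (integer) and `"used_fallback"` (logical).
#' @export
trim_low_years <- function(series, primary = 24, fallback = 12) {
  stopifnot(inherits(series, "monthly_series"))
  if (length(series$counts) < 12)
    stop("series shorter than 12 months cannot be year-trimmed", call. = FALSE)
  yrs <- year_of(series)
  totals <- tapply(series$counts, yrs, sum)
  uyrs <- as.integer(names(totals))

  lead_drop <- function(th) {
    k <- 0L
    for (v in totals) {
      if (v >= th) break
      k <- k + 1L
    }
    k
  }
  k <- lead_drop(primary)
  used_fallback <- FALSE
  if (k >= length(totals)) {
    k <- lead_drop(fallback)
    used_fallback <- TRUE
    if (k >= length(totals))
      stop("untestable series: every leading year falls below the fallback threshold",
           call. = FALSE)
  }
  out <- if (k == 0L) series else {
    first_keep <- match(TRUE, yrs == uyrs[k + 1L])
    series_window(series, first_keep, length(series$counts))
  }
  attr(out, "years_trimmed") <- k
  attr(out, "used_fallback") <- used_fallback
  out
}

#' Remove a quadratic trend by division
#'
#' Fits the least-squares second-order polynomial in the month index
#' `t = 0..n-1` to the counts and divides the series by the fitted
#' values. Division (rather than subtraction) both removes the trend
#' and damps the heteroscedasticity that comes with growing counts:
#' Poisson variance scales with the mean, so the ratio series has
#' roughly stable variance. Zero-count months are retained as ratio 0.
#'
#' @param series a [monthly_series()] of counts.
#' @return A [monthly_series()] on the ratio scale (`scale = "ratio"`).
#'   Errors with "degenerate trend fit" if any fitted value is at or
#'   below `1e-6` times the overall mean, since dividing by a near-zero
#'   or negative trend is meaningless.
#' @export
detrend_series <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  y <- series$counts
  n <- length(y)
  if (n < 3) stop("need at least 3 months to fit a quadratic", call. = FALSE)
  tt <- seq_len(n) - 1
  fit <- fitted(lm(y ~ tt + I(tt^2)))
  eps <- 1e-6 * mean(y)
  if (any(fit <= eps))
    stop("degenerate trend fit: fitted quadratic is non-positive within the span",
         call. = FALSE)
  monthly_series(y / fit, start = c(series$start_year, series$start_month),
                 site_id = series$site_id, latitude = series$latitude,
                 scale = "ratio")
}

#' Monthly climatology of a series
#'
#' For each of the 12 calendar months, the mean value over all
#' occurrences of that month in the span, together with the number of
#' occurrences and the overall monthly mean (total divided by span
#' length). Requires the span to reach every calendar month at least
#' once.
#'
#' @param series a [monthly_series()].
#' @return An object of class `climatology` with fields `means` (length
#'   12, January first), `occurrences` (length 12), `overall_mean`,
#'   `n_months`, `total`, `site_id`, `latitude`.
#' @export
#' @examples
#' s <- simulate_site(site_spec("x", amplitude = 0.4, peak_month = 2,
#'                              n_months = 240, seed = 3))
#' cl <- climatology(s)
#' which.max(cl$means)
climatology <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  m <- month_of(series)
  occ <- tabulate(m, nbins = 12L)
  if (any(occ == 0L))
    stop("span shorter than a full year: some calendar month never occurs",
         call. = FALSE)
  sums <- vapply(1:12, function(k) sum(series$counts[m == k]), 0)
  structure(
    list(means = sums / occ, occurrences = occ,
         overall_mean = sum(series$counts) / length(series$counts),
         n_months = length(series$counts), total = sum(series$counts),
         site_id = series$site_id, latitude = series$latitude),
    class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> site %s: %d months, overall mean %.4g\n",
              x$site_id, x$n_months, x$overall_mean))
  print(round(stats::setNames(x$means, month.abb), 4))
  invisible(x)
}

#' Normalize a climatology by its overall monthly mean
#'
#' Dividing the 12 monthly means by the overall monthly mean puts sites
#' of very different size on a common dimensionless scale (ratio 1 =
#' average month), so that each site carries the same weight in sector
#' aggregation.
#'
#' @param clim a [climatology()].
#' @return Numeric vector of 12 ratios, named by month abbreviation.
#' @export
normalize_climatology <- function(clim) {
  stopifnot(inherits(clim, "climatology"))
  if (clim$overall_mean <= 0)
    stop("overall monthly mean is zero; cannot normalize", call. = FALSE)
  stats::setNames(clim$means / clim$overall_mean, month.abb)
}
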