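#' Specification of one synthetic surveillance site
#'
#' Describes the generative model for a single site's monthly counts:
#' independent Poisson counts with intensity
#' \deqn{\lambda(t) = r(t)\,(c_0 + c_1 t + c_2 t^2)\,
#'   \{1 + A \cos(2\pi (m(t) - \phi)/12)\},}
#' where `t = 0, 1, ...` indexes months, `m(t)` is the calendar month,
#' `A` the relative seasonal amplitude, `phi` (`peak_month`) the calendar
#' month of peak intensity, and `r(t)` a linear reporting ramp rising
#' from 0 at `t = 0` to 1 at `t = ramp_months` (identically 1 when
#' `ramp_months = 0`). The ramp emulates the sparse, zero-heavy early
#' years typical of newly established surveillance records; the
#' quadratic baseline emulates secular trends with the attendant
#' heteroscedasticity of growing counts.
#'
#' @param site_id character site label.
#' @param latitude degrees in -90..90.
#' @param start `c(year, month)` of the first simulated month.
#' @param n_months span length, at least 12.
#' @param trend_coeffs `c(c0, c1, c2)`: baseline cases/month as a
#'   quadratic in the month index; must stay positive over the span.
#' @param amplitude seasonal amplitude `A` in `[0, 1)` (0 = no season).
#' @param peak_month calendar month 1..12 of peak intensity.
#' @param ramp_months length of the linear reporting ramp (0 = none).
#' @param seed integer seed for this site's Poisson draws.
#'
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, latitude = 35, start = c(2000, 1),
                      n_months = 120, trend_coeffs = c(10, 0, 0),
                      amplitude = 0, peak_month = 1, ramp_months = 0,
                      seed = 1L) {
  if (n_months < 12) stop("'n_months' must be at least 12", call. = FALSE)
  if (amplitude < 0 || amplitude >= 1)
    stop("'amplitude' must lie in [0, 1)", call. = FALSE)
  if (!peak_month %in% 1:12)
    stop("'peak_month' must be a calendar month 1..12", call. = FALSE)
  if (ramp_months < 0) stop("'ramp_months' must be >= 0", call. = FALSE)
  if (length(trend_coeffs) != 3)
    stop("'trend_coeffs' must be c(c0, c1, c2)", call. = FALSE)
  tt <- 0:(n_months - 1)
  base <- trend_coeffs[1] + trend_coeffs[2] * tt + trend_coeffs[3] * tt^2
  if (any(base <= 0))
    stop("baseline trend must be positive over the whole span", call. = FALSE)
  structure(
    list(site_id = as.character(site_id), latitude = latitude,
         start = as.integer(start), n_months = as.integer(n_months),
         trend_coeffs = as.numeric(trend_coeffs),
         amplitude = amplitude, peak_month = as.integer(peak_month),
         ramp_months = as.integer(ramp_months), seed = as.integer(seed)),
    class = "site_spec")
}

# uniform integer in [a, b] immune to sample()'s scalar expansion
sample_int_range <- function(a, b) {
  if (a == b) as.integer(a) else
    as.integer(a) + sample.int(as.integer(b - a) + 1L, 1L) - 1L
}

# deterministic 31-bit stream seed for a site under a master seed, so
# per-site output is reproducible across subset runs and parallelism
site_stream_seed <- function(master_seed, site_id) {
  h <- 0
  for (cc in utf8ToInt(as.character(site_id)))
    h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(master_seed) * 7919 + h + 1) %% 2147483647)
}

#' Simulate monthly counts for one site
#'
#' Draws independent Poisson monthly counts under the intensity model of
#' [site_spec()]. Identical spec (including seed) gives identical
#' output.
#'
#' @param spec a [site_spec()].
#' @return A [monthly_series()] of simulated counts.
#' @export
#' @examples
#' s <- simulate_site(site_spec("demo", amplitude = 0.4, peak_month = 2,
#'                              seed = 7))
#' climatology(s)
simulate_site <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  tt <- 0:(spec$n_months - 1)
  base <- spec$trend_coeffs[1] + spec$trend_coeffs[2] * tt +
    spec$trend_coeffs[3] * tt^2
  m <- ((spec$start[2] - 1 + tt) %% 12) + 1
  seas <- 1 + spec$amplitude * cos(2 * pi * (m - spec$peak_month) / 12)
  ramp <- if (spec$ramp_months > 0) pmin(1, tt / spec$ramp_months) else 1
  lambda <- ramp * base * seas
  if (any(lambda < 0)) stop("negative intensity; rejecting spec", call. = FALSE)
  counts <- withr::with_seed(spec$seed, rpois(spec$n_months, lambda))
  monthly_series(counts, start = spec$start, site_id = spec$site_id,
                 latitude = spec$latitude)
}

#' Simulate a latitude sector of heterogeneous sites
#'
#' Generates `n_sites` independent site specifications sharing a common
#' seasonal peak month up to an integer jitter, with site sizes drawn
#' log-uniformly (surveillance records span orders of magnitude, from
#' tens to hundreds of thousands of cases) and spans drawn uniformly,
#' then simulates each site. Per-site seeds are derived from the master
#' seed by stable hashing of the site id, so any subset of sites
#' reproduces exactly.
#'
#' @param n_sites number of sites, at least 1.
#' @param shared_peak common calendar peak month 1..12.
#' @param peak_jitter maximum absolute integer jitter (months) applied
#'   to each site's peak, wrapped mod 12. `peak_jitter = 6` makes phases
#'   uniform over the year (a phase-null sector).
#' @param size_range `c(min, max)` baseline cases/month, sampled
#'   log-uniformly.
#' @param span_range `c(min, max)` span in months, sampled uniformly.
#' @param amplitude_range `c(min, max)` seasonal amplitude per site.
#' @param latitude_range `c(min, max)` latitudes assigned to sites.
#' @param start `c(year, month)` shared span start.
#' @param ramp_range `c(min, max)` reporting-ramp length in months.
#' @param seed master integer seed.
#'
#' @return A list of [monthly_series()], one per site, with the
#'   generating `site_spec`s attached as attribute `"specs"`.
#' @export
simulate_sector <- function(n_sites, shared_peak = 2, peak_jitter = 1,
                            size_range = c(10, 500),
                            span_range = c(120, 360),
                            amplitude_range = c(0.2, 0.5),
                            latitude_range = c(25, 60),
                            start = c(1990, 1), ramp_range = c(0, 0),
                            seed = 1L) {
  if (n_sites < 1) stop("'n_sites' must be at least 1", call. = FALSE)
  for (rg in list(size_range, span_range, amplitude_range, ramp_range))
    if (length(rg) != 2 || rg[2] < rg[1])
      stop("ranges must be c(min, max) with min <= max", call. = FALSE)
  if (size_range[1] <= 0) stop("'size_range' must be positive", call. = FALSE)
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_sites), function(i) {
      id <- sprintf("site%02d", i)
      jit <- sample_int_range(-peak_jitter, peak_jitter)
      site_spec(
        site_id = id,
        latitude = runif(1, latitude_range[1], latitude_range[2]),
        start = start,
        n_months = sample_int_range(span_range[1], span_range[2]),
        trend_coeffs = c(exp(runif(1, log(size_range[1]), log(size_range[2]))),
                         0, 0),
        amplitude = runif(1, amplitude_range[1], amplitude_range[2]),
        peak_month = ((shared_peak - 1 + jit) %% 12) + 1,
        ramp_months = if (ramp_range[2] > 0)
          sample_int_range(ramp_range[1], ramp_range[2]) else 0L,
        seed = site_stream_seed(seed, id))
    })
  })
  out <- lapply(specs, simulate_site)
  names(out) <- vapply(specs, `[[`, "", "site_id")
  attr(out, "specs") <- specs
  out
}

#' Expand a monthly count series to case-level records
#'
#' Produces one record per case, the unit resampled by the per-site
#' Monte Carlo test. Inverse of [aggregate_to_monthly()].
#'
#' @param series a [monthly_series()] of non-negative integer counts.
#' @return A data frame with columns `site`, `year`, `month` and one row
#'   per case, in chronological order.
#' @export
#' @examples
#' s <- monthly_series(c(2, 0, 1), start = c(2001, 1))
#' cases_from_counts(s)
cases_from_counts <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  cn <- series$counts
  if (any(cn != round(cn)))
    stop("counts must be integers to expand into case records", call. = FALSE)
  idx <- rep.int(seq_along(cn), cn)
  data.frame(site = rep.int(series$site_id, length(idx)),
             year = year_of(series)[idx],
             month = month_of(series)[idx],
             stringsAsFactors = FALSE)
}
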