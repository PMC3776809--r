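#' Monthly count series for one surveillance site
#'
#' The basic container of the package: a vector of case counts (or
#' detrended count ratios) for consecutive calendar months at one site,
#' together with the span start and optional site metadata. Missing
#' months are not permitted; a month with no reported cases is an
#' explicit zero.
#'
#' @param counts numeric vector of non-negative values, one per
#'   consecutive calendar month.
#' @param start length-2 integer vector `c(year, month)` of the first
#'   observation; `month` in 1..12.
#' @param site_id character scalar identifying the site.
#' @param latitude site latitude in degrees (-90..90), `NA` if unknown.
#' @param scale `"count"` for raw case counts, `"ratio"` for detrended
#'   series (counts divided by a fitted trend).
#'
#' @return An object of class `monthly_series`.
#' @export
#' @examples
#' s <- monthly_series(c(2, 0, 1, 4), start = c(2001, 11), site_id = "demo")
#' month_of(s)   # 11 12 1 2
monthly_series <- function(counts, start, site_id = "site",
                           latitude = NA_real_, scale = c("count", "ratio")) {
  scale <- match.arg(scale)
  counts <- as.numeric(counts)
  if (length(counts) < 1L)
    stop("'counts' must contain at least one month", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("'counts' must be non-negative and free of NA", call. = FALSE)
  if (length(start) != 2L || start[2] < 1 || start[2] > 12)
    stop("'start' must be c(year, month) with month in 1..12", call. = FALSE)
  if (!is.na(latitude) && (latitude < -90 || latitude > 90))
    stop("'latitude' must lie in [-90, 90]", call. = FALSE)
  structure(
    list(site_id = as.character(site_id),
         latitude = as.numeric(latitude),
         start_year = as.integer(start[1]),
         start_month = as.integer(start[2]),
         counts = counts,
         scale = scale),
    class = "monthly_series")
}

#' @export
length.monthly_series <- function(x) length(x$counts)

#' Calendar month (1..12) of each observation in a series
#' @param x a [monthly_series()].
#' @return Integer vector the length of the series.
#' @export
month_of <- function(x) {
  stopifnot(inherits(x, "monthly_series"))
  ((x$start_month - 1L + seq_along(x$counts) - 1L) %% 12L) + 1L
}

#' Calendar year of each observation in a series
#' @param x a [monthly_series()].
#' @return Integer vector the length of the series.
#' @export
year_of <- function(x) {
  stopifnot(inherits(x, "monthly_series"))
  x$start_year + (x$start_month - 1L + seq_along(x$counts) - 1L) %/% 12L
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$counts)
  end_m <- ((x$start_month - 1L + n - 1L) %% 12L) + 1L
  end_y <- x$start_year + (x$start_month - 1L + n - 1L) %/% 12L
  cat(sprintf("<monthly_series> site %s (lat %s): %d months, %s-%02d to %s-%02d\n",
              x$site_id, format(x$latitude), n,
              x$start_year, x$start_month, end_y, end_m))
  cat(sprintf("  total %s cases/month units (%s scale), mean %.3g\n",
              format(sum(x$counts)), x$scale, mean(x$counts)))
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(site = x$site_id, year = year_of(x), month = month_of(x),
             count = x$counts, stringsAsFactors = FALSE)
}

# internal: take a sub-window [from, to] (1-based month indices) of a series
series_window <- function(x, from, to) {
  stopifnot(from >= 1, to <= length(x$counts), from <= to)
  off <- x$start_month - 1L + from - 1L
  monthly_series(x$counts[from:to],
                 start = c(x$start_year + off %/% 12L, (off %% 12L) + 1L),
                 site_id = x$site_id, latitude = x$latitude, scale = x$scale)
}
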