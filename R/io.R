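#' Read and write surveillance data as delimited text
#'
#' All files are comma-delimited UTF-8 with a header row. Case lists
#' have columns `site,year,month` (one row per case); monthly count
#' tables are long format `site,year,month,count`; site metadata is
#' `site,latitude`.
#'
#' @param path file path.
#' @name kd_io
NULL

check_columns <- function(df, wanted, path) {
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

check_month_col <- function(df, path) {
  bad <- which(!(df$month %in% 1:12))
  if (length(bad))
    stop(sprintf("'%s': month out of 1..12 at row(s) %s", path,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' @rdname kd_io
#' @return `read_cases()`: a data frame `site,year,month`, one row per case.
#' @export
read_cases <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, c("site", "year", "month"), path)
  check_month_col(df, path)
  df[c("site", "year", "month")]
}

#' @rdname kd_io
#' @param cases data frame `site,year,month`.
#' @export
write_cases <- function(cases, path) {
  write.csv(cases[c("site", "year", "month")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname kd_io
#' @return `read_counts()`: a named list of [monthly_series()], one per
#'   site, built from the long-format table; months must be consecutive
#'   within each site.
#' @export
read_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, c("site", "year", "month", "count"), path)
  check_month_col(df, path)
  if (any(df$count < 0) || anyNA(df$count))
    stop(sprintf("'%s': counts must be non-negative and non-missing", path),
         call. = FALSE)
  out <- lapply(split(df, df$site), function(d) {
    d <- d[order(d$year, d$month), ]
    idx <- d$year * 12L + (d$month - 1L)
    if (nrow(d) > 1 && any(diff(idx) != 1L))
      stop(sprintf("'%s': site %s has gaps or duplicate months; missing months must be explicit zeros",
                   path, d$site[1]), call. = FALSE)
    monthly_series(d$count, start = c(d$year[1], d$month[1]),
                   site_id = d$site[1])
  })
  out[order(names(out))]
}

#' @rdname kd_io
#' @param series_list a list of [monthly_series()].
#' @export
write_counts <- function(series_list, path) {
  if (inherits(series_list, "monthly_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname kd_io
#' @return `read_sites()`: a data frame `site,latitude`.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, c("site", "latitude"), path)
  if (anyNA(df$latitude) || any(df$latitude < -90 | df$latitude > 90))
    stop(sprintf("'%s': latitude must lie in [-90, 90]", path), call. = FALSE)
  df[c("site", "latitude")]
}

#' Aggregate case-level records to a monthly count series
#'
#' Bins one-row-per-case records into the consecutive calendar months of
#' a declared span. Cases falling outside the span are an error (the
#' offending record is named), so silent truncation cannot occur.
#'
#' @param cases data frame with columns `site`, `year`, `month` (one row
#'   per case); at most one site.
#' @param start `c(year, month)` of the span.
#' @param n_months span length in months.
#' @param site_id site label for the result; defaults to the one site
#'   present in `cases` (required when `cases` is empty).
#' @param latitude optional latitude carried into the result.
#' @return A [monthly_series()] whose counts sum to `nrow(cases)`.
#' @export
aggregate_to_monthly <- function(cases, start, n_months,
                                 site_id = NULL, latitude = NA_real_) {
  check_columns(cases, c("site", "year", "month"), "cases")
  if (is.null(site_id)) {
    ids <- unique(cases$site)
    if (length(ids) > 1)
      stop("'cases' holds several sites; aggregate one site at a time",
           call. = FALSE)
    site_id <- if (length(ids)) ids else "site"
  }
  idx <- (cases$year - start[1]) * 12L + (cases$month - start[2]) + 1L
  bad <- which(idx < 1L | idx > n_months)
  if (length(bad))
    stop(sprintf("case record(s) outside the declared span, e.g. row %d (%d-%02d)",
                 bad[1], cases$year[bad[1]], cases$month[bad[1]]),
         call. = FALSE)
  monthly_series(tabulate(idx, nbins = n_months), start = start,
                 site_id = site_id, latitude = latitude)
}
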