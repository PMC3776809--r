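#' Latitude sector of a site
#'
#' Sectors split at 23 degrees: the Northern Hemisphere extra-tropics
#' poleward of 23N, the Southern Hemisphere extra-tropics poleward of
#' 23S, and the tropics between (the 23-degree boundary itself counts
#' as tropics, "poleward" being read strictly).
#'
#' @param latitude degrees, in -90..90.
#' @return One of `"NH-extratropics"`, `"tropics"`, `"SH-extratropics"`.
#' @export
#' @examples
#' assign_sector(35.7)   # "NH-extratropics"
#' assign_sector(23)     # "tropics"
assign_sector <- function(latitude) {
  if (anyNA(latitude) || any(latitude < -90 | latitude > 90))
    stop("'latitude' must lie in [-90, 90]", call. = FALSE)
  ifelse(latitude > 23, "NH-extratropics",
         ifelse(latitude < -23, "SH-extratropics", "tropics"))
}

# normalize a list of count series into a sites x 12 ratio matrix
ratio_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 12) stop("ratio matrix must have 12 columns", call. = FALSE)
    return(x)
  }
  if (inherits(x, "monthly_series")) x <- list(x)
  rows <- lapply(x, function(s) {
    if (inherits(s, "monthly_series")) normalize_climatology(climatology(s))
    else if (inherits(s, "climatology")) normalize_climatology(s)
    else if (is.numeric(s) && length(s) == 12) s
    else stop("cannot interpret input as normalized climatologies",
              call. = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(x))) rownames(out) <- names(x)
  out
}

#' Equal-weight sector aggregate of normalized climatologies
#'
#' Averages the sites' normalized 12-month climatologies with equal
#' weight per site — normalization by each site's overall monthly mean
#' ensures a 271,000-case record counts no more than a 300-case one —
#' and summarizes the aggregate's peak, trough and relative seasonal
#' excess.
#'
#' @param x a list of [monthly_series()] / [climatology()] objects or
#'   normalized 12-vectors, or a sites-by-12 matrix of ratios.
#' @param sector optional sector label carried into the result.
#' @return List of class `sector_aggregate`: `aggregate` (12 mean
#'   ratios), `peak_month`, `trough_month`, `excess_pct`
#'   (`(max - min)/min * 100`), `n_sites`, `site_ids`, `sector`.
#' @export
aggregate_sector <- function(x, sector = NA_character_) {
  mat <- ratio_matrix(x)
  if (nrow(mat) < 1) stop("empty sector: no sites to aggregate", call. = FALSE)
  agg <- colMeans(mat)
  structure(list(aggregate = stats::setNames(agg, month.abb),
                 peak_month = unname(which.max(agg)),
                 trough_month = unname(which.min(agg)),
                 excess_pct = (max(agg) - min(agg)) / min(agg) * 100,
                 n_sites = nrow(mat),
                 site_ids = rownames(mat),
                 sector = sector),
            class = "sector_aggregate")
}

#' @export
print.sector_aggregate <- function(x, ...) {
  cat(sprintf("<sector_aggregate> %s: %d sites, peak %s, trough %s, excess %.1f%%\n",
              x$sector, x$n_sites, month.abb[x$peak_month],
              month.abb[x$trough_month], x$excess_pct))
  print(round(x$aggregate, 3))
  invisible(x)
}

#' Circular-shift Monte Carlo test of a sector aggregate
#'
#' Null hypothesis: the sites' seasonal phases are unrelated, so the
#' aggregate's monthly variation is what random phase alignment
#' produces. Each replicate rotates every site's normalized 12-month
#' climatology by an independent uniform circular shift (the monthly
#' means and their relative sequence are preserved, only the phase
#' moves), averages across sites, and records the largest difference
#' between any two aggregate months (identically max - min). The
#' p-value is the add-one rank of the observed statistic. With a
#' single site the statistic is rotation-invariant and p is 1 by
#' construction.
#'
#' @inheritParams aggregate_sector
#' @param n_sims Monte Carlo replicates (default 10,000).
#' @param seed integer seed.
#' @return List of class `sector_mc_result`: `observed_stat`,
#'   `p_value`, `n_sims`, `seed`.
#' @export
sector_mc_test <- function(x, n_sims = 10000, seed = 1L) {
  if (n_sims < 1) stop("'n_sims' must be at least 1", call. = FALSE)
  mat <- ratio_matrix(x)
  agg <- colMeans(mat)
  d_obs <- max(agg) - min(agg)
  n_ge <- withr::with_seed(as.integer(seed), {
    chunk <- 5000L
    acc <- 0L
    done <- 0L
    idx <- outer(0:11, 0:11, function(m, k) ((m + k) %% 12) + 1)
    while (done < n_sims) {
      nk <- as.integer(min(chunk, n_sims - done))
      tot <- matrix(0, 12, nk)
      for (s in seq_len(nrow(mat))) {
        rot <- matrix(mat[s, idx], 12, 12)   # column k+1 = shift by k
        shifts <- sample.int(12L, nk, replace = TRUE)
        tot <- tot + rot[, shifts]
      }
      sims <- (apply(tot, 2, max) - apply(tot, 2, min)) / nrow(mat)
      acc <- acc + sum(sims >= d_obs)
      done <- done + nk
    }
    acc
  })
  p <- (n_ge + 1) / (n_sims + 1)
  structure(list(observed_stat = unname(d_obs), p_value = p,
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "sector_mc_result")
}

#' @export
print.sector_mc_result <- function(x, ...) {
  cat(sprintf("<sector_mc_result> D = %.4g, p = %.4f (%d replicates)\n",
              x$observed_stat, x$p_value, x$n_sims))
  invisible(x)
}

#' Hewitt's test on a sector aggregate
#'
#' Applies [hewitt_test()] to the 12 aggregate mean ratios.
#'
#' @param agg a [aggregate_sector()] result.
#' @inheritParams hewitt_pvalue
#' @return A `hewitt_result`.
#' @export
hewitt_on_aggregate <- function(agg, method = c("montecarlo", "exact"),
                                n_sims = 1e6, seed = 1L) {
  stopifnot(inherits(agg, "sector_aggregate"))
  hewitt_test(agg$aggregate, method = method, n_sims = n_sims, seed = seed)
}

#' Half-split consistency of a sector's seasonality
#'
#' Splits every site's record into halves ([half_split()]), rebuilds
#' the sector aggregate and reruns the circular-shift Monte Carlo on
#' each half independently, and reports the circular distance between
#' the two halves' peak months. A genuine, stable seasonal signal
#' yields significant p-values in both halves with nearby peaks; sites
#' shorter than 24 months cannot be split and are excluded with a
#' warning.
#'
#' @param series_list list of [monthly_series()] in one sector.
#' @param n_sims,seed passed to [sector_mc_test()].
#' @return List of class `half_split_report`: `first`, `second` (each
#'   a `sector_aggregate`), `mc_first`, `mc_second`, `peak_distance`
#'   (0..6 months), `n_sites_used`, `excluded`.
#' @export
half_split_sector <- function(series_list, n_sims = 10000, seed = 1L) {
  if (inherits(series_list, "monthly_series"))
    series_list <- list(series_list)
  ok <- vapply(series_list, function(s) length(s$counts) >= 24, TRUE)
  if (any(!ok)) {
    excluded <- unname(vapply(series_list[!ok], `[[`, "", "site_id"))
    warning(sprintf("excluding %d site(s) shorter than 24 months from the half-split: %s",
                    sum(!ok), paste(excluded, collapse = ", ")),
            call. = FALSE)
  } else excluded <- character(0)
  series_list <- series_list[ok]
  if (!length(series_list))
    stop("no site is long enough to half-split", call. = FALSE)
  halves <- lapply(series_list, half_split)
  firsts <- lapply(halves, `[[`, "first")
  seconds <- lapply(halves, `[[`, "second")
  agg1 <- aggregate_sector(firsts)
  agg2 <- aggregate_sector(seconds)
  mc1 <- sector_mc_test(firsts, n_sims = n_sims, seed = seed)
  mc2 <- sector_mc_test(seconds, n_sims = n_sims, seed = seed + 1L)
  d <- abs(agg1$peak_month - agg2$peak_month)
  structure(list(first = agg1, second = agg2,
                 mc_first = mc1, mc_second = mc2,
                 peak_distance = min(d, 12 - d),
                 n_sites_used = length(series_list),
                 excluded = excluded),
            class = "half_split_report")
}
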