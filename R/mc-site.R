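#' Largest monthly-mean difference
#'
#' The seasonal-range statistic: the highest of the 12 climatological
#' monthly means minus the lowest. Zero for a flat climatology; under a
#' pure seasonal cycle of relative amplitude `A` on baseline `b` it
#' approaches `2Ab`.
#'
#' @param clim a [climatology()].
#' @return Non-negative scalar `D`, in cases/month.
#' @export
climatology_range <- function(clim) {
  stopifnot(inherits(clim, "climatology"))
  max(clim$means) - min(clim$means)
}

#' Per-site Monte Carlo seasonality test
#'
#' Tests whether the observed largest monthly-mean difference `D` could
#' arise from random scatter of the site's cases over its record. Each
#' replicate reassigns every case independently and uniformly at random
#' to one of the record's month slots (all `L` months of the span, so
#' calendar months appearing more often in the span receive
#' proportionally more mass), recomputes the 12 monthly means exactly
#' as for the observed data, and takes `D_sim = max - min`. The
#' p-value is the add-one rank
#' `p = (#\{D_sim >= D_obs\} + 1) / (n_sims + 1)`, which can never be
#' zero: with 10,000 replicates the floor is `1/10001`, printed as
#' 0.0001.
#'
#' @param series a [monthly_series()] of counts covering every calendar
#'   month, with at least one case.
#' @param n_sims number of Monte Carlo replicates (default 10,000).
#' @param seed integer seed.
#' @param on_detrended if `TRUE`, both the observed statistic and every
#'   replicate are computed on the quadratic-detrended ratio series
#'   rather than on raw counts. The default `FALSE` matches testing the
#'   cases directly.
#' @return List of class `mc_result`: `observed_stat`, `p_value`
#'   (also rounded to 4 decimals as `p_printed`), `n_sims`, `seed`.
#' @export
#' @examples
#' s <- simulate_site(site_spec("x", amplitude = 0.5, trend_coeffs = c(50, 0, 0),
#'                              n_months = 120, seed = 9))
#' site_mc_test(s, n_sims = 2000, seed = 1)
site_mc_test <- function(series, n_sims = 10000, seed = 1L,
                         on_detrended = FALSE) {
  stopifnot(inherits(series, "monthly_series"))
  if (n_sims < 1) stop("'n_sims' must be at least 1", call. = FALSE)
  total <- sum(series$counts)
  if (total < 1) stop("series holds no cases to reassign", call. = FALSE)
  if (any(series$counts != round(series$counts)))
    stop("the case-reassignment test needs integer counts", call. = FALSE)
  L <- length(series$counts)
  m <- month_of(series)
  occ <- tabulate(m, nbins = 12L)
  if (any(occ == 0L))
    stop("span must cover all 12 calendar months", call. = FALSE)

  stat_of <- function(counts_mat) {
    # counts_mat: L x k matrix of (possibly detrended) monthly values
    mon <- rowsum(counts_mat, group = m, reorder = TRUE) / occ
    apply(mon, 2, max) - apply(mon, 2, min)
  }
  prep <- if (on_detrended) {
    tt <- seq_len(L) - 1
    X <- cbind(1, tt, tt^2)
    H <- X %*% solve(crossprod(X), t(X))
    function(cm) {
      fit <- H %*% cm
      eps <- 1e-6 * (total / L)
      if (any(fit <= eps))
        stop("degenerate trend fit in a Monte Carlo replicate", call. = FALSE)
      cm / fit
    }
  } else identity

  d_obs <- stat_of(prep(matrix(series$counts, ncol = 1)))
  n_ge <- withr::with_seed(as.integer(seed), {
    chunk <- 2000L
    acc <- 0L
    done <- 0L
    while (done < n_sims) {
      k <- min(chunk, n_sims - done)
      sims <- rmultinom(k, size = total, prob = rep(1 / L, L))
      acc <- acc + sum(stat_of(prep(sims)) >= d_obs)
      done <- done + k
    }
    acc
  })
  p <- (n_ge + 1) / (n_sims + 1)
  structure(list(observed_stat = unname(d_obs), p_value = p,
                 p_printed = round(p, 4), n_sims = as.integer(n_sims),
                 seed = as.integer(seed), site_id = series$site_id),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> site %s: D = %.4g, p = %.4f (%d replicates)\n",
              x$site_id, x$observed_stat, x$p_value, x$n_sims))
  invisible(x)
}

#' Split a series into two halves at a month boundary
#'
#' Used for the temporal-consistency check: the first `ceiling(n/2)`
#' months and the remainder, each re-testable independently.
#'
#' @param series a [monthly_series()] spanning at least 24 months.
#' @return List of two [monthly_series()], `first` and `second`.
#' @export
half_split <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  n <- length(series$counts)
  if (n < 24)
    stop("need at least 24 months to split into testable halves",
         call. = FALSE)
  cut <- ceiling(n / 2)
  list(first = series_window(series, 1L, cut),
       second = series_window(series, cut + 1L, n))
}
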