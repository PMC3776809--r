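#' Rank the 12 monthly means
#'
#' Ascending integer ranks 1..12 (1 = lowest mean). Ties are broken
#' deterministically in favour of the earlier calendar month, which
#' keeps the rank vector a true permutation so the tabulated null of
#' the rank-sum statistic remains valid; ties have probability zero for
#' continuous means and are rare in practice.
#'
#' @param means numeric vector of 12 monthly values (January first).
#' @return Integer permutation of 1..12.
#' @export
rank_months <- function(means) {
  if (length(means) != 12)
    stop("'means' must hold exactly 12 monthly values", call. = FALSE)
  as.integer(rank(means, ties.method = "first"))
}

#' Maximum circular 6-month rank sum
#'
#' Hewitt's seasonality statistic: over the 12 windows of 6 consecutive
#' calendar months (circular, December wraps to January), the largest
#' sum of the monthly ranks. Ranges over 40..57 for any permutation of
#' 1..12 — 57 when ranks 7..12 are consecutive, and never below 40
#' (window sums average 39, and equality of all windows would force
#' `rank[i] = rank[i+6]`, impossible for a permutation). A large value
#' means the six highest-ranked months are concentrated in one half of
#' the year.
#'
#' @param ranks integer permutation of 1..12 from [rank_months()].
#' @return List: `T` (the statistic), `window_start` (first month of
#'   the maximizing window; smallest start wins ties), `window_sums`
#'   (all 12 circular window sums).
#' @export
#' @examples
#' max_rank_sum(rank_months(c(8, 9, 10, 7, 5, 3, 1, 2, 4, 6, 11, 12)))
max_rank_sum <- function(ranks) {
  if (length(ranks) != 12 || !setequal(ranks, 1:12))
    stop("'ranks' must be a permutation of 1..12", call. = FALSE)
  w <- vapply(1:12, function(k) sum(ranks[((k - 1 + 0:5) %% 12) + 1]), 0)
  list(T = as.integer(max(w)), window_start = which.max(w),
       window_sums = as.integer(w))
}

# vectorized null sampler: n_sims random permutations of 1..12,
# returning each one's maximum circular 6-window rank sum
hewitt_null_sample <- function(n_sims, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    chunk <- 200000L
    out <- integer(0)
    done <- 0L
    while (done < n_sims) {
      k <- as.integer(min(chunk, n_sims - done))
      X <- matrix(runif(k * 12L), k, 12L)
      R <- matrix(0L, k, 12L)
      for (j in 1:12) for (l in 1:12) R[, j] <- R[, j] + (X[, l] <= X[, j])
      W <- matrix(0L, k, 12L)
      W[, 1] <- rowSums(R[, 1:6])
      for (kk in 1:11)
        W[, kk + 1] <- W[, kk] - R[, kk] + R[, (kk + 5L) %% 12L + 1L]
      out <- c(out, do.call(pmax, as.data.frame(W)))
      done <- done + k
    }
    out
  })
}

# exact tail distribution of the statistic, by complete enumeration of
# the 11! rotation-class representatives (compiled); cached per session
hewitt_exact_dist <- function() {
  if (is.null(.kdseason_cache$hewitt_exact)) {
    counts <- hewitt_exact_counts()        # T = 40..57 over 11! perms
    .kdseason_cache$hewitt_exact <-
      data.frame(T = 40:57, prob = counts / factorial(11))
  }
  .kdseason_cache$hewitt_exact
}

#' Null p-value of Hewitt's statistic
#'
#' `P(T_null >= T)` for a uniformly random permutation of the 12 ranks.
#' `method = "montecarlo"` (default) samples permutations and applies
#' the add-one correction; `method = "exact"` enumerates the null
#' completely, exploiting rotational symmetry of the statistic (value
#' 12 is pinned to January, leaving the 11! distinguishable
#' arrangements) via compiled code, and caches the distribution for the
#' session.
#'
#' @param T observed statistic, an integer in 40..57.
#' @param method `"montecarlo"` or `"exact"`.
#' @param n_sims Monte Carlo sample size (default 1e6).
#' @param seed integer seed (Monte Carlo only).
#' @return The p-value. `p = 1` at `T = 40` since every permutation
#'   attains at least 40.
#' @export
#' @examples
#' hewitt_pvalue(56, method = "exact")   # ~0.025
hewitt_pvalue <- function(T, method = c("montecarlo", "exact"),
                          n_sims = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (length(T) != 1 || T != round(T) || T < 40 || T > 57)
    stop("'T' must be a single integer in 40..57", call. = FALSE)
  if (method == "exact") {
    d <- hewitt_exact_dist()
    sum(d$prob[d$T >= T])
  } else {
    sims <- hewitt_null_sample(n_sims, seed)
    (sum(sims >= T) + 1) / (n_sims + 1)
  }
}

#' Full Hewitt null table
#'
#' Tail probabilities `P(T_null >= T)` for every attainable `T`.
#'
#' @inheritParams hewitt_pvalue
#' @return Data frame with columns `T` (40..57) and `p`.
#' @export
hewitt_null_table <- function(method = c("montecarlo", "exact"),
                              n_sims = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (method == "exact") {
    d <- hewitt_exact_dist()
    data.frame(T = d$T, p = rev(cumsum(rev(d$prob))))
  } else {
    sims <- hewitt_null_sample(n_sims, seed)
    data.frame(T = 40:57,
               p = vapply(40:57,
                          function(t) (sum(sims >= t) + 1) / (n_sims + 1), 0))
  }
}

#' Hewitt's seasonality test on 12 monthly means
#'
#' Ranks the means, computes the maximum circular 6-month rank sum and
#' its null p-value. A perfectly flat input is ranked by the
#' deterministic tie rule (January lowest), which yields the degenerate
#' maximum `T = 57`; a warning marks that verdict unreliable.
#'
#' @param means 12 monthly values (January first).
#' @inheritParams hewitt_pvalue
#' @return List of class `hewitt_result`: `ranks`, `T`, `window_start`,
#'   `p_value`, `method`, `degenerate`.
#' @export
hewitt_test <- function(means, method = c("montecarlo", "exact"),
                        n_sims = 1e6, seed = 1L) {
  method <- match.arg(method)
  degenerate <- length(unique(means)) < 12
  if (all(means == means[1]))
    warning("flat monthly means: Hewitt ranks fall back to month order; verdict unreliable",
            call. = FALSE)
  r <- rank_months(means)
  ms <- max_rank_sum(r)
  p <- hewitt_pvalue(ms$T, method = method, n_sims = n_sims, seed = seed)
  structure(list(ranks = r, T = ms$T, window_start = ms$window_start,
                 p_value = p, method = method, degenerate = degenerate),
            class = "hewitt_result")
}

#' @export
print.hewitt_result <- function(x, ...) {
  cat(sprintf("<hewitt_result> T = %d (window starting %s), p = %.4g [%s]%s\n",
              x$T, month.abb[x$window_start], x$p_value, x$method,
              if (x$degenerate) "  (ties present)" else ""))
  invisible(x)
}
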