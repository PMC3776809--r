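#' Candidate ARMA model grid
#'
#' All combinations of non-seasonal orders `(p, q)` up to `max_order`
#' and seasonal orders `(P, Q)` at period 12 up to `seasonal_max_order`.
#' A candidate is "seasonal" when `P + Q >= 1`. With the default bounds
#' of 2 this is 81 candidates, 9 of them non-seasonal.
#'
#' @param max_order maximum non-seasonal AR and MA order.
#' @param seasonal_max_order maximum seasonal AR and MA order.
#' @return Data frame with columns `p, q, P, Q, seasonal`.
#' @export
arma_grid <- function(max_order = 2, seasonal_max_order = 2) {
  g <- expand.grid(p = 0:max_order, q = 0:max_order,
                   P = 0:seasonal_max_order, Q = 0:seasonal_max_order)
  g$seasonal <- (g$P + g$Q) >= 1
  g
}

#' Fit the candidate ARMA models to a preprocessed series
#'
#' Fits every candidate in [arma_grid()] to the (detrended) monthly
#' values by maximum likelihood with a fitted mean, seasonal period 12
#' and no differencing (the trend is assumed already removed).
#' Candidates whose optimisation errors or triggers a convergence
#' warning are flagged `converged = FALSE` and are excluded from model
#' selection rather than being treated as infinitely bad.
#'
#' @param values numeric vector of monthly values, or a
#'   [monthly_series()]; at least 36 months (three seasonal cycles are
#'   needed to identify period-12 terms).
#' @param max_order,seasonal_max_order grid bounds, see [arma_grid()].
#' @return Data frame of class `arma_fits`: columns
#'   `p, q, P, Q, seasonal, aic, converged`.
#' @export
fit_arma_candidates <- function(values, max_order = 2,
                                seasonal_max_order = 2) {
  if (inherits(values, "monthly_series")) values <- values$counts
  values <- as.numeric(values)
  if (length(values) < 36)
    stop("need at least 36 months to fit seasonal ARMA candidates",
         call. = FALSE)
  g <- arma_grid(max_order, seasonal_max_order)
  g$aic <- NA_real_
  g$converged <- FALSE
  for (i in seq_len(nrow(g))) {
    ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(
        arima(values, order = c(g$p[i], 0, g$q[i]),
              seasonal = list(order = c(g$P[i], 0, g$Q[i]), period = 12),
              include.mean = TRUE, method = "ML"),
        error = function(e) NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (!is.null(fit) && ok && is.finite(fit$aic)) {
      g$aic[i] <- fit$aic
      g$converged[i] <- TRUE
    }
  }
  class(g) <- c("arma_fits", "data.frame")
  g
}

#' Classify seasonality from best seasonal and non-seasonal AIC
#'
#' The evidence for seasonality is the AIC relative likelihood
#' `RL = exp((AIC_nonseasonal - AIC_seasonal) / 2)`, the factor by which
#' the best seasonal model is more likely to be the better description
#' than the best non-seasonal one. Categories:
#'
#' * `SS` strongly seasonal: `RL > 5`
#' * `S` seasonal: `2 < RL <= 5`
#' * `I` indeterminate: `1/2 <= RL <= 2`
#' * `N` non-seasonal: `1/5 <= RL < 1/2`
#' * `NN` strongly non-seasonal: `RL < 1/5`
#'
#' Boundary values resolve toward the weaker claim (RL exactly 5 is
#' `S`, exactly 2 or 1/2 is `I`, exactly 1/5 is `N`).
#'
#' @param aic_seasonal AIC of the best converged seasonal candidate.
#' @param aic_nonseasonal AIC of the best converged non-seasonal
#'   candidate.
#' @return List of class `arma_verdict`: `category`,
#'   `relative_likelihood`, `aic_seasonal`, `aic_nonseasonal`.
#' @export
#' @examples
#' classify_seasonality(100, 104)$category     # "SS" (RL = e^2)
#' classify_seasonality(100, 100)$category     # "I"
classify_seasonality <- function(aic_seasonal, aic_nonseasonal) {
  if (!is.finite(aic_seasonal) || !is.finite(aic_nonseasonal))
    stop("both AIC values must be finite", call. = FALSE)
  rl <- exp((aic_nonseasonal - aic_seasonal) / 2)
  # values within floating-point noise of a boundary count as the
  # boundary, so ties resolve toward the weaker claim deterministically
  gt <- function(a, b) a > b * (1 + 1e-9)
  category <-
    if (gt(rl, 5)) "SS"
    else if (gt(rl, 2)) "S"
    else if (!gt(0.5, rl)) "I"
    else if (!gt(0.2, rl)) "N"
    else "NN"
  structure(list(category = category, relative_likelihood = rl,
                 aic_seasonal = aic_seasonal,
                 aic_nonseasonal = aic_nonseasonal),
            class = "arma_verdict")
}

#' @export
print.arma_verdict <- function(x, ...) {
  cat(sprintf("<arma_verdict> %s  (relative likelihood %.3g; AIC seasonal %.2f vs non-seasonal %.2f)\n",
              x$category, x$relative_likelihood, x$aic_seasonal,
              x$aic_nonseasonal))
  invisible(x)
}

#' Seasonal vs non-seasonal ARMA comparison for one series
#'
#' Fits the full candidate grid, selects the best converged seasonal
#' and non-seasonal models by AIC, and classifies with
#' [classify_seasonality()].
#'
#' @inheritParams fit_arma_candidates
#' @return An `arma_verdict` with the two best fits attached as
#'   `best_seasonal` and `best_nonseasonal` (rows of the fit table).
#' @export
arma_seasonality_test <- function(values, max_order = 2,
                                  seasonal_max_order = 2) {
  fits <- fit_arma_candidates(values, max_order, seasonal_max_order)
  pick <- function(sub, label) {
    sub <- sub[sub$converged, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("class unfit: no %s candidate converged", label),
           call. = FALSE)
    sub[which.min(sub$aic), , drop = FALSE]
  }
  bs <- pick(fits[fits$seasonal, ], "seasonal")
  bn <- pick(fits[!fits$seasonal, ], "non-seasonal")
  out <- classify_seasonality(bs$aic, bn$aic)
  out$best_seasonal <- bs
  out$best_nonseasonal <- bn
  out$fits <- fits
  out
}
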