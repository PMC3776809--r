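#' Autocovariance spectrum of a preprocessed series
#'
#' Estimates the power spectrum as the Fourier transform of the sample
#' autocovariance — numerically, the periodogram (Wiener–Khinchin) —
#' lightly smoothed with a modified Daniell kernel, and attaches
#' significance thresholds. The null background is the theoretical
#' spectrum of the best-fit lag-1 autoregressive ("red noise") process
#' with matched variance, the standard null for geophysical and
#' epidemiological monthly series: it is conservative against residual
#' low-frequency structure surviving the detrending. Thresholds at each
#' frequency are `background * qchisq(tier, edof) / edof`, with the
#' equivalent degrees of freedom `edof = 2 / sum(kernel^2)` implied by
#' the smoothing kernel.
#'
#' @param values numeric vector of monthly values (mean is removed
#'   internally), or a [monthly_series()]; at least 48 months.
#' @param smooth_span width of the modified Daniell smoother (odd,
#'   `>= 1`; 1 disables smoothing). The default 3 gives edof ~ 5.3, a
#'   reasonable variance/leakage balance for 10–40 year records.
#' @param background `"ar1"` (red noise, default) or `"white"`.
#' @return An object of class `kd_spectrum`: `freq` (cycles/month, the
#'   positive Fourier grid), `power` (smoothed density), `raw_power`
#'   (unsmoothed periodogram density; satisfies Parseval's identity
#'   `sum(raw_power) / n = var`), `background`, `thresholds` (matrix
#'   with columns `"90" "95" "99"`), `edof`, `rho` (fitted lag-1
#'   autocorrelation), `n`.
#' @export
estimate_spectrum <- function(values, smooth_span = 3,
                              background = c("ar1", "white")) {
  background <- match.arg(background)
  if (inherits(values, "monthly_series")) values <- values$counts
  x <- as.numeric(values)
  n <- length(x)
  if (n < 48)
    stop("need at least 48 months for spectral analysis", call. = FALSE)
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) stop("constant series has no spectrum", call. = FALSE)

  # two-sided periodogram on the full Fourier grid j = 1..n-1, so the
  # Daniell smoother can wrap circularly as in spec.pgram
  per_full <- Mod(fft(x))^2 / n^2            # includes j = 0 term (= 0)
  per_full <- per_full[-1]                   # drop mean frequency
  if (smooth_span > 1) {
    m <- (smooth_span - 1) %/% 2
    kern <- kernel("modified.daniell", m)
    sm_full <- kernapply(per_full, kern, circular = TRUE)
    edof <- 2 / sum(kern[-kern$m:kern$m]^2)
  } else {
    sm_full <- per_full
    edof <- 2
  }
  half <- seq_len(n %/% 2)
  freq <- half / n
  # density scaling: sum(raw_power)/n equals the biased sample variance
  raw_power <- n * per_full[half] * ifelse(half < n / 2, 2, 1)
  power <- n * sm_full[half] * ifelse(half < n / 2, 2, 1)

  rho <- if (background == "ar1")
    max(0, acf(x, lag.max = 1, plot = FALSE)$acf[2]) else 0
  shape <- (1 - rho^2) / (1 - 2 * rho * cos(2 * pi * freq) + rho^2)
  bg <- shape * v * n / sum(shape)           # matched total variance
  tiers <- c(0.90, 0.95, 0.99)
  thresholds <- outer(bg, qchisq(tiers, edof) / edof)
  colnames(thresholds) <- c("90", "95", "99")

  structure(list(freq = freq, power = power, raw_power = raw_power,
                 background = bg, thresholds = thresholds,
                 edof = edof, rho = rho, n = n,
                 background_model = background),
            class = "kd_spectrum")
}

#' Grade annual / semiannual spectral peaks
#'
#' Looks up the smoothed power at the Fourier frequencies nearest the
#' annual (1/12 cycles/month) and semiannual (1/6) frequencies and
#' reports the highest significance tier (99, 95 or 90 percent)
#' exceeded at either; a significant peak at either frequency is taken
#' to indicate seasonal structure. When both frequencies qualify at the
#' awarded tier the annual peak takes precedence.
#'
#' @param spectrum a `kd_spectrum` from [estimate_spectrum()].
#' @return List of class `spectral_verdict`: `tier` (`"99"`, `"95"`,
#'   `"90"` or `"none"`), `peak_frequency` (`"annual"`, `"semiannual"`
#'   or `"none"`), plus the inspected powers and thresholds.
#' @export
seasonal_peak_test <- function(spectrum) {
  stopifnot(inherits(spectrum, "kd_spectrum"))
  bin <- function(f0) which.min(abs(spectrum$freq - f0))
  bins <- c(annual = bin(1 / 12), semiannual = bin(1 / 6))
  pow <- spectrum$power[bins]
  thr <- spectrum$thresholds[bins, , drop = FALSE]
  tier_of <- function(i) {
    if (pow[i] > thr[i, "99"]) 99L
    else if (pow[i] > thr[i, "95"]) 95L
    else if (pow[i] > thr[i, "90"]) 90L
    else 0L
  }
  tiers <- vapply(1:2, tier_of, 0L)
  best <- max(tiers)
  if (best == 0L) {
    tier <- "none"; peak <- "none"
  } else {
    tier <- as.character(best)
    peak <- if (tiers[1] == best) "annual" else "semiannual"
  }
  structure(list(tier = tier, peak_frequency = peak,
                 power_annual = unname(pow[1]),
                 power_semiannual = unname(pow[2]),
                 thresholds_annual = thr[1, ],
                 thresholds_semiannual = thr[2, ]),
            class = "spectral_verdict")
}

#' @export
print.spectral_verdict <- function(x, ...) {
  cat(sprintf("<spectral_verdict> tier %s at %s frequency (annual power %.3g, semiannual %.3g)\n",
              x$tier, x$peak_frequency, x$power_annual, x$power_semiannual))
  invisible(x)
}

#' One-call spectral seasonality test
#'
#' Convenience wrapper: [estimate_spectrum()] then
#' [seasonal_peak_test()].
#'
#' @inheritParams estimate_spectrum
#' @return A `spectral_verdict`.
#' @export
spectral_seasonality_test <- function(values, smooth_span = 3,
                                      background = c("ar1", "white")) {
  seasonal_peak_test(estimate_spectrum(values, smooth_span, background))
}
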