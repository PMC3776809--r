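---
title: "Methods: seasonality testing for multi-site surveillance counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonality testing for multi-site surveillance counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods in `kdseason`, the
assumptions behind them, and the reasoning for every default that a
user might want to change. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The data model and preprocessing

The unit of analysis is a site's monthly case-count series. Real
surveillance records of a rare disease such as Kawasaki disease have
three awkward features that the preprocessing addresses in order:

* **Tiny sites.** A record with fewer than 30 total cases cannot yield
  a stable 12-month climatology (fewer than 2.5 cases per calendar
  month on average), so `filter_min_cases()` drops it. The threshold is
  a tunable (`min_cases`, default 30 cases).
* **Ramp-up years.** Newly established records open with years of
  near-zero reporting. `trim_low_years()` removes whole leading
  calendar years with fewer than `trim_primary = 24` cases, stopping at
  the first compliant year; if that would discard the entire record the
  rule is relaxed to `trim_fallback = 12` so genuinely small sites
  remain analysable. Two readings of "observations per year" are
  possible — reported cases, or months with any data — and the package
  reads it as *cases*: only that reading makes a fallback of 12 per
  year meaningful for small sites whose every month has data. Interior
  sparse years are never removed; trimming is strictly a leading-run
  rule, so one bad year in the middle of a good record cannot amputate
  its start.
* **Trends and heteroscedasticity.** Case ascertainment grows (or
  decays) over years, and Poisson-like counts carry variance
  proportional to the mean. `detrend_series()` fits the least-squares
  quadratic in the month index and *divides* by the fitted values.
  Division both removes the trend and roughly stabilises the variance
  of the ratio series. Zero-count months stay in the series as ratio 0
  — a true zero in January is seasonal signal, not a missing value. A
  fitted value at or below `1e-6` times the overall mean aborts with a
  "degenerate trend fit" error rather than produce explosive ratios.

The 12-month climatology (`climatology()`) is the mean count per
calendar month over all its occurrences in the span; occurrences are
counted per month because spans need not be whole years. Dividing by
the overall monthly mean (`normalize_climatology()`) gives a
dimensionless curve around 1 in which a 300-case site and a
271,000-case site are directly comparable. Two exact identities are
maintained and tested: occurrence-weighted monthly means sum to the
total count, and the occurrence-weighted mean of the normalized ratios
is exactly 1.

Preprocessing order matters and is deliberately asymmetric: the ARMA
and spectral tests run on the trimmed, detrended series (they model
autocorrelation structure, which trends corrupt), while the
case-reassignment Monte Carlo and the sector climatologies use the raw
filtered counts — the reassignment null conditions on the record's
actual exposure, and trimming is a model-fitting remedy, not part of
that null. A config flag (`on_detrended`) runs the site Monte Carlo on
detrended values for sensitivity analysis.

## 2. Per-site tests

### ARMA model comparison

`arma_seasonality_test()` fits all ARMA(p,q)×(P,Q)₁₂ candidates with
p, q, P, Q ≤ 2 by maximum likelihood (`stats::arima`, mean included, no
differencing — the trend is already gone). "Seasonal" means P + Q ≥ 1;
the non-seasonal class is the same grid with P = Q = 0 (9 of the 81
candidates). Candidates that fail to converge are flagged and excluded
from selection, never silently assigned infinite AIC. The evidence
measure is the AIC relative likelihood `RL = exp((AICₙ − AICₛ)/2)` — the
standard Akaike evidence ratio, which is the natural formalisation of
"x times as likely to be correct". Categories: `SS` (RL > 5), `S`
(2 < RL ≤ 5), `I` (1/2 ≤ RL ≤ 2), `N` (1/5 ≤ RL < 1/2), `NN`
(RL < 1/5). Boundary values resolve toward the weaker claim, and values
within a relative `1e-9` of a boundary are treated as the boundary so
the tie rule does not depend on floating-point accidents. The whole
classification depends only on the AIC *difference*, which the test
suite checks by translation invariance and by the antisymmetry
SS↔NN / S↔N under swapping the two AICs.

Whether to include an intercept and which estimator to use are not
forced by the method's definition; the package fixes ML-with-mean and
documents it, and nothing downstream depends on per-site categories
matching any particular historical analysis.

### Spectral peak significance

`estimate_spectrum()` computes the periodogram — numerically identical
to the Fourier transform of the sample autocovariance — on the
demeaned, detrended series, smooths it with a modified Daniell kernel
(`smooth_span = 3`, i.e. weights ¼,½,¼, equivalent degrees of freedom
≈ 5.3; span 1 disables smoothing), and scales it so the unsmoothed
spectrum satisfies Parseval's identity exactly: `sum(raw_power)/n`
equals the biased sample variance. The significance background is the
theoretical spectrum of an AR(1) ("red noise") process at the fitted
lag-1 autocorrelation with matched total variance; red noise is the
standard null for geophysical and epidemiological monthly series and is
conservative against low-frequency structure that survives detrending.
A white-noise background is available (`background = "white"`) and is
what the calibration tests use, since there the nominal tier levels are
exact targets. Thresholds are `background × qchisq(tier, edof)/edof`
at the 90/95/99% tiers.

`seasonal_peak_test()` inspects only the Fourier bins nearest 1/12 and
1/6 cycles/month (nearest-bin matching, no interpolation — sub-bin
precision would be invented, not measured) and awards the highest tier
exceeded at either; the annual frequency takes precedence when both
qualify. The verdict is scale-invariant by construction.

### Case-reassignment Monte Carlo

`site_mc_test()` is the only per-site test that works on cases rather
than on a fitted model. The statistic is `D = max − min` of the 12
climatological monthly means. Under the null, each of the record's `N`
cases is equally likely to have occurred in any of the span's `L`
months; a replicate draws all `N` cases uniformly over the `L`
month-slots (a multinomial draw), recomputes the monthly means through
the identical pipeline, and records `D_sim`. Reassignment is uniform
over month-*slots*, not over the 12 calendar-month labels: when a span
covers some calendar months more often than others, slots preserve that
exposure imbalance, which the observed statistic is also subject to.
The p-value uses the add-one convention `(#{D_sim ≥ D_obs}+1)/(n_sims+1)`,
whose floor at the default `n_sims = 10000` is `1/10001`, printed as
0.0001 — a Monte Carlo p-value of exactly 0 is never reported. The
test's null calibration (rejection at 5% ± binomial error under a
flat-seasonality generator) is verified at 1000 replicates in the
acceptance suite.

`half_split()` cuts a record into its first `⌈n/2⌉` months and the
remainder at a month boundary, so temporal consistency of a seasonal
signal can be checked by re-testing each half independently.

## 3. Hewitt's test and the sector stage

### Hewitt's circular rank-sum statistic

Rank the 12 monthly values 1 (lowest) to 12 (highest); `T` is the
maximum, over the 12 *circular* windows of 6 consecutive months, of the
window's rank sum. `T` ranges 40–57: 57 iff ranks 7–12 occupy six
consecutive positions, and 40 is the sharp lower bound (window sums
average 39, and all windows equal would force `rank[i] = rank[i+6]`).
Windows must wrap the year boundary: a November–April winter peak is
exactly the case of interest, and the circular null reproduces the
published tail (`P(T ≥ 56) = 0.0253`); half-year windows without
wrap-around would roughly halve that tail and are not what the
tabulated values describe.

The null distribution is computed two ways, which the suite checks
against each other: sampled random permutations (default, `n_sims =
1e6`, add-one correction) and *exact enumeration* — the statistic is
rotation-invariant, so pinning rank 12 to one position leaves 11! ≈
4×10⁷ representatives, enumerated in compiled code in about a second
and cached for the session. Enumeration reproduces the analytic spot
value `P(T = 57) = 12·6!·6!/12! ≈ 0.01299` to machine precision.

Ties between monthly means are broken deterministically toward the
earlier calendar month (`ties.method = "first"`), keeping `T` integral
and the permutation null valid; midranks would break both. A perfectly
flat input therefore degenerates to ranks 1..12 in month order — and to
`T = 57` — so flat inputs trigger an explicit warning and a
`degenerate` flag rather than a silently confident verdict.

### Sector aggregation and the circular-shift Monte Carlo

`assign_sector()` stratifies at 23° latitude; the boundary itself is
assigned to the tropics ("poleward of 23°" read strictly).
`aggregate_sector()` averages normalized climatologies with equal
weight per site and reports the peak month, trough month and the
relative excess `(max − min)/min × 100` (%). For a common amplitude `A`
and common integer peak month across sites, the aggregate excess has
closed form `100·2A/(1 − A)` in the long-span limit — the acceptance
suite verifies convergence within 5% at 40-year spans.

`sector_mc_test()` asks whether the *phases* of the member sites align:
each replicate rotates every site's 12-month curve by an independent
uniform circular shift (the curve's shape is preserved exactly — only
its phase moves), averages across sites, and records the largest
difference between any two aggregate months, which for 12 values is
identically max − min. The add-one rank p-value follows. Two structural
properties are tested: the test is invariant under a common rotation
applied to all sites, and a single-site "sector" gives p = 1 by
rotation invariance — one site alone carries no cross-site phase
information. `half_split_sector()` repeats aggregation and testing on
each half of every record (sites shorter than 24 months are excluded
with a warning) and reports the circular distance between the two
halves' peak months.

## 4. The synthetic world

`simulate_site()` draws independent Poisson counts with intensity

λ(t) = r(t) · (c₀ + c₁t + c₂t²) · (1 + A·cos(2π(m(t) − φ)/12)),

multiplicative seasonality on a quadratic baseline with a linear
reporting ramp. Defaults and ranges are chosen to mirror the structure
of real multi-site KD surveillance: baselines log-uniform over tens to
hundreds of cases/month (record totals then span tens to tens of
thousands of cases, as in real consortium tables), spans 10–30 years,
amplitudes `A ∈ [0.2, 0.5]` (the hemispheric winter excess is of order
40%, i.e. A ≈ 0.2 at aggregate level, with individual sites stronger),
peak-month jitter ±1 month around a shared sector phase, and
`peak_jitter = 6` as the phase-null configuration. The multiplicative
cosine form is chosen over an additive one because the *normalized*
climatology is then analytically known — month m's expected ratio is
`1 + A·cos(2π(m − φ)/12)` regardless of baseline — which gives the
closed-form oracles used in testing. Noise is Poisson without
overdispersion in this version (the simplest model consistent with
count data; negative binomial is a noted extension), and the ramp is
linear-multiplicative, which reproduces zero-heavy openings without a
changepoint model. One master seed spawns per-site substreams by a
stable hash of the site id, so any subset of sites reproduces
byte-identically.

What a green test does *not* establish: the generator has no
overdispersion, no reporting gaps, no diagnostic drift, no spatial
correlation between sites, and its seasonality is a pure first
harmonic. Passing calibration and power suites means the tests behave
correctly *in this stated world*; it does not certify performance
against, e.g., epidemic-year outliers of the kind real KD records
contain.

## 5. Numerical choices and edge cases

* Monte Carlo p-values always use the add-one convention; exact
  enumeration reports the true tail probability without it.
* `classify_seasonality()` treats relative likelihoods within `1e-9`
  (relative) of a category boundary as *at* the boundary; ties resolve
  toward the weaker claim.
* The detrend guard is `fit ≤ 1e-6 × mean`; the spectral stage refuses
  series shorter than 48 months or with zero variance; ARMA fitting
  refuses fewer than 36 months (three seasonal cycles).
* Peak-recovery in the generator is inherently noisy: at 20
  occurrences per calendar month and A = 0.4, the peak month's
  climatological mean exceeds its neighbours' by roughly one standard
  error of the difference, so exact-month recovery runs near 75%, while
  ±1-month recovery exceeds 95%. Tests assert the attainable statement.
* Quadratic detrending cannot leave the output exactly orthogonal to
  the quadratic basis (the seasonal cycle projects weakly onto it);
  residual refit coefficients are ~3 orders of magnitude below the
  injected trend, which is what the suite asserts.
* Half-splits put the odd month in the first half (`⌈n/2⌉`).
* All randomised functions take explicit integer seeds and are
  byte-reproducible; `run_pipeline()` derives per-site and per-sector
  seeds from the master seed by stable hashing.

## 6. Known limitations

Seasonal differencing models, model averaging, multitaper or wavelet
spectra, unequal-exposure variants of the sector null, population
denominators (incidence rather than counts), and any spatial or
wind-pattern analysis are out of scope. The Hewitt machinery is
parameterised internally but only validated for 6-month windows over
12 periods. ARMA fitting at the full order-2 grid costs a few seconds
per site; large worlds should reduce the grid or parallelise outside
the package.
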