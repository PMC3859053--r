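#' Biased sample autocorrelation of a series
#'
#' Computes `r[k] = (1/N) * sum_{n=1..N-k} x[n] * x[n+k]` for lags
#' `k = 0..max_lag`, optionally after subtracting the sample mean and
#' optionally normalized by `r[0]`. The 1/N (biased) normalization is used
#' throughout: it keeps the normalized sequence bounded by 1 in magnitude at
#' every lag. High, slowly decaying autocorrelation is the signature of an
#' underlying autoregressive process; an (approximately) zero sequence beyond
#' lag 0 indicates white noise.
#'
#' @param x numeric series of length `N >= 2`.
#' @param max_lag largest lag, `max_lag < N`.
#' @param normalized divide by `r[0]`? Errors if `r[0] == 0`.
#' @param demean subtract the sample mean first?
#' @return An object of class `autocorrelation_series` with fields `lags`,
#'   `values`, `n`, `normalized`.
#' @export
autocorrelation <- function(x, max_lag = min(20L, length(x) - 1L),
                            normalized = FALSE, demean = FALSE) {
  n <- length(x)
  if (n < 2L) stop_param("series must have at least 2 points")
  if (max_lag >= n) stop_param("max_lag must be smaller than the series length")
  if (max_lag < 0) stop_param("max_lag must be non-negative")
  if (demean) x <- x - mean(x)
  vals <- vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
  if (normalized) {
    if (vals[1L] == 0) stop_data("degenerate signal: zero power, cannot normalize")
    vals <- vals / vals[1L]
  }
  structure(list(lags = 0:max_lag, values = vals, n = n,
                 normalized = normalized),
            class = "autocorrelation_series")
}

#' @export
print.autocorrelation_series <- function(x, ...) {
  cat(sprintf("<autocorrelation_series> N = %d, lags 0..%d%s\n", x$n,
              max(x$lags), if (x$normalized) " (normalized)" else ""))
  print(utils::head(data.frame(lag = x$lags, r = x$values), 10L))
  invisible(x)
}

#' Lagged value pairs of a series
#'
#' Returns the `(Y[i-lag], Y[i])` pairs that a lag plot displays. Tight
#' clustering of the pairs along the diagonal marks strong positive
#' autocorrelation (non-random structure); a shapeless cloud marks randomness.
#'
#' @param x numeric series.
#' @param lag fixed displacement in samples, `1 <= lag < length(x)`.
#' @return A data frame with columns `lagged` (`Y[i-lag]`) and `current`
#'   (`Y[i]`), in series order, `length(x) - lag` rows.
#' @export
lag_pairs <- function(x, lag = 1L) {
  n <- length(x)
  if (lag < 1 || lag >= n) stop_param("lag must satisfy 1 <= lag < length(x)")
  lag <- as.integer(lag)
  data.frame(lagged = x[seq_len(n - lag)], current = x[seq_len(n - lag) + lag])
}

#' Residual whiteness test
#'
#' Model-validation check: residuals of a well-specified model should be
#' white noise. The normalized (demeaned) autocorrelation at lags `1..L` is
#' compared against the approximate 95% confidence band `+/- 1.96/sqrt(N)`
#' for an i.i.d. series; the series is declared white when at most
#' `threshold` of the tested lags fall outside the band. For i.i.d. noise
#' about 5% of lags are expected outside, so the default 10% exceedance
#' budget passes white series with high probability while any real residual
#' structure pushes many lags out. A constant (zero-variance) series is
#' degenerate and reported not-white with `fraction_outside = 1`.
#'
#' @param x numeric series, `length(x) > lags_tested + 1`.
#' @param lags_tested number of lags `L` examined (default 20).
#' @param threshold maximum tolerated fraction of out-of-band lags.
#' @return An object of class `whiteness_report` with fields
#'   `band_halfwidth`, `fraction_outside`, `white` (logical verdict),
#'   `lags_tested`, `threshold`, `n`.
#' @export
whiteness_test <- function(x, lags_tested = 20L, threshold = 0.10) {
  n <- length(x)
  if (n <= lags_tested + 1L) stop_param("series too short for lags_tested")
  band <- 1.96 / sqrt(n)
  if (stats::sd(x) == 0) {
    frac <- 1
  } else {
    ac <- autocorrelation(x, max_lag = lags_tested, normalized = TRUE,
                          demean = TRUE)
    frac <- mean(abs(ac$values[-1L]) > band)
  }
  structure(list(band_halfwidth = band, fraction_outside = frac,
                 white = frac <= threshold, lags_tested = as.integer(lags_tested),
                 threshold = threshold, n = n),
            class = "whiteness_report")
}

#' @export
print.whiteness_report <- function(x, ...) {
  cat(sprintf(
    "<whiteness_report> N = %d, band +/-%.4f, %.0f%% of %d lags outside -> %s\n",
    x$n, x$band_halfwidth, 100 * x$fraction_outside, x$lags_tested,
    if (x$white) "white" else "not white"))
  invisible(x)
}
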