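# Shared correlation machinery for the regularity and coordination metrics.

# Raw cross-correlation sums for all lags via FFT convolution.
# Returns res with res[m + N] = sum_n x[n + m] * y[n] (lag m applied to x),
# m in -(N-1) .. (N-1).
raw_xcorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  stats::convolve(x, y, type = "open")
}

# Normalized cross-correlation over symmetric lags.
# r(m) = sum_n x[n+m] y[n] / sqrt(sum x^2 * sum y^2), sums over the
# overlapping samples only, so |r| <= 1 exactly (Cauchy-Schwarz).
norm_xcorr <- function(x, y, max_lag) {
  N <- length(x)
  max_lag <- min(max_lag, N - 1L)
  cc <- raw_xcorr(x, y)
  cx <- cumsum(x^2); cy <- cumsum(y^2)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(m) {
    num <- cc[m + N]
    if (m >= 0) { ex <- cx[N] - if (m) cx[m] else 0; ey <- cy[N - m] }
    else        { ex <- cx[N + m];                  ey <- cy[N] - cy[-m] }
    den <- sqrt(ex * ey)
    if (den <= 0) 0 else num / den
  }, numeric(1))
  list(lags = lags, r = r)
}

# Unbiased normalized autocorrelation at positive lags:
# r(m) = (sum x[n] x[n+m] / (N - m)) / (sum x^2 / N).
autocorr_unbiased <- function(x, lag_min, lag_max) {
  N <- length(x)
  lag_max <- min(lag_max, N - 1L)
  if (lag_min > lag_max) return(numeric(0))
  cc <- raw_xcorr(x, x)
  e0 <- cc[N] / N
  if (e0 <= 0) return(rep(0, lag_max - lag_min + 1L))
  m <- lag_min:lag_max
  (cc[m + N] / (N - m)) / e0
}

# Tukey (tapered cosine) window, cosine fraction r.
tukey_window <- function(n, r = 0.3) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t >= 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}
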