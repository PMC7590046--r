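#' Zero-phase Butterworth low-pass filter
#'
#' Filters each gyroscope axis with a second-order Butterworth low-pass
#' design applied forward and backward (zero phase shift, effective
#' fourth-order magnitude response). The default 3 Hz cutoff removes sensor
#' noise and tremor components while passing the 0.3--3 Hz arm-swing band.
#'
#' Ends are extended by odd reflection before filtering and trimmed
#' afterwards, so constant and slowly varying signals pass without the edge
#' transients of an unpadded forward-backward filter.
#'
#' @param rec a [gyro_recording()].
#' @param cutoff cutoff frequency, Hz. Must be below `fs / 2`.
#' @return A `gyro_recording` of the same length and rate with filtered axes.
#' @export
lowpass_filter <- function(rec, cutoff = 3) {
  stopifnot(inherits(rec, "gyro_recording"))
  if (rec$fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff frequency")
  n <- length(rec$t)
  bf <- signal::butter(2, cutoff / (rec$fs / 2), type = "low")
  # warm-up: need enough samples for the reflected padding to settle
  minlen <- 3L * (length(bf$a) + length(bf$b))
  if (n < minlen)
    stop(sprintf("recording too short for filtering: %d samples, need >= %d (filter warm-up)",
                 n, minlen))
  for (ax in c("omega_x", "omega_y", "omega_z"))
    rec[[ax]] <- zero_phase(bf, rec[[ax]], rec$fs, cutoff)
  rec
}

# forward-backward filtering with odd-reflection end padding
zero_phase <- function(bf, x, fs, cutoff) {
  n <- length(x)
  pad <- min(n - 1L, max(9L, ceiling(3 * fs / cutoff)))
  head_ext <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_ext, x, tail_ext))
  y[(pad + 1L):(pad + n)]
}

#' Project the transverse gyroscope axes onto the swing direction
#'
#' Principal component analysis of the mean-centred (x, y) angular-velocity
#' channels. The first principal direction is the swing direction; the
#' projection onto it is the scalar swing-direction angular velocity used by
#' everything downstream. The longitudinal z-axis is excluded entirely so
#' that turning (a rotation about the forearm axis) cannot contaminate the
#' swing signal, and the projection makes the result insensitive to how the
#' sensor is rotated about the forearm.
#'
#' The principal direction's sign is arbitrary; it is fixed so that the
#' loading of larger magnitude is positive (tie: x positive). Consequently
#' "forward"/"backward" swing labels are a consistent convention, not an
#' anatomical guarantee.
#'
#' @param rec a filtered [gyro_recording()].
#' @return An object of class `swing_axis_signal`: list with `omega_swing`
#'   (deg/s), `loadings` (unit 2-vector on x, y), `sign_fixed = TRUE`, `fs`,
#'   `t`, and `no_axis` (TRUE when x and y carry no variance, i.e. a
#'   motionless arm, in which case `omega_swing` is all zero).
#' @export
project_swing_axis <- function(rec) {
  stopifnot(inherits(rec, "gyro_recording"))
  x <- rec$omega_x - mean(rec$omega_x)
  y <- rec$omega_y - mean(rec$omega_y)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  cv <- matrix(c(sum(x * x), sum(x * y), sum(x * y), sum(y * y)) / (n - 1), 2)
  no_axis <- sum(diag(cv)) <= 0
  if (no_axis) {
    v <- c(1, 0)
    w <- numeric(n)
  } else {
    eg <- eigen(cv, symmetric = TRUE)
    v <- eg$vectors[, 1]
    # sign convention: larger-magnitude loading positive, tie -> x positive
    lead <- if (abs(v[1]) >= abs(v[2])) v[1] else v[2]
    if (lead < 0) v <- -v
    w <- x * v[1] + y * v[2]
  }
  structure(
    list(omega_swing = w, loadings = v, sign_fixed = TRUE,
         fs = rec$fs, t = rec$t, no_axis = no_axis),
    class = "swing_axis_signal")
}

#' @export
print.swing_axis_signal <- function(x, ...) {
  cat(sprintf("<swing_axis_signal> %d samples @ %g Hz, loadings (%.3f, %.3f)%s\n",
              length(x$omega_swing), x$fs, x$loadings[1], x$loadings[2],
              if (x$no_axis) " [no swing axis]" else ""))
  invisible(x)
}

#' Integrate the swing-direction angular velocity to a swing angle
#'
#' Cumulative trapezoidal integration of the swing-direction angular
#' velocity; the angle starts at exactly zero.
#'
#' @param sig a [project_swing_axis()] result.
#' @return An object of class `angle_signal`: list with `alpha` (deg, the
#'   integrated angle), `fs`, `t`, and empty `trend` / `alpha_detrend` slots
#'   filled by [detrend_angle()].
#' @export
integrate_angle <- function(sig) {
  stopifnot(inherits(sig, "swing_axis_signal"))
  w <- sig$omega_swing
  n <- length(w)
  dt <- 1 / sig$fs
  alpha <- c(0, cumsum((w[-1] + w[-n]) / 2) * dt)
  structure(
    list(alpha = alpha, trend = NULL, alpha_detrend = NULL,
         fs = sig$fs, t = sig$t, q = NULL),
    class = "angle_signal")
}

#' Weights of the symmetric moving-average trend
#'
#' Half-open weights: 1/(4q) at the two window ends (j = +/- q) and 1/(2q)
#' elsewhere, summing to exactly 1 for every q >= 1.
#'
#' @param q half-window length in samples.
#' @return Numeric weight vector of length `2q + 1`.
#' @export
detrend_weights <- function(q) {
  stopifnot(q >= 1)
  b <- rep(1 / (2 * q), 2 * q + 1)
  b[c(1, 2 * q + 1)] <- 1 / (4 * q)
  b
}

#' Remove integration drift from the swing angle
#'
#' Subtracts a symmetric moving average with a window of about one second
#' (`2q + 1` samples with `q = round(fs / 2)`, i.e. 1.005 s at 200 Hz) from
#' the integrated angle, removing the low-frequency drift that numerical
#' integration of a biased gyroscope accumulates. The end weights are halved
#' (see [detrend_weights()]) so the weights sum to one and a linear drift is
#' annihilated exactly on interior samples.
#'
#' Near the series ends, where the window would run off the data, the angle
#' is extended by edge-value replication so the trend and detrended angle
#' have full length; samples with index `q < n < N - q` (1-based: from
#' `q + 2` to `N - q`) are unaffected by the padding.
#'
#' @param angle an [integrate_angle()] result.
#' @param q half-window in samples; default `round(fs / 2)`.
#' @return The `angle_signal` with `trend` and `alpha_detrend` filled and
#'   `q` recorded.
#' @export
detrend_angle <- function(angle, q = NULL) {
  stopifnot(inherits(angle, "angle_signal"))
  if (is.null(q)) q <- round(angle$fs / 2)
  n <- length(angle$alpha)
  if (n <= 2 * q)
    stop(sprintf("bout too short to detrend: %d samples <= window 2q = %d", n, 2 * q))
  b <- detrend_weights(q)
  padded <- c(rep(angle$alpha[1], q), angle$alpha, rep(angle$alpha[n], q))
  trend <- stats::filter(padded, b, method = "convolution", sides = 2)
  trend <- as.numeric(trend[(q + 1):(q + n)])
  angle$trend <- trend
  angle$alpha_detrend <- angle$alpha - trend
  angle$q <- q
  angle
}

#' @export
print.angle_signal <- function(x, ...) {
  cat(sprintf("<angle_signal> %d samples @ %g Hz%s\n",
              length(x$alpha), x$fs,
              if (is.null(x$alpha_detrend)) " (not detrended)"
              else sprintf(", detrended (q = %d)", x$q)))
  invisible(x)
}
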