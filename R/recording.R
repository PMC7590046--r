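#' Construct a gyroscope recording
#'
#' Container for one arm's raw 3-axis angular velocity at a fixed sampling
#' rate. Axes follow the sensor's right-handed frame with the z-axis along
#' the longitudinal (forearm) axis; x and y span the transverse plane in
#' which the swinging motion is measured. Units are deg/s throughout; use
#' the `units` argument of [read_gyro_csv()] to convert rad/s input.
#'
#' @param t numeric vector of sample times in seconds, uniformly spaced.
#' @param omega_x,omega_y,omega_z angular velocity about the sensor axes,
#'   deg/s, same length as `t`.
#' @param fs sampling rate in Hz. If missing it is inferred from `t`.
#' @param side `"left"`, `"right"` or `NA`.
#' @param label free-text label.
#'
#' @return An object of class `gyro_recording`: a list with fields `t`,
#'   `omega_x`, `omega_y`, `omega_z`, `fs`, `side`, `label`.
#'
#' @details Sample spacing must be uniform to within a relative tolerance of
#'   1e-6 and `fs` must be at least 20 Hz so that the 3 Hz low-pass and the
#'   0.3--3 Hz analysis band are representable. Bouts shorter than 3 s (one
#'   spectral window) are rejected.
#' @export
gyro_recording <- function(t, omega_x, omega_y, omega_z, fs = NULL,
                           side = NA_character_, label = "") {
  n <- length(t)
  if (n < 2L) stop("a recording needs at least 2 samples")
  if (length(omega_x) != n || length(omega_y) != n || length(omega_z) != n)
    stop("t, omega_x, omega_y, omega_z must have equal length")
  if (any(!is.finite(t))) stop("non-finite sample times")
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 1e-6 * dt0))
    stop("non-uniform sampling (relative spacing deviates by more than 1e-6); ",
         "resample before analysis")
  if (is.null(fs)) fs <- 1 / dt0
  if (fs < 20) stop("sampling rate below 20 Hz cannot support the 0.3-3 Hz analysis band")
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left', 'right' or NA")
  structure(
    list(t = as.numeric(t),
         omega_x = as.numeric(omega_x), omega_y = as.numeric(omega_y),
         omega_z = as.numeric(omega_z),
         fs = as.numeric(fs), side = side, label = label),
    class = "gyro_recording")
}

#' @export
print.gyro_recording <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1]
  cat(sprintf("<gyro_recording> %s%s: %d samples, %.1f s @ %g Hz\n",
              ifelse(is.na(x$side), "", paste0(x$side, " arm ")),
              ifelse(nzchar(x$label), paste0("[", x$label, "]"), ""),
              length(x$t), dur, x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [gyro_recording()].
#' @return Duration spanned by the samples, seconds.
#' @export
rec_duration <- function(rec) rec$t[length(rec$t)] - rec$t[1]
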