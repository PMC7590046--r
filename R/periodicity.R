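#' Sliding-window spectral analysis of the detrended swing angle
#'
#' Slides 3-s rectangular windows (75% overlap, i.e. the start advances by a
#' quarter of the window) over the detrended angle. For each window the
#' discrete Fourier spectrum gives the dominant frequency (largest non-DC
#' magnitude up to Nyquist) and the fraction of non-DC spectral power lying
#' in the arm-swing band. A window is valid — i.e. contains periodic
#' movement in the arm-swing frequency domain — when at least `power_gate`
#' (default 90%) of its power is in-band and the dominant frequency itself
#' is in-band. A trailing remainder shorter than one window is dropped.
#'
#' With a 3-s rectangular window the frequency resolution is 1/3 Hz, so the
#' dominant frequency is always a multiple of 1/3 Hz; a 0.9 Hz swing reports
#' the nearest bin.
#'
#' @param angle a detrended [angle_signal][detrend_angle()].
#' @param band numeric length-2, the periodicity band in Hz (closed
#'   interval; bins on the edge count as in-band).
#' @param power_gate minimum in-band power fraction for a valid window.
#' @param window_s window duration, seconds.
#' @param overlap fractional overlap of consecutive windows.
#' @return A data frame of class `spectral_windows` with one row per window:
#'   `start_time`, `start_index`, `duration`, `dominant_freq`,
#'   `band_power_fraction`, `valid`. Attribute `n_samples` records the bout
#'   length for the sample-coverage mask. Empty (0-row) with a warning when
#'   the bout is shorter than one window.
#' @export
analyze_windows <- function(angle, band = c(0.3, 3), power_gate = 0.9,
                            window_s = 3, overlap = 0.75) {
  stopifnot(inherits(angle, "angle_signal"))
  if (is.null(angle$alpha_detrend)) stop("detrend the angle first")
  x <- angle$alpha_detrend
  fs <- angle$fs
  n <- length(x)
  L <- round(window_s * fs)
  out <- data.frame(start_time = numeric(0), start_index = integer(0),
                    duration = numeric(0), dominant_freq = numeric(0),
                    band_power_fraction = numeric(0), valid = logical(0))
  if (n < L) {
    warning("bout too short for spectral analysis (< one window)")
    return(structure(out, class = c("spectral_windows", "data.frame"),
                     n_samples = n, window_len = L))
  }
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  rows <- lapply(starts, function(s) {
    sp <- window_spectrum(x[s:(s + L - 1L)], fs)
    bp <- if (is.finite(sp$dominant_freq)) band_power_fraction(sp, band) else 0
    data.frame(start_time = angle$t[s], start_index = s,
               duration = L / fs,
               dominant_freq = sp$dominant_freq,
               band_power_fraction = bp,
               valid = is.finite(sp$dominant_freq) && bp >= power_gate &&
                 sp$dominant_freq >= band[1] - 1e-9 &&
                 sp$dominant_freq <= band[2] + 1e-9)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("spectral_windows", "data.frame"),
            n_samples = n, window_len = L)
}

# magnitude spectrum of one rectangular window; non-DC bins up to Nyquist
window_spectrum <- function(seg, fs) {
  L <- length(seg)
  mag <- Mod(stats::fft(seg))
  kmax <- floor(L / 2)                      # exclude DC (k = 0), keep <= Nyquist
  freqs <- (1:kmax) * fs / L
  p <- mag[2:(kmax + 1)]^2
  dom <- if (sum(p) <= 1e-12 * L^2 * max(mean(seg^2), .Machine$double.eps)) {
    NA_real_                                 # flat segment: no non-DC power
  } else freqs[which.max(p)]
  list(freqs = freqs, power = p, dominant_freq = dom)
}

band_power_fraction <- function(sp, band) {
  tot <- sum(sp$power)
  if (tot <= 0) return(0)
  inb <- sp$freqs >= band[1] - 1e-9 & sp$freqs <= band[2] + 1e-9
  sum(sp$power[inb]) / tot
}

#' Average arm-swing cycle time
#'
#' The reciprocal of the mean dominant frequency over valid spectral
#' windows.
#'
#' @param windows an [analyze_windows()] result.
#' @return Cycle time in seconds, or `NA_real_` (with a warning) when no
#'   window is valid — no periodic movement, so no swing parameters can be
#'   computed downstream.
#' @export
mean_cycle_time <- function(windows) {
  v <- windows$valid
  if (!any(v)) {
    warning("no periodic movement: no valid spectral windows")
    return(NA_real_)
  }
  1 / mean(windows$dominant_freq[v])
}

#' Per-sample analyzability mask
#'
#' A sample is analyzable when it is covered by at least one valid spectral
#' window; extrema outside analyzable stretches are discarded by
#' [detect_extrema()].
#'
#' @param windows an [analyze_windows()] result.
#' @return Logical vector over the bout's samples.
#' @export
analyzable_mask <- function(windows) {
  n <- attr(windows, "n_samples")
  L <- attr(windows, "window_len")
  mask <- rep(FALSE, n)
  for (i in which(windows$valid)) {
    s <- windows$start_index[i]
    mask[s:min(n, s + L - 1L)] <- TRUE
  }
  mask
}
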