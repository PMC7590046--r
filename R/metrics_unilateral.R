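#' Swing regularity from windowed autocorrelation
#'
#' Quantifies how similar each swing is to its neighbours. The detrended
#' angle is cut into 4.5-s windows advanced by 1% of the window length
#' (99% overlap), each window is tapered with a Tukey window (cosine
#' fraction 0.3), and the unbiased normalized autocorrelation of the
#' tapered segment is computed. The maximum autocorrelation over the lag
#' search range is extracted per window and the average over windows,
#' clipped to \[0, 1\], is the regularity. A value of 1 means a swing is
#' exactly similar to its neighbouring swings.
#'
#' The lag search starts at 1/3 s — the period of the fastest admissible
#' swing — because every signal has autocorrelation 1 at lag zero, so lags
#' on the shoulder of the lag-0 peak must be excluded for the maximum to be
#' informative; it ends at half the window length, where the unbiased
#' estimate still averages at least half the window.
#'
#' @param angle detrended [angle_signal][detrend_angle()].
#' @param window_s window length, seconds.
#' @param cosine_frac Tukey taper cosine fraction.
#' @param overlap fractional window overlap.
#' @param lag_range lag search range, seconds.
#' @return Regularity in \[0, 1\], or `NA_real_` (with a warning) for bouts
#'   shorter than one window.
#' @export
regularity <- function(angle, window_s = 4.5, cosine_frac = 0.3,
                       overlap = 0.99, lag_range = c(1 / 3, window_s / 2)) {
  stopifnot(inherits(angle, "angle_signal"))
  if (is.null(angle$alpha_detrend)) stop("detrend the angle first")
  x <- angle$alpha_detrend
  fs <- angle$fs
  n <- length(x)
  L <- round(window_s * fs)
  if (n < L) {
    warning(sprintf("bout shorter than %.1f s: regularity not computed", window_s))
    return(NA_real_)
  }
  hop <- max(1L, round((1 - overlap) * L))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  taper <- tukey_window(L, cosine_frac)
  lag_min <- round(lag_range[1] * fs)
  lag_max <- min(floor(L / 2), round(lag_range[2] * fs))
  mx <- vapply(starts, function(s) {
    r <- autocorr_unbiased(x[s:(s + L - 1L)] * taper, lag_min, lag_max)
    if (!length(r)) 0 else max(r)
  }, numeric(1))
  min(1, max(0, mean(mx)))
}

#' Per-arm arm-swing summary
#'
#' Aggregates retained swings and the spectral windows of one arm into the
#' per-arm parameter set: swing count, mean amplitude, mean peak angular
#' velocity (overall and split into forward and backward swings), the
#' percentage of the walking bout during which swings were detected, the
#' swing frequency (mean dominant frequency over valid windows), and the
#' regularity. When no swings survive the retention filters the count is 0
#' and the swing-based parameters are `NA` ("not computed"): the arm
#' movements were too small or not periodic.
#'
#' @param swings a filtered [swing_table][filter_swings()].
#' @param windows an [analyze_windows()] result.
#' @param angle the detrended [angle_signal][detrend_angle()].
#' @param bout_duration bout length, seconds.
#' @return An object of class `arm_summary`: list with `n_swings`,
#'   `amplitude_mean`, `peak_omega_mean`, `peak_omega_forward_mean`,
#'   `peak_omega_backward_mean` (all magnitudes), `pct_swing_time`,
#'   `frequency`, `regularity`.
#' @export
summarize_arm <- function(swings, windows, angle, bout_duration) {
  stopifnot(bout_duration > 0)
  ret <- swings[swings$retained, , drop = FALSE]
  freq <- if (any(windows$valid)) mean(windows$dominant_freq[windows$valid])
          else NA_real_
  reg <- suppressWarnings(regularity(angle))
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  if (!nrow(ret)) {
    out <- list(n_swings = 0L, amplitude_mean = NA_real_,
                peak_omega_mean = NA_real_, peak_omega_forward_mean = NA_real_,
                peak_omega_backward_mean = NA_real_, pct_swing_time = 0,
                frequency = freq, regularity = reg)
  } else {
    fwd <- ret$direction == "forward"
    out <- list(
      n_swings = nrow(ret),
      amplitude_mean = mean(ret$amplitude),
      peak_omega_mean = mean(abs(ret$peak_omega)),
      peak_omega_forward_mean = mean_or_na(abs(ret$peak_omega[fwd])),
      peak_omega_backward_mean = mean_or_na(abs(ret$peak_omega[!fwd])),
      pct_swing_time = 100 * interval_union_length(ret$t_start, ret$t_end) /
        bout_duration,
      frequency = freq,
      regularity = reg)
  }
  structure(out, class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat("<arm_summary>\n")
  cat(sprintf("  swings retained       %d\n", x$n_swings))
  cat(sprintf("  amplitude             %.1f deg\n", x$amplitude_mean))
  cat(sprintf("  peak angular velocity %.1f deg/s (fwd %.1f / bwd %.1f)\n",
              x$peak_omega_mean, x$peak_omega_forward_mean,
              x$peak_omega_backward_mean))
  cat(sprintf("  %% of walk swinging    %.1f\n", x$pct_swing_time))
  cat(sprintf("  frequency             %.2f Hz\n", x$frequency))
  cat(sprintf("  regularity            %.2f\n", x$regularity))
  invisible(x)
}

# total length of the union of intervals [a_i, b_i]
interval_union_length <- function(a, b) {
  if (!length(a)) return(0)
  o <- order(a)
  a <- a[o]; b <- b[o]
  tot <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_b) { tot <- tot + (cur_b - cur_a); cur_a <- a[i]; cur_b <- b[i] }
    else cur_b <- max(cur_b, b[i])
  }
  tot + (cur_b - cur_a)
}
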