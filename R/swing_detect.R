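#' Detect angle extrema in sliding windows
#'
#' Runs prominence-based peak detection on the detrended swing angle in 3-s
#' windows with 50% overlap. Positive and negative peaks each need a
#' prominence of at least `prominence` degrees and a minimum distance of
#' `min_distance_frac` of the window's own cycle time (from the window's
#' dominant frequency; same-kind extrema of a swing are one cycle apart, so
#' the distance rule is applied to maxima and minima separately). Peaks
#' found by several overlapping windows are counted once; two same-kind
#' detections closer than the distance rule allows are taken to be the same
#' physical peak and the larger magnitude is kept. Extrema falling on
#' samples not covered by any valid spectral window are dropped, and
#' alternation of maxima and minima is enforced by discarding the
#' smaller-magnitude extremum of any same-kind adjacent pair.
#'
#' @param angle detrended [angle_signal][detrend_angle()].
#' @param windows an [analyze_windows()] result (provides the validity
#'   mask and the global mean cycle time for cross-window deduplication).
#' @param prominence minimum peak prominence, degrees.
#' @param min_distance_frac minimum peak distance as a fraction of the
#'   per-window cycle time.
#' @param window_s,overlap peak-detection window length (s) and overlap.
#' @return A data frame with one row per extremum: `sample_index`, `time`,
#'   `value` (deg, signed detrended angle), `kind` (`"max"`/`"min"`).
#' @export
detect_extrema <- function(angle, windows, prominence = 2,
                           min_distance_frac = 0.6,
                           window_s = 3, overlap = 0.5) {
  stopifnot(inherits(angle, "angle_signal"))
  x <- angle$alpha_detrend
  fs <- angle$fs
  n <- length(x)
  L <- round(window_s * fs)
  empty <- data.frame(sample_index = integer(0), time = numeric(0),
                      value = numeric(0), kind = character(0))
  if (n < L || !any(windows$valid)) return(empty)
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  idx_max <- integer(0); idx_min <- integer(0)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    dom <- window_spectrum(seg, fs)$dominant_freq
    if (!is.finite(dom)) next
    md <- max(1L, round(min_distance_frac * fs / dom))
    idx_max <- c(idx_max, s - 1L + find_peaks(seg, prominence, md))
    idx_min <- c(idx_min, s - 1L + find_peaks(-seg, prominence, md))
  }
  T_mean <- suppressWarnings(mean_cycle_time(windows))
  md_global <- max(1L, round(min_distance_frac * fs * T_mean))
  idx_max <- dedup_peaks(unique(idx_max), x, md_global)
  idx_min <- dedup_peaks(unique(idx_min), -x, md_global)
  mask <- analyzable_mask(windows)
  idx_max <- idx_max[mask[idx_max]]
  idx_min <- idx_min[mask[idx_min]]
  if (!length(idx_max) && !length(idx_min)) return(empty)
  ext <- rbind(
    data.frame(sample_index = idx_max, kind = "max"),
    data.frame(sample_index = idx_min, kind = "min"))
  ext <- ext[order(ext$sample_index), , drop = FALSE]
  ext <- enforce_alternation(ext, x)
  data.frame(sample_index = ext$sample_index,
             time = angle$t[ext$sample_index],
             value = x[ext$sample_index],
             kind = ext$kind)
}

# same-kind detections closer than min_dist are one physical peak:
# keep the higher (on the oriented signal), greedily from the top
dedup_peaks <- function(idx, oriented, min_dist) {
  if (length(idx) < 2L) return(sort(idx))
  ord <- idx[order(oriented[idx], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord)
    if (!length(taken) || min(abs(taken - i)) >= min_dist)
      taken <- c(taken, i)
  sort(taken)
}

# between two maxima only one minimum (and vice versa): drop the
# smaller-magnitude member of any same-kind adjacent pair, repeat
enforce_alternation <- function(ext, x) {
  repeat {
    if (nrow(ext) < 2L) return(ext)
    same <- which(ext$kind[-1] == ext$kind[-nrow(ext)])
    if (!length(same)) return(ext)
    i <- same[1]
    drop <- if (abs(x[ext$sample_index[i]]) <= abs(x[ext$sample_index[i + 1]]))
      i else i + 1L
    ext <- ext[-drop, , drop = FALSE]
  }
}

#' Pair alternating extrema into swings
#'
#' Each consecutive pair of (alternating) angle extrema delimits one arm
#' swing. The swing amplitude is the sum of the magnitudes of its two
#' bounding extrema; the peak angular velocity is the largest-magnitude
#' value of the swing-direction angular velocity within the swing's closed
#' sample interval (earliest sample on ties), and its sign labels the swing
#' forward (positive, a velocity maximum) or backward.
#'
#' @param extrema a [detect_extrema()] result.
#' @param sig the [swing_axis_signal][project_swing_axis()] of the same bout.
#' @return A data frame of class `swing_table`, one row per swing:
#'   `t_start`, `t_end`, `duration`, `amplitude` (deg), `peak_omega`
#'   (deg/s, signed), `direction`, `retained` (initially `TRUE`),
#'   `reject_reason` (initially `"none"`), plus bounding sample indices and
#'   extremum magnitudes used by the retention filters.
#' @export
build_swings <- function(extrema, sig) {
  stopifnot(inherits(sig, "swing_axis_signal"))
  empty <- swing_table(NULL)
  m <- nrow(extrema)
  if (is.null(m) || m < 2L) return(empty)
  i1 <- extrema$sample_index[-m]; i2 <- extrema$sample_index[-1]
  v1 <- extrema$value[-m];        v2 <- extrema$value[-1]
  pk <- vapply(seq_len(m - 1L), function(k) {
    seg <- sig$omega_swing[i1[k]:i2[k]]
    seg[which.max(abs(seg))]
  }, numeric(1))
  swing_table(data.frame(
    t_start = extrema$time[-m], t_end = extrema$time[-1],
    duration = extrema$time[-1] - extrema$time[-m],
    amplitude = abs(v1) + abs(v2),
    peak_omega = pk,
    direction = ifelse(pk > 0, "forward", "backward"),
    i_start = i1, i_end = i2,
    ext_mag_start = abs(v1), ext_mag_end = abs(v2),
    retained = TRUE, reject_reason = "none"))
}

swing_table <- function(df) {
  if (is.null(df))
    df <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     duration = numeric(0), amplitude = numeric(0),
                     peak_omega = numeric(0), direction = character(0),
                     i_start = integer(0), i_end = integer(0),
                     ext_mag_start = numeric(0), ext_mag_end = numeric(0),
                     retained = logical(0), reject_reason = character(0))
  structure(df, class = c("swing_table", "data.frame"))
}

#' Apply the swing retention filters
#'
#' Flags swings in the stated order, recording only the first rule tripped:
#' \enumerate{
#'   \item `too_long`: duration exceeds twice the average cycle time (a
#'     half-cycle that long is unlikely to be a real swing);
#'   \item `outlier`: a bounding extremum magnitude exceeds `outlier_factor`
#'     times the `outlier_percentile`-th percentile (linear interpolation)
#'     of all detected extremum magnitudes — movements such as scratching
#'     the head rather than swinging;
#'   \item `below_amplitude`: amplitude under `amp_threshold` (5 degrees,
#'     the minimum movement defined to be an arm swing);
#'   \item `below_velocity`: peak angular velocity magnitude under
#'     `vel_threshold` (10 deg/s) — detection accuracy cannot be guaranteed
#'     for such small movements.
#' }
#'
#' @param swings a [build_swings()] result.
#' @param T_mean average cycle time, s (from [mean_cycle_time()]).
#' @param extremum_mags magnitudes of all detected extrema (defaults to the
#'   bounding magnitudes in `swings`).
#' @param long_swing_factor,outlier_factor,outlier_percentile,amp_threshold,vel_threshold
#'   rule parameters, see above.
#' @return The swing table with `retained` and `reject_reason` set.
#' @export
filter_swings <- function(swings, T_mean, extremum_mags = NULL,
                          long_swing_factor = 2, outlier_factor = 3,
                          outlier_percentile = 80,
                          amp_threshold = 5, vel_threshold = 10) {
  if (!nrow(swings)) return(swings)
  if (is.null(extremum_mags))
    extremum_mags <- c(swings$ext_mag_start, swings$ext_mag_end[nrow(swings)])
  p80 <- stats::quantile(extremum_mags, outlier_percentile / 100,
                         names = FALSE, type = 7)
  reason <- rep("none", nrow(swings))
  hit <- function(cond, lab) ifelse(reason == "none" & cond, lab, reason)
  reason <- hit(is.finite(T_mean) & swings$duration > long_swing_factor * T_mean,
                "too_long")
  reason <- hit(pmax(swings$ext_mag_start, swings$ext_mag_end) >
                  outlier_factor * p80, "outlier")
  reason <- hit(swings$amplitude < amp_threshold, "below_amplitude")
  reason <- hit(abs(swings$peak_omega) < vel_threshold, "below_velocity")
  swings$reject_reason <- reason
  swings$retained <- reason == "none"
  swings
}
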