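#' Analysis configuration
#'
#' All tunable constants of the pipeline in one validated object. Every
#' default is the published operating point of the algorithm; any value can
#' be overridden here or, from the command line, via flags.
#'
#' @param cutoff low-pass cutoff, Hz.
#' @param band periodicity band, Hz (closed interval).
#' @param power_gate minimum in-band power fraction for a valid window.
#' @param prominence minimum extremum prominence, deg.
#' @param min_distance_frac minimum peak distance as fraction of cycle time.
#' @param fft_window spectral/peak window length, s.
#' @param fft_overlap_freq overlap of the frequency-analysis windows.
#' @param fft_overlap_peaks overlap of the peak-detection windows.
#' @param amp_threshold minimum swing amplitude, deg.
#' @param vel_threshold minimum peak angular velocity, deg/s.
#' @param long_swing_factor maximum swing duration in cycle times.
#' @param outlier_factor,outlier_percentile extremum-outlier rule: reject
#'   above `outlier_factor` times the `outlier_percentile`-th percentile.
#' @param regularity_window regularity window, s.
#' @param regularity_cosine_frac Tukey taper cosine fraction.
#' @param regularity_overlap regularity window overlap.
#' @param simultaneity_tol direction-change matching tolerance, s.
#' @param eligibility minimum simultaneous fraction (0--1) for bilateral
#'   asymmetry/coordination.
#' @param coordination_max_lag,coordination_margin cross-correlation lag
#'   half-range and per-swing interval margin, s.
#' @param units input units, `"deg/s"` or `"rad/s"` (converted on read).
#' @return Object of class `analysis_config` (validated list).
#' @export
analysis_config <- function(cutoff = 3, band = c(0.3, 3), power_gate = 0.9,
                            prominence = 2, min_distance_frac = 0.6,
                            fft_window = 3, fft_overlap_freq = 0.75,
                            fft_overlap_peaks = 0.5,
                            amp_threshold = 5, vel_threshold = 10,
                            long_swing_factor = 2, outlier_factor = 3,
                            outlier_percentile = 80,
                            regularity_window = 4.5,
                            regularity_cosine_frac = 0.3,
                            regularity_overlap = 0.99,
                            simultaneity_tol = 0.5, eligibility = 0.6,
                            coordination_max_lag = 0.5,
                            coordination_margin = 0.5,
                            units = c("deg/s", "rad/s")) {
  units <- match.arg(units)
  stopifnot(cutoff > 0, length(band) == 2, band[1] > 0, band[2] > band[1],
            power_gate > 0, power_gate <= 1, prominence >= 0,
            min_distance_frac > 0, fft_window > 0,
            fft_overlap_freq >= 0, fft_overlap_freq < 1,
            fft_overlap_peaks >= 0, fft_overlap_peaks < 1,
            amp_threshold >= 0, vel_threshold >= 0, long_swing_factor > 0,
            outlier_factor > 0, outlier_percentile > 0,
            outlier_percentile <= 100,
            regularity_window > 0, regularity_cosine_frac >= 0,
            regularity_cosine_frac <= 1, regularity_overlap >= 0,
            regularity_overlap < 1, simultaneity_tol >= 0,
            eligibility >= 0, eligibility <= 1,
            coordination_max_lag > 0, coordination_margin >= 0)
  structure(as.list(environment()), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
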