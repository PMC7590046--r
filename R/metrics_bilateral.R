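#' Simultaneously swinging phases of the two arms
#'
#' A direction change is the bounding extremum instant of a retained swing
#' (the arm reverses from forward to backward or vice versa there). A swing
#' is simultaneous when any of its direction changes falls within `tol`
#' (default 500 ms) of a direction change of the other arm. The percentage
#' of the walking bout spent with simultaneously swinging arms is the union
#' duration of all simultaneous swings of both arms over the bout duration.
#'
#' Both arms must share a synchronized time base; the reader is responsible
#' for synchronization and no resampling is performed here.
#'
#' @param left,right filtered [swing_table][filter_swings()]s of the two arms.
#' @param tol matching tolerance, seconds.
#' @param bout_duration common bout duration, seconds.
#' @return List with `left_sim` / `right_sim` (logical over the retained
#'   swings of each arm), `intervals` (two-column matrix, the union of
#'   simultaneous swing intervals) and `pct_simultaneous`.
#' @export
simultaneous_phases <- function(left, right, tol = 0.5, bout_duration) {
  stopifnot(bout_duration > 0)
  lret <- left[left$retained, , drop = FALSE]
  rret <- right[right$retained, , drop = FALSE]
  ev_l <- unique(c(lret$t_start, lret$t_end))
  ev_r <- unique(c(rret$t_start, rret$t_end))
  near <- function(ts, ev) {
    if (!length(ev)) return(rep(FALSE, length(ts)))
    vapply(ts, function(t0) min(abs(ev - t0)) <= tol, logical(1))
  }
  left_sim <- near(lret$t_start, ev_r) | near(lret$t_end, ev_r)
  right_sim <- near(rret$t_start, ev_l) | near(rret$t_end, ev_l)
  a <- c(lret$t_start[left_sim], rret$t_start[right_sim])
  b <- c(lret$t_end[left_sim], rret$t_end[right_sim])
  ints <- if (length(a)) merge_intervals(a, b) else
    matrix(numeric(0), ncol = 2)
  list(left_sim = left_sim, right_sim = right_sim, intervals = ints,
       pct_simultaneous = 100 * interval_union_length(a, b) / bout_duration)
}

merge_intervals <- function(a, b) {
  o <- order(a); a <- a[o]; b <- b[o]
  out_a <- a[1]; out_b <- b[1]
  for (i in seq_along(a)[-1]) {
    k <- length(out_a)
    if (a[i] > out_b[k]) { out_a <- c(out_a, a[i]); out_b <- c(out_b, b[i]) }
    else out_b[k] <- max(out_b[k], b[i])
  }
  cbind(start = out_a, end = out_b)
}

#' Asymmetry index
#'
#' `ASI = (L - R) / max(L, R) * 100`, comparing a left-arm and a right-arm
#' mean (amplitude or peak angular velocity, computed over simultaneous
#' swings only). An ASI of 0% reflects identical values of the left and
#' right arm; the sign says which arm is larger. Both inputs must be
#' strictly positive.
#'
#' @param L,R left and right values, same units (deg or deg/s).
#' @return Signed asymmetry index, %.
#' @export
asymmetry_index <- function(L, R) {
  if (!is.finite(L) || !is.finite(R) || L <= 0 || R <= 0) {
    warning("asymmetry index needs strictly positive left and right values")
    return(NA_real_)
  }
  (L - R) / max(L, R) * 100
}

#' Bilateral coordination from normalized cross-correlation
#'
#' For each simultaneous swing the two arms' swing-direction angular
#' velocities over the swing interval extended by `margin` seconds on each
#' side are cross-correlated over lags of 0 +/- `max_lag` s, normalizing by
#' the root energies of the overlapping segments so the score is bounded by
#' 1 in magnitude. The per-swing score is the absolute value of the minimum
#' over lags; coordination is the mean score over swings, clipped to
#' \[0, 1\]. A value of 1 indicates the arms swing with a similar rhythm
#' exactly out of phase; 0 indicates no coordination.
#'
#' Note that for swing frequencies of 1 Hz and above the +/- 0.5 s lag
#' range spans at least half a period, so in-phase and anti-phase arms both
#' score near 1; this is inherent to the definition.
#'
#' @param sig_left,sig_right [swing_axis_signal][project_swing_axis()]s on a
#'   common time base.
#' @param swings data frame of simultaneous swings with `i_start` / `i_end`
#'   sample indices (any mix of left- and right-arm swings).
#' @param max_lag lag half-range, seconds.
#' @param margin interval extension on each side, seconds.
#' @return Coordination in \[0, 1\], or `NA_real_` when `swings` is empty.
#' @export
coordination <- function(sig_left, sig_right, swings, max_lag = 0.5,
                         margin = 0.5) {
  stopifnot(inherits(sig_left, "swing_axis_signal"),
            inherits(sig_right, "swing_axis_signal"))
  if (is.null(swings) || !nrow(swings)) {
    warning("no simultaneous swings: coordination not computed")
    return(NA_real_)
  }
  fs <- sig_left$fs
  n <- min(length(sig_left$omega_swing), length(sig_right$omega_swing))
  lag_n <- round(max_lag * fs)
  pad <- round(margin * fs)
  scores <- vapply(seq_len(nrow(swings)), function(k) {
    i1 <- max(1L, swings$i_start[k] - pad)
    i2 <- min(n, swings$i_end[k] + pad)
    xc <- norm_xcorr(sig_left$omega_swing[i1:i2],
                     sig_right$omega_swing[i1:i2], lag_n)
    abs(min(xc$r))
  }, numeric(1))
  min(1, max(0, mean(scores)))
}

#' Bilateral arm-swing summary
#'
#' Combines the two arms' swing tables and swing-axis signals into the
#' left-versus-right parameters: percentage of the bout with simultaneously
#' swinging arms, the amplitude and peak-angular-velocity asymmetry indices
#' (signed and magnitude) and the coordination. The asymmetry indices and
#' coordination are only computed when at least `eligibility` (default 60%)
#' of the walking episode had simultaneously swinging arms, and their
#' left/right means use simultaneous swings only.
#'
#' @param left_swings,right_swings filtered [swing_table][filter_swings()]s.
#' @param sig_left,sig_right the arms' swing-axis signals.
#' @param bout_duration seconds.
#' @param tol simultaneity tolerance, seconds.
#' @param eligibility minimum simultaneous fraction (0--1) for asymmetry and
#'   coordination.
#' @param max_lag,margin passed to [coordination()].
#' @return Object of class `bilateral_summary`: list with
#'   `pct_simultaneous`, `eligible`, `asi_amplitude`, `asi_peak_omega`,
#'   `asi_amplitude_abs`, `asi_peak_omega_abs`, `coordination`.
#' @export
summarize_bilateral <- function(left_swings, right_swings, sig_left, sig_right,
                                bout_duration, tol = 0.5, eligibility = 0.6,
                                max_lag = 0.5, margin = 0.5) {
  sim <- simultaneous_phases(left_swings, right_swings, tol, bout_duration)
  eligible <- sim$pct_simultaneous >= 100 * eligibility
  out <- list(pct_simultaneous = sim$pct_simultaneous, eligible = eligible,
              asi_amplitude = NA_real_, asi_peak_omega = NA_real_,
              asi_amplitude_abs = NA_real_, asi_peak_omega_abs = NA_real_,
              coordination = NA_real_)
  if (eligible) {
    lsim <- left_swings[left_swings$retained, , drop = FALSE][sim$left_sim, , drop = FALSE]
    rsim <- right_swings[right_swings$retained, , drop = FALSE][sim$right_sim, , drop = FALSE]
    if (nrow(lsim) && nrow(rsim)) {
      out$asi_amplitude <- asymmetry_index(mean(lsim$amplitude),
                                           mean(rsim$amplitude))
      out$asi_peak_omega <- asymmetry_index(mean(abs(lsim$peak_omega)),
                                            mean(abs(rsim$peak_omega)))
      out$asi_amplitude_abs <- abs(out$asi_amplitude)
      out$asi_peak_omega_abs <- abs(out$asi_peak_omega)
      out$coordination <- coordination(sig_left, sig_right,
                                       rbind(lsim, rsim), max_lag, margin)
    }
  }
  structure(out, class = "bilateral_summary")
}

#' @export
print.bilateral_summary <- function(x, ...) {
  cat("<bilateral_summary>\n")
  cat(sprintf("  %% simultaneous       %.1f (eligible: %s)\n",
              x$pct_simultaneous, x$eligible))
  cat(sprintf("  ASI amplitude        %.1f %% (|%.1f|)\n",
              x$asi_amplitude, x$asi_amplitude_abs))
  cat(sprintf("  ASI peak velocity    %.1f %% (|%.1f|)\n",
              x$asi_peak_omega, x$asi_peak_omega_abs))
  cat(sprintf("  coordination         %.2f\n", x$coordination))
  invisible(x)
}
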