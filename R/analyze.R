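#' Run the full single-arm pipeline
#'
#' Low-pass filter, swing-axis projection, trapezoidal integration,
#' moving-average detrend, sliding-window spectral gating, extrema
#' detection, swing construction and the retention filters, then the
#' per-arm summary.
#'
#' @param rec a [gyro_recording()] (at least 3 s).
#' @param config an [analysis_config()].
#' @param verbose emit per-stage counts via [message()].
#' @return List with `status` (`"ok"` or `"no_periodic_movement"`), `sig`,
#'   `angle`, `windows`, `T_mean`, `swings`, `summary`, `counts`.
#' @export
analyze_arm <- function(rec, config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(rec, "gyro_recording"))
  dur <- rec_duration(rec)
  if (dur < config$fft_window)
    stop(sprintf("bout too short: %.2f s < one %.0f-s window", dur,
                 config$fft_window))
  say <- function(...) if (verbose) message(sprintf(...))
  filt <- lowpass_filter(rec, config$cutoff)
  sig <- project_swing_axis(filt)
  angle <- detrend_angle(integrate_angle(sig))
  windows <- analyze_windows(angle, band = config$band,
                             power_gate = config$power_gate,
                             window_s = config$fft_window,
                             overlap = config$fft_overlap_freq)
  say("%s: %d/%d spectral windows valid", rec$side,
      sum(windows$valid), nrow(windows))
  empty <- list(status = "no_periodic_movement", sig = sig, angle = angle,
                windows = windows, T_mean = NA_real_,
                swings = swing_table(NULL),
                summary = summarize_arm(swing_table(NULL), windows, angle, dur),
                counts = list(windows_valid = sum(windows$valid),
                              windows_total = nrow(windows),
                              extrema = 0L, swings = 0L, retained = 0L,
                              rejected = c()))
  if (sig$no_axis || !any(windows$valid)) return(empty)
  T_mean <- mean_cycle_time(windows)
  extrema <- detect_extrema(angle, windows,
                            prominence = config$prominence,
                            min_distance_frac = config$min_distance_frac,
                            window_s = config$fft_window,
                            overlap = config$fft_overlap_peaks)
  say("%s: %d extrema after deduplication and alternation", rec$side,
      nrow(extrema))
  swings <- build_swings(extrema, sig)
  swings <- filter_swings(swings, T_mean,
                          extremum_mags = abs(extrema$value),
                          long_swing_factor = config$long_swing_factor,
                          outlier_factor = config$outlier_factor,
                          outlier_percentile = config$outlier_percentile,
                          amp_threshold = config$amp_threshold,
                          vel_threshold = config$vel_threshold)
  rejected <- table(swings$reject_reason[!swings$retained])
  say("%s: %d swings, %d retained (%s)", rec$side, nrow(swings),
      sum(swings$retained),
      if (length(rejected)) paste(names(rejected), rejected, sep = ": ",
                                  collapse = ", ") else "none rejected")
  list(status = "ok", sig = sig, angle = angle, windows = windows,
       T_mean = T_mean, swings = swings,
       summary = summarize_arm(swings, windows, angle, dur),
       counts = list(windows_valid = sum(windows$valid),
                     windows_total = nrow(windows),
                     extrema = nrow(extrema), swings = nrow(swings),
                     retained = sum(swings$retained),
                     rejected = as.list(rejected)))
}

#' Analyze a walking bout from one or two arm recordings
#'
#' Orchestrates the whole pipeline. With one recording, the per-arm
#' parameters are computed and the bilateral block carries the reason
#' `"single_arm"`; with two synchronized recordings the bilateral
#' simultaneity, asymmetry and coordination parameters are added.
#'
#' @param left a [gyro_recording()] or a CSV path for [read_gyro_csv()].
#' @param right optional second arm, same forms.
#' @param config an [analysis_config()].
#' @param verbose emit per-stage counts.
#' @return Object of class `armswing_report`: list with `status`, `fs`,
#'   `bout_duration`, `arms` (named list of per-arm summaries), `bilateral`,
#'   `counts`, and `swings` (combined per-swing table with a `side` column;
#'   not serialized by [write_report()], use [write_swing_csv()]).
#' @export
analyze_bout <- function(left, right = NULL, config = analysis_config(),
                         verbose = FALSE) {
  as_rec <- function(x, side) {
    if (is.character(x)) x <- read_gyro_csv(x, units = config$units, side = side)
    if (is.na(x$side)) x$side <- side
    x
  }
  left <- as_rec(left, "left")
  both <- !is.null(right)
  if (both) {
    right <- as_rec(right, "right")
    if (abs(left$fs - right$fs) > 1e-6 * left$fs)
      stop("left and right recordings have different sampling rates")
  }
  dur <- if (both) min(rec_duration(left), rec_duration(right))
         else rec_duration(left)
  res <- list(left = analyze_arm(left, config, verbose))
  if (both) res$right <- analyze_arm(right, config, verbose)
  swings <- do.call(rbind, lapply(names(res), function(s) {
    sw <- res[[s]]$swings
    if (nrow(sw)) cbind(side = s, as.data.frame(sw)) else NULL
  }))
  status <- if (all(vapply(res, function(r) r$status, "") ==
                    "no_periodic_movement")) "no_periodic_movement" else "ok"
  bilateral <- if (!both) {
    list(reason = "single_arm")
  } else if (status == "no_periodic_movement") {
    list(reason = "no_periodic_movement")
  } else {
    summarize_bilateral(res$left$swings, res$right$swings,
                        res$left$sig, res$right$sig, dur,
                        tol = config$simultaneity_tol,
                        eligibility = config$eligibility,
                        max_lag = config$coordination_max_lag,
                        margin = config$coordination_margin)
  }
  structure(list(status = status, fs = left$fs, bout_duration = dur,
                 arms = lapply(res, function(r) r$summary),
                 bilateral = bilateral,
                 counts = lapply(res, function(r) r$counts),
                 swings = swings),
            class = "armswing_report")
}

#' @export
print.armswing_report <- function(x, ...) {
  cat(sprintf("<armswing_report> status %s, %.1f s @ %g Hz\n",
              x$status, x$bout_duration, x$fs))
  for (s in names(x$arms)) {
    cat(sprintf("-- %s arm --\n", s)); print(x$arms[[s]])
  }
  if (inherits(x$bilateral, "bilateral_summary")) print(x$bilateral)
  else cat(sprintf("-- bilateral: not computed (%s)\n", x$bilateral$reason))
  invisible(x)
}

#' Write / read a bout report as JSON
#'
#' Serializes the summary parts of an [analyze_bout()] report (status,
#' per-arm parameters, bilateral parameters, stage counts) at full numeric
#' precision. The per-swing table is not included; write it with
#' [write_swing_csv()].
#'
#' @param report an `armswing_report`.
#' @param path output / input path.
#' @return `path` invisibly; `read_report()` returns the deserialized list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "armswing_report"))
  out <- list(status = report$status, fs = report$fs,
              bout_duration = report$bout_duration,
              arms = lapply(report$arms, unclass),
              bilateral = unclass(report$bilateral),
              counts = report$counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
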