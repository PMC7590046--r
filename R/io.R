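#' Read a gyroscope CSV file
#'
#' Reads a delimited text export with a time column (seconds) and three
#' angular-velocity columns. Values in rad/s are converted to deg/s when
#' `units = "rad/s"`. Short dropout gaps (runs of missing values up to
#' `max_gap` seconds) are filled by linear interpolation; longer gaps abort
#' with a gap report, since silently bridging them would fabricate signal.
#' Non-monotone or non-uniform time stamps are rejected; no resampling is
#' performed.
#'
#' @param path file path.
#' @param columns named character vector mapping `time`, `x`, `y`, `z` to
#'   the column names in the file.
#' @param units input units.
#' @param fs sampling rate override, Hz; if `NULL` it is inferred from the
#'   time column.
#' @param side,label recording metadata.
#' @param max_gap longest interpolatable missing-value run, seconds.
#' @return A [gyro_recording()].
#' @export
read_gyro_csv <- function(path,
                          columns = c(time = "time", x = "gyro_x",
                                      y = "gyro_y", z = "gyro_z"),
                          units = c("deg/s", "rad/s"), fs = NULL,
                          side = NA_character_, label = basename(path),
                          max_gap = 0.25) {
  units <- match.arg(units)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  t <- as.numeric(df[[columns[["time"]]]])
  if (any(diff(t) <= 0)) stop("non-monotone time column in ", path)
  dt <- stats::median(diff(t))
  chans <- lapply(c("x", "y", "z"), function(a) as.numeric(df[[columns[[a]]]]))
  # dropout gaps: interpolate short runs, reject long ones
  chans <- lapply(chans, function(v) fill_gaps(v, t, max_gap / dt))
  scale <- if (units == "rad/s") 180 / pi else 1
  gyro_recording(t, chans[[1]] * scale, chans[[2]] * scale,
                 chans[[3]] * scale, fs = fs, side = side, label = label)
}

fill_gaps <- function(v, t, max_run) {
  na <- is.na(v) | is.nan(v)
  if (!any(na)) return(v)
  r <- rle(na)
  runs <- r$lengths[r$values]
  if (any(runs > max_run)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths > max_run)
    stop(sprintf("missing-value gap(s) too long to interpolate: %s",
                 paste(sprintf("%.3f-%.3f s (%d samples)",
                               t[starts[bad]], t[ends[bad]],
                               r$lengths[bad]), collapse = "; ")))
  }
  stats::approx(t[!na], v[!na], xout = t, rule = 2)$y
}

#' Write a gyroscope recording as CSV
#'
#' Writes the dialect [read_gyro_csv()] reads by default: comma-separated,
#' header `time, gyro_x, gyro_y, gyro_z`, time in seconds, rates in deg/s.
#'
#' @param rec a [gyro_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gyro_recording"))
  utils::write.csv(
    data.frame(time = rec$t, gyro_x = rec$omega_x,
               gyro_y = rec$omega_y, gyro_z = rec$omega_z),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a per-swing CSV table
#'
#' One row per swing: side, interval, duration, amplitude, signed peak
#' angular velocity, direction, retention flag and rejection reason.
#'
#' @param swings a [swing_table][filter_swings()] (or a report's `$swings`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swing_csv <- function(swings, path) {
  cols <- intersect(c("side", "t_start", "t_end", "duration", "amplitude",
                      "peak_omega", "direction", "retained", "reject_reason"),
                    names(swings))
  utils::write.csv(as.data.frame(swings)[, cols, drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}
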