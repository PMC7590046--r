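#' Method-agreement statistics for paired measurements
#'
#' Bland-Altman style agreement between a test method and a reference
#' measuring the same swings: the systematic error is the mean difference
#' (test minus reference), the random error is the half-width of the 95%
#' limits of agreement (1.96 times the sample standard deviation of the
#' differences), plus the root-mean-square error and the mean absolute
#' error.
#'
#' @param test,reference equal-length numeric vectors of paired values.
#' @return Object of class `agreement_stats`: list with `rmse`,
#'   `systematic_error`, `random_error`, `absolute_error`, `n`. Fields are
#'   `NA` (with a warning) when fewer than 2 pairs are available.
#' @export
agreement <- function(test, reference) {
  if (length(test) != length(reference))
    stop("test and reference must have equal length")
  d <- test - reference
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) {
    warning("fewer than 2 complete pairs: agreement not computed")
    return(structure(list(rmse = NA_real_, systematic_error = NA_real_,
                          random_error = NA_real_, absolute_error = NA_real_,
                          n = n), class = "agreement_stats"))
  }
  structure(list(rmse = sqrt(mean(d^2)),
                 systematic_error = mean(d),
                 random_error = 1.96 * stats::sd(d),
                 absolute_error = mean(abs(d)),
                 n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d\n", x$n))
  cat(sprintf("  RMSe             %.4g\n", x$rmse))
  cat(sprintf("  systematic error %.4g\n", x$systematic_error))
  cat(sprintf("  random error     %.4g (1.96 x SD of differences)\n",
              x$random_error))
  cat(sprintf("  absolute error   %.4g\n", x$absolute_error))
  invisible(x)
}

#' Match detected swings to reference swing intervals
#'
#' Greedy nearest-midpoint matching: the detected/reference pair with the
#' smallest midpoint distance is matched first, both are removed, and the
#' process repeats while the smallest distance is within `max_offset`.
#'
#' @param detected data frame with `t_start` / `t_end` (e.g. a retained
#'   [swing_table][filter_swings()]).
#' @param truth data frame with `t_start` / `t_end` (e.g. a `synth_truth`
#'   arm table).
#' @param max_offset maximum midpoint distance for a match, seconds.
#' @return List with `pairs` (data frame of `detected_idx`, `truth_idx`,
#'   `offset`), `unmatched_detected`, `unmatched_truth` (integer indices).
#' @export
match_swings <- function(detected, truth, max_offset = 0.25) {
  mid_d <- (detected$t_start + detected$t_end) / 2
  mid_t <- (truth$t_start + truth$t_end) / 2
  nd <- length(mid_d); nt <- length(mid_t)
  pairs <- data.frame(detected_idx = integer(0), truth_idx = integer(0),
                      offset = numeric(0))
  if (nd && nt) {
    dmat <- abs(outer(mid_d, mid_t, "-"))
    repeat {
      k <- which.min(dmat)
      if (!length(k) || dmat[k] > max_offset || !is.finite(dmat[k])) break
      i <- (k - 1) %% nd + 1
      j <- (k - 1) %/% nd + 1
      pairs <- rbind(pairs, data.frame(detected_idx = i, truth_idx = j,
                                       offset = dmat[k]))
      dmat[i, ] <- Inf
      dmat[, j] <- Inf
      if (all(!is.finite(dmat))) break
    }
  }
  list(pairs = pairs[order(pairs$detected_idx), , drop = FALSE],
       unmatched_detected = setdiff(seq_len(nd), pairs$detected_idx),
       unmatched_truth = setdiff(seq_len(nt), pairs$truth_idx))
}
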