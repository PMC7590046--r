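#' Local maxima with a prominence and minimum-distance constraint
#'
#' Finds strict local maxima of `x`, computes each peak's topographic
#' prominence (height above the higher of the two bases, where a base is the
#' lowest point between the peak and the nearest higher sample or the series
#' end), keeps peaks with prominence at least `min_prom`, then enforces the
#' minimum distance by keeping higher peaks first and discarding any peak
#' within `min_dist` samples of one already kept.
#'
#' Minima are found by calling this on `-x`.
#'
#' @param x numeric vector.
#' @param min_prom minimum prominence, same units as `x`.
#' @param min_dist minimum separation between kept peaks, samples.
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prom = 0, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- cand[prom >= min_prom]
  if (!length(keep)) return(integer(0))
  if (min_dist > 1L && length(keep) > 1L) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    taken <- integer(0)
    for (i in ord)
      if (!length(taken) || min(abs(taken - i)) >= min_dist)
        taken <- c(taken, i)
    keep <- sort(taken)
  }
  keep
}

# topographic prominence of the peak at index i
peak_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  rmin <- h
  j <- i + 1L
  while (j <= n && x[j] <= h) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  h - max(lmin, rmin)
}
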