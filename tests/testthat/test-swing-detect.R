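test_that("prominence peak finder matches an independently computed reference", {
  # multi-tone fixture; expected indices/prominences computed once with an
  # independent topographic-prominence implementation and frozen
  t <- seq(0, 7.99, by = 0.01)
  x <- 5 * sin(2 * pi * 0.7 * t) + 2 * sin(2 * pi * 1.9 * t + 1.0) +
    0.8 * sin(2 * pi * 3.3 * t + 2.2)
  idx <- find_peaks(x, min_prom = 2.0)
  expect_equal(idx, c(56L, 117L, 173L, 326L, 479L, 599L, 632L, 749L))
  prom <- vapply(idx, function(i) armswing:::peak_prominence(x, i), numeric(1))
  expect_equal(prom, c(3.583372, 2.349512, 10.610925, 13.62806, 12.59031,
                       2.349512, 10.610925, 8.452557), tolerance = 1e-6)
  expect_equal(find_peaks(x, min_prom = 2.0, min_dist = 120L),
               c(56L, 326L, 479L, 599L, 749L))
})

test_that("a 1 Hz sinusoidal bout yields alternating extrema at the closed-form times", {
  res <- analyze_arm(sine_rec(10, 1.0, duration = 30))
  ext <- detect_extrema(res$angle, res$windows)
  expect_gte(nrow(ext), 58)            # ~59: one extremum per half-second
  expect_lte(nrow(ext), 60)
  expect_true(all(ext$kind[-1] != ext$kind[-nrow(ext)]))   # alternation
  interior <- diff(ext$time)[2:(nrow(ext) - 2)]  # ends feel the detrend edge
  expect_equal(interior, rep(0.5, length(interior)), tolerance = 0.02)
  expect_equal(abs(ext$value), rep(10, nrow(ext)), tolerance = 0.1)
})

test_that("sub-prominence oscillation yields no extrema", {
  res <- analyze_arm(sine_rec(0.8, 1.0, duration = 30))  # 1.6 deg prominence
  expect_equal(nrow(detect_extrema(res$angle, res$windows)), 0L)
})

test_that("an extra same-kind peak is resolved by dropping the smaller one", {
  # a notch carved into every fifth crest creates adjacent double maxima
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  x <- 10 * sin(2 * pi * 1.0 * t)
  crest <- seq(51L, length(t) - 31L, by = 1000L)   # every 5 s at a crest
  for (i in crest) {
    j <- i + (-30:30)
    x[j] <- x[j] - 6 * exp(-((t[j] - t[i]) / 0.05)^2)
  }
  win <- analyze_windows(fake_angle(x))
  ext <- detect_extrema(fake_angle(x), win)
  expect_true(all(ext$kind[-1] != ext$kind[-nrow(ext)]))
  # the two halves of each split crest are lower than a clean crest, but
  # only one representative per crest may survive
  expect_lte(nrow(ext), 60)
})

test_that("swing construction follows the sum-of-magnitudes amplitude rule", {
  ext <- data.frame(sample_index = c(100L, 200L, 300L),
                    time = c(0.5, 1.0, 1.5),
                    value = c(-10, 10, -4),
                    kind = c("min", "max", "min"))
  sw <- build_swings(ext, fake_sig(rep(1, 400)))
  expect_equal(sw$amplitude, c(20, 14))
  ext2 <- ext; ext2$value <- c(8, -4, 2)  # +8 then -4 -> 12
  expect_equal(build_swings(ext2, fake_sig(rep(1, 400)))$amplitude[1], 12)
  expect_equal(nrow(build_swings(ext[1, ], fake_sig(rep(1, 400)))), 0L)
})

test_that("peak angular velocity matches the closed-form derivative and alternates sign", {
  res <- analyze_arm(sine_rec(10, 1.0, duration = 30))
  ret <- res$swings[res$swings$retained, ]
  expect_gt(nrow(ret), 50)
  expect_equal(mean(abs(ret$peak_omega)), 2 * pi * 10, tolerance = 0.02)
  expect_true(all(diff(sign(ret$peak_omega)) != 0))   # alternating direction
  expect_setequal(unique(ret$direction), c("forward", "backward"))
})

test_that("retention filters trip in order and record only the first reason", {
  base <- data.frame(t_start = c(0, 1, 2, 3), t_end = c(0.5, 4.0, 2.5, 3.5),
                     duration = c(0.5, 3.0, 0.5, 0.5),
                     amplitude = c(20, 20, 3, 20),
                     peak_omega = c(60, 60, 60, 5),
                     direction = "forward",
                     i_start = 1L, i_end = 2L,
                     ext_mag_start = 10, ext_mag_end = 10,
                     retained = TRUE, reject_reason = "none")
  out <- filter_swings(armswing:::swing_table(base), T_mean = 1,
                       extremum_mags = rep(10, 8))
  expect_equal(out$reject_reason,
               c("none", "too_long", "below_amplitude", "below_velocity"))
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the 3x80th-percentile rule flags an inserted outlier excursion", {
  # hand trace: extremum magnitudes 10 x ~10 plus one of 200;
  # 80th percentile ~ 10, threshold ~ 30 -> only the 200 deg excursion trips
  mags <- c(rep(10, 10), 200)
  sw <- data.frame(t_start = 0:9, t_end = 0:9 + 0.5, duration = 0.5,
                   amplitude = 20, peak_omega = 60, direction = "forward",
                   i_start = 1L, i_end = 2L,
                   ext_mag_start = c(rep(10, 9), 200),
                   ext_mag_end = 10,
                   retained = TRUE, reject_reason = "none")
  out <- filter_swings(armswing:::swing_table(sw), T_mean = 1,
                       extremum_mags = mags)
  expect_equal(out$reject_reason[10], "outlier")
  expect_true(all(out$retained[1:9]))
})

test_that("swings below the 5 deg amplitude definition are never retained", {
  res <- analyze_arm(sine_rec(2, 1.0, duration = 30))   # 4 deg peak-to-peak
  expect_equal(sum(res$swings$retained), 0L)
  res2 <- analyze_arm(sine_rec(10, 1.0, duration = 30)) # 20 deg peak-to-peak
  expect_true(all(res2$swings$retained))
})

test_that("5 Hz tremor is removed by the low-pass and leaves amplitudes unchanged", {
  clean <- analyze_arm(sine_rec(10, 1.0, duration = 30))
  trem <- analyze_arm(sine_rec(10, 1.0, duration = 30, tremor_amp = 10))
  a1 <- clean$swings$amplitude[clean$swings$retained]
  a2 <- trem$swings$amplitude[trem$swings$retained]
  expect_equal(length(a1), length(a2))
  expect_true(all(abs(a2 - a1) / a1 < 0.01))
})

test_that("identical input gives identical swing tables", {
  r1 <- analyze_arm(sine_rec(10, 1.0, duration = 30))$swings
  r2 <- analyze_arm(sine_rec(10, 1.0, duration = 30))$swings
  expect_identical(r1, r2)
})

test_that("retained swings tile without overlap", {
  res <- analyze_arm(sine_rec(12, 0.9, duration = 30))
  ret <- res$swings[res$swings$retained, ]
  expect_true(all(ret$t_start[-1] >= ret$t_end[-nrow(ret)] - 1e-12))
})
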