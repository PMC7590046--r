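test_that("zero-phase low-pass has unit DC gain and the analytic magnitude response", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  const <- gyro_recording(t, rep(7, length(t)), rep(7, length(t)),
                          rep(7, length(t)), fs = fs)
  fc <- lowpass_filter(const)
  for (ax in c("omega_x", "omega_y", "omega_z"))
    expect_equal(fc[[ax]], rep(7, length(t)), tolerance = 1e-6)

  for (case in list(c(f = 10, tol = 0.10), c(f = 1, tol = 0.005))) {
    rec <- gyro_recording(t, sin(2 * pi * case[["f"]] * t), rep(0, length(t)),
                          rep(0, length(t)), fs = fs)
    got <- mid_amp(lowpass_filter(rec)$omega_x)
    expect_equal(got, butter2_zp_mag(case[["f"]], 3),
                 tolerance = case[["tol"]])
  }
})

test_that("zero-phase filtering leaves a passband sinusoid's extrema in place", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  rec <- gyro_recording(t, sin(2 * pi * 1 * t), rep(0, length(t)),
                        rep(0, length(t)), fs = fs)
  y <- lowpass_filter(rec)$omega_x
  mid <- 600:700                       # one crest, at t = 3.25 s
  expect_lte(abs(which.max(y[mid]) - which.max(sin(2 * pi * t[mid]))), 1)
})

test_that("filtering rejects recordings shorter than the warm-up length", {
  t <- seq(0, 10 / 200, by = 1 / 200)
  expect_error(lowpass_filter(gyro_recording(t, t, t, t, fs = 200)),
               "too short")
})

test_that("swing-axis projection recovers single-axis and rotated planar motion", {
  rec <- sine_rec(10, 1, mount = 0)
  sig <- project_swing_axis(rec)
  expect_equal(abs(sig$loadings), c(1, 0), tolerance = 1e-12)
  expect_equal(sig$omega_swing, rec$omega_x - mean(rec$omega_x),
               tolerance = 1e-9)

  # planar motion at 30 deg: loadings from a direct eigen-decomposition
  rec30 <- sine_rec(10, 1, mount = pi / 6)
  sig30 <- project_swing_axis(rec30)
  cv <- stats::cov(cbind(rec30$omega_x, rec30$omega_y))
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0) v <- -v
  expect_equal(abs(sig30$loadings), abs(v), tolerance = 1e-9)
  expect_equal(sum(sig30$loadings^2), 1, tolerance = 1e-12)
  # the projection recovers the planar source signal
  s <- rec30$omega_x * cos(pi / 6) + rec30$omega_y * sin(pi / 6)
  expect_equal(abs(sig30$omega_swing), abs(s - mean(s)), tolerance = 1e-9)
})

test_that("the longitudinal z channel never reaches the swing signal", {
  rec <- sine_rec(10, 1)
  turn <- sine_rec(10, 1, z = 40)   # strong turning bout on z
  expect_identical(project_swing_axis(rec)$omega_swing,
                   project_swing_axis(turn)$omega_swing)
  # and bit-for-bit through integration and detrend
  a1 <- detrend_angle(integrate_angle(project_swing_axis(rec)))
  a2 <- detrend_angle(integrate_angle(project_swing_axis(turn)))
  expect_identical(a1$alpha, a2$alpha)
  expect_identical(a1$alpha_detrend, a2$alpha_detrend)
})

test_that("mounting rotation about the forearm changes loadings, not |omega_swing|", {
  base <- abs(project_swing_axis(sine_rec(10, 1, mount = 0))$omega_swing)
  for (rho in c(0.3, 1.0, 2.4, -0.7)) {
    rot <- abs(project_swing_axis(sine_rec(10, 1, mount = rho))$omega_swing)
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("a motionless arm yields no swing axis and no swings downstream", {
  t <- seq(0, 10, by = 1 / 200)
  rec <- gyro_recording(t, rep(0, length(t)), rep(0, length(t)),
                        rep(5, length(t)), fs = 200)
  sig <- project_swing_axis(rec)
  expect_true(sig$no_axis)
  res <- analyze_arm(rec)
  expect_equal(res$status, "no_periodic_movement")
  expect_equal(res$summary$n_swings, 0L)
})

test_that("trapezoidal integration matches closed forms", {
  fs <- 200
  expect_equal(integrate_angle(fake_sig(rep(0, 1000)))$alpha, rep(0, 1000))
  # constant 10 deg/s for 1 s ends at exactly 10 deg
  a <- integrate_angle(fake_sig(rep(10, fs + 1)))$alpha
  expect_identical(a[1], 0)
  expect_equal(a[length(a)], 10, tolerance = 1e-12)
  # sinusoid: closed-form antiderivative, max error below 0.01 deg
  t <- seq(0, 10, by = 1 / fs)
  a <- integrate_angle(fake_sig(2 * pi * 10 * cos(2 * pi * t)))$alpha
  expect_lt(max(abs(a - 10 * sin(2 * pi * t))), 0.01)
})

test_that("detrend weights sum to one for any half-window", {
  for (q in c(1, 2, 5, 50, 100, 333))
    expect_equal(sum(detrend_weights(q)), 1, tolerance = 1e-15)
})

test_that("the moving-average detrend annihilates constants and linear drift", {
  fs <- 200; q <- 100
  t <- seq(0, 10, by = 1 / fs)
  ang <- fake_angle(rep(0, length(t)))
  ang$alpha <- rep(3.7, length(t))
  d <- detrend_angle(ang)
  expect_equal(d$trend, rep(3.7, length(t)), tolerance = 1e-12)
  expect_equal(max(abs(d$alpha_detrend)), 0, tolerance = 1e-12)

  ang$alpha <- 2 + 0.8 * t
  d <- detrend_angle(ang)
  interior <- (q + 2):(length(t) - q)
  expect_equal(max(abs(d$alpha_detrend[interior])), 0, tolerance = 1e-9)
})

test_that("detrend matches the brute-force weighted average on the interior", {
  fs <- 200; q <- 100
  t <- seq(0, 10, by = 1 / fs)
  ang <- fake_angle(rep(0, length(t)))
  ang$alpha <- 1.5 * t + 10 * sin(2 * pi * 1.0 * t)
  d <- detrend_angle(ang)
  interior <- (q + 2):(length(t) - q)
  expect_equal(d$trend[interior], detrend_oracle(ang$alpha, q),
               tolerance = 1e-12)

  # and on rough random input
  set.seed(7)
  ang2 <- fake_angle(rep(0, 1500))
  ang2$alpha <- cumsum(rnorm(1500))
  d2 <- detrend_angle(ang2)
  expect_equal(d2$trend[(q + 2):(1500 - q)], detrend_oracle(ang2$alpha, q),
               tolerance = 1e-12)
})

test_that("bouts shorter than the detrend window are rejected", {
  ang <- fake_angle(rnorm(150))
  ang$alpha <- ang$alpha_detrend
  expect_error(detrend_angle(ang), "too short")
})
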