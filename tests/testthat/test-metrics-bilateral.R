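test_that("asymmetry index follows its defining identity and antisymmetry", {
  expect_identical(asymmetry_index(20, 20), 0)     # identical arms -> 0 %
  expect_identical(asymmetry_index(57, 57), 0)
  expect_equal(asymmetry_index(20, 10), 50)
  expect_equal(asymmetry_index(10, 20), -50)
  expect_equal(abs(asymmetry_index(10, 20)), 50)
  set.seed(31)
  for (i in 1:20) {
    L <- runif(1, 1, 100); R <- runif(1, 1, 100)
    expect_equal(asymmetry_index(L, R), -asymmetry_index(R, L),
                 tolerance = 1e-12)
    expect_lte(abs(asymmetry_index(L, R)), 100)
  }
  expect_warning(bad <- asymmetry_index(0, 10), "positive")
  expect_true(is.na(bad))
})

test_that("simultaneity matches direction changes within 500 ms", {
  sw <- function(t0, len = 1) armswing:::swing_table(data.frame(
    t_start = t0, t_end = t0 + len, duration = len,
    amplitude = 20, peak_omega = 60, direction = "forward",
    i_start = 1L, i_end = 2L, ext_mag_start = 10, ext_mag_end = 10,
    retained = TRUE, reject_reason = "none"))
  # identical event times: everything simultaneous
  a <- sw(c(0, 2, 4))
  sim <- simultaneous_phases(a, a, tol = 0.5, bout_duration = 6)
  expect_true(all(sim$left_sim) && all(sim$right_sim))
  expect_equal(sim$pct_simultaneous, 50)   # union of [0,1],[2,3],[4,5] over 6 s

  # direction changes at {0, 2, 4} vs {0.6, 2.6, 4.6}: every offset > 0.5 s
  a2 <- sw(c(0, 2, 4), len = 0.05)
  b <- sw(c(0.6, 2.6, 4.6), len = 0.05)
  sim2 <- simultaneous_phases(a2, b, tol = 0.5, bout_duration = 6)
  expect_equal(sim2$pct_simultaneous, 0)

  # one empty side
  empty <- armswing:::swing_table(NULL)
  expect_equal(simultaneous_phases(a, empty, bout_duration = 6)$pct_simultaneous, 0)
})

test_that("percent simultaneous cannot exceed either arm's percent swing time", {
  g <- generate_recording(synth_preset("healthy_fast", duration = 30,
                                       amp_jitter_cv = 0.2, seed = 5))
  rep <- analyze_bout(g$left, g$right)
  expect_lte(rep$bilateral$pct_simultaneous,
             min(rep$arms$left$pct_swing_time,
                 rep$arms$right$pct_swing_time) + 1)
})

test_that("coordination is 1 for exactly anti-phase arms and ~0 for in-phase slow arms", {
  res <- analyze_arm(sine_rec(10, 0.9, duration = 60))
  sw <- res$swings[res$swings$retained, ]
  neg <- fake_sig(-res$sig$omega_swing)
  expect_equal(coordination(res$sig, neg, sw), 1, tolerance = 1e-6)

  # identical in-phase arms at 0.5 Hz: the +/- 0.5 s lag range only reaches a
  # quarter period, where the correlation of a sinusoid crosses zero
  res5 <- analyze_arm(sine_rec(20, 0.5, duration = 60))
  sw5 <- res5$swings[res5$swings$retained, ]
  expect_gte(nrow(sw5), 1)
  # the infinite-segment value is 0 (cos of a quarter period); finite 2-s
  # per-swing segments leave a residue, but far from the anti-phase score 1
  expect_lt(coordination(res5$sig, res5$sig, sw5), 0.3)
})

test_that("coordination of independent noise arms is low", {
  set.seed(41)
  sw <- armswing:::swing_table(data.frame(
    t_start = seq(1, 50, by = 1.1), t_end = seq(1, 50, by = 1.1) + 0.55,
    duration = 0.55, amplitude = 20, peak_omega = 60, direction = "forward",
    i_start = as.integer(seq(1, 50, by = 1.1) * 200),
    i_end = as.integer(seq(1, 50, by = 1.1) * 200 + 110),
    ext_mag_start = 10, ext_mag_end = 10,
    retained = TRUE, reject_reason = "none"))
  a <- fake_sig(rnorm(60 * 200 + 1))
  b <- fake_sig(rnorm(60 * 200 + 1))
  expect_lt(coordination(a, b, sw), 0.2)
})

test_that("coordination is invariant to positive rescaling of either arm", {
  res <- analyze_arm(sine_rec(10, 0.9, duration = 30))
  sw <- res$swings[res$swings$retained, ]
  other <- fake_sig(-0.5 * res$sig$omega_swing + 0)
  c1 <- coordination(res$sig, other, sw)
  c2 <- coordination(fake_sig(3 * res$sig$omega_swing), other, sw)
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_gte(c1, 0); expect_lte(c1, 1)
})

test_that("bilateral summary applies the 60% eligibility gate", {
  g <- generate_recording(synth_preset("healthy_fast", duration = 30))
  rep <- analyze_bout(g$left, g$right)
  expect_true(rep$bilateral$eligible)
  expect_gt(rep$bilateral$pct_simultaneous, 90)
  expect_false(is.na(rep$bilateral$coordination))

  # one arm swinging far below threshold: nothing simultaneous, gate closes
  quiet <- synth_config(duration = 30, amp_left = 18, amp_right = 1,
                        swing_freq = 0.9)
  g2 <- generate_recording(quiet)
  rep2 <- analyze_bout(g2$left, g2$right)
  expect_false(rep2$bilateral$eligible)
  expect_true(is.na(rep2$bilateral$asi_amplitude))
  expect_true(is.na(rep2$bilateral$coordination))
})

test_that("the bilateral amplitude asymmetry recovers the generated asymmetry", {
  g <- generate_recording(synth_config(duration = 60, swing_freq = 1.0,
                                       amp_left = 20, amp_right = 10))
  rep <- analyze_bout(g$left, g$right)
  expect_equal(g$truth$asi_amplitude, 50)
  expect_equal(rep$bilateral$asi_amplitude, 50, tolerance = 0.04)
})
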