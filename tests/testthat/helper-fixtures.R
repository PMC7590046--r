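# Fixtures are generated in code: sinusoidal swing bouts with known angle
# amplitude, plus direct constructors for mid-pipeline objects.

# recording whose swing-plane angle is A * sin(2*pi*f*t) (deg), i.e. the
# gyro swing-plane channel is the exact derivative, rotated about z by
# `mount` and optionally contaminated
sine_rec <- function(A, f, fs = 200, duration = 30, mount = 0,
                     z = 0, tremor_amp = 0, tremor_freq = 5, side = "left") {
  t <- seq(0, duration, by = 1 / fs)
  w <- A * 2 * pi * f * cos(2 * pi * f * t)
  trem <- if (tremor_amp > 0) tremor_amp * sin(2 * pi * tremor_freq * t) else 0
  gyro_recording(t, w * cos(mount) + trem, w * sin(mount),
                 rep_len(z, length(t)), fs = fs, side = side)
}

# fabricate an angle_signal directly from a detrended series
fake_angle <- function(xd, fs = 200) {
  structure(list(alpha = xd, trend = rep(0, length(xd)), alpha_detrend = xd,
                 fs = fs, t = seq(0, by = 1 / fs, length.out = length(xd)),
                 q = round(fs / 2)),
            class = "angle_signal")
}

# fabricate a swing_axis_signal from a series
fake_sig <- function(w, fs = 200) {
  structure(list(omega_swing = w, loadings = c(1, 0), sign_fixed = TRUE,
                 fs = fs, t = seq(0, by = 1 / fs, length.out = length(w)),
                 no_axis = all(w == 0)),
            class = "swing_axis_signal")
}

# brute-force symmetric moving average with the exact end-halved weights,
# interior samples only (independent oracle for detrend_angle)
detrend_oracle <- function(alpha, q) {
  n <- length(alpha)
  b <- c(1 / (4 * q), rep(1 / (2 * q), 2 * q - 1), 1 / (4 * q))
  sapply((q + 2):(n - q), function(i) sum(b * alpha[(i - q):(i + q)]))
}

# analytic squared single-pass magnitude of a second-order Butterworth
# applied forward and backward
butter2_zp_mag <- function(f, fc) 1 / (1 + (f / fc)^4)

# amplitude of the middle portion of a series (avoids filter edges)
mid_amp <- function(x) {
  n <- length(x)
  max(abs(x[round(n / 4):round(3 * n / 4)]))
}
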