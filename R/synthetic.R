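#' Configuration for the synthetic bilateral swing generator
#'
#' Describes a bilateral quasi-sinusoidal arm-swing bout plus the confounds
#' a wrist gyroscope sees in practice: constant bias drift on each axis,
#' white sensor noise, a tremor component above the low-pass cutoff,
#' longitudinal turning on the z-axis, an arbitrary sensor mounting rotation
#' about the forearm axis, left/right amplitude asymmetry, a phase offset
#' between arms, and per-half-cycle amplitude jitter.
#'
#' The swing angle of each arm is `A_k * sin(2*pi*f*t + phase)`, with the
#' half-amplitude `A_k` redrawn each half-cycle from a lognormal
#' distribution with mean `amp` and coefficient of variation
#' `amp_jitter_cv` (jitter at the zero crossings keeps the angle
#' continuous). The swing-plane angular velocity is the exact derivative,
#' distributed over the x and y channels by the mounting rotation.
#'
#' @param fs sampling rate, Hz.
#' @param duration bout length, s (>= 3).
#' @param swing_freq swing frequency, Hz.
#' @param amp_left,amp_right half-amplitude of the angle sinusoid per arm,
#'   deg (a half-cycle swing then has true amplitude `2 * amp`).
#' @param phase_offset phase of the right arm relative to the left, rad
#'   (`pi` = physiological anti-phase swinging).
#' @param mount_rotation rotation of the sensor about the forearm axis per
#'   arm, rad; length 1 or 2 (left, right).
#' @param gyro_bias constant bias per axis, deg/s (length 1 or 3).
#' @param noise_sd white noise standard deviation on every axis, deg/s.
#' @param tremor_freq,tremor_amp tremor sinusoid frequency (Hz) and
#'   amplitude (deg/s), added to the x channel.
#' @param turn_profile optional function of time (s) giving a z-axis
#'   angular-velocity turning bout, deg/s.
#' @param amp_jitter_cv coefficient of variation of per-half-cycle
#'   amplitudes (0 = strictly periodic).
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @return Object of class `synth_config` (validated list).
#' @export
synth_config <- function(fs = 200, duration = 60, swing_freq = 0.9,
                         amp_left = 18, amp_right = 18, phase_offset = pi,
                         mount_rotation = pi / 6, gyro_bias = 0,
                         noise_sd = 0, tremor_freq = 5, tremor_amp = 0,
                         turn_profile = NULL, amp_jitter_cv = 0, seed = 1L) {
  if (duration < 3) stop("invalid 'duration': need at least 3 s (one spectral window)")
  if (fs <= 2 * max(swing_freq, tremor_freq))
    stop("invalid 'fs': must exceed twice the swing and tremor frequencies")
  if (amp_left < 0 || amp_right < 0 || tremor_amp < 0 || noise_sd < 0 ||
      amp_jitter_cv < 0)
    stop("invalid amplitude parameter: amplitudes and noise must be >= 0")
  if (length(mount_rotation) == 1L) mount_rotation <- rep(mount_rotation, 2)
  if (length(gyro_bias) == 1L) gyro_bias <- rep(gyro_bias, 3)
  structure(list(fs = fs, duration = duration, swing_freq = swing_freq,
                 amp_left = amp_left, amp_right = amp_right,
                 phase_offset = phase_offset,
                 mount_rotation = mount_rotation, gyro_bias = gyro_bias,
                 noise_sd = noise_sd, tremor_freq = tremor_freq,
                 tremor_amp = tremor_amp, turn_profile = turn_profile,
                 amp_jitter_cv = amp_jitter_cv, seed = as.integer(seed)),
            class = "synth_config")
}

#' Preset generator configurations
#'
#' Three documented study conditions: `healthy_slow` and `healthy_fast`
#' bracket the amplitudes of healthy adults walking slowly (about 16 deg
#' swing amplitude) and briskly (about 36 deg) at the typical 0.9 Hz arm
#' swing frequency; `parkinsonian` has a reduced mean amplitude (about 17
#' deg averaged over arms), a ~36% left/right amplitude asymmetry, strong
#' per-cycle variability producing intermittent sub-threshold cycles, a
#' 5 Hz tremor component and more sensor noise.
#'
#' @param name one of `"healthy_slow"`, `"healthy_fast"`, `"parkinsonian"`.
#' @param ... overrides passed on to [synth_config()].
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("healthy_slow", "healthy_fast",
                                  "parkinsonian"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    healthy_slow = list(swing_freq = 0.9, amp_left = 8, amp_right = 8,
                        amp_jitter_cv = 0.08, noise_sd = 1),
    healthy_fast = list(swing_freq = 0.9, amp_left = 18, amp_right = 18,
                        amp_jitter_cv = 0.08, noise_sd = 1),
    parkinsonian = list(swing_freq = 0.9, amp_left = 10.4, amp_right = 6.65,
                        amp_jitter_cv = 0.35, noise_sd = 3,
                        tremor_freq = 5, tremor_amp = 10))
  do.call(synth_config, utils::modifyList(base, list(...)))
}

#' Generate a bilateral gyroscope recording with exact ground truth
#'
#' @param config a [synth_config()].
#' @return List with `left` and `right` [gyro_recording()]s and `truth`, an
#'   object of class `synth_truth` holding per-arm data frames of true
#'   swing events (`t_start`, `t_end`, `amplitude` = sum of the two
#'   bounding extremum magnitudes, `peak_omega` = largest swing-plane
#'   angular-velocity magnitude in the swing) plus the true amplitude
#'   asymmetry index and the phase offset.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = 1 / config$fs)
  arms <- list(
    left = synth_arm(t, config, config$amp_left, 0, config$mount_rotation[1]),
    right = synth_arm(t, config, config$amp_right, config$phase_offset,
                      config$mount_rotation[2]))
  tl <- arms$left$truth; tr <- arms$right$truth
  asi_amp <- if (nrow(tl) && nrow(tr))
    asymmetry_index(mean(tl$amplitude), mean(tr$amplitude)) else NA_real_
  truth <- structure(
    list(left = tl, right = tr, asi_amplitude = asi_amp,
         phase_offset = config$phase_offset,
         swing_freq = config$swing_freq),
    class = "synth_truth")
  list(left = arms$left$rec, right = arms$right$rec, truth = truth)
}

# one arm: exact piecewise-sinusoidal angle/velocity plus confounds
synth_arm <- function(t, cf, amp, phase, mount) {
  f <- cf$swing_freq
  ph <- 2 * pi * f * t + phase
  half <- floor(ph / pi)                     # half-cycle index per sample
  hrange <- min(half):max(half)
  n_half <- length(hrange)
  amps <- if (cf$amp_jitter_cv > 0 && amp > 0) {
    sdlog <- sqrt(log(1 + cf$amp_jitter_cv^2))
    stats::rlnorm(n_half, meanlog = log(amp) - sdlog^2 / 2, sdlog = sdlog)
  } else rep(amp, n_half)
  A <- amps[half - hrange[1] + 1L]
  omega_plane <- A * 2 * pi * f * cos(ph)
  n <- length(t)
  noise <- function() if (cf$noise_sd > 0) stats::rnorm(n, 0, cf$noise_sd) else numeric(n)
  tremor <- if (cf$tremor_amp > 0) cf$tremor_amp * sin(2 * pi * cf$tremor_freq * t)
            else numeric(n)
  turn <- if (is.null(cf$turn_profile)) numeric(n) else cf$turn_profile(t)
  rec <- gyro_recording(
    t = t,
    omega_x = omega_plane * cos(mount) + cf$gyro_bias[1] + tremor + noise(),
    omega_y = omega_plane * sin(mount) + cf$gyro_bias[2] + noise(),
    omega_z = turn + cf$gyro_bias[3] + noise(),
    fs = cf$fs)
  # truth: angle extrema at phase = pi/2 + k*pi, one per half-cycle
  k <- seq(ceiling((2 * pi * f * t[1] + phase - pi / 2) / pi),
           floor((2 * pi * f * t[n] + phase - pi / 2) / pi))
  t_ext <- (pi / 2 + k * pi - phase) / (2 * pi * f)
  h_ext <- floor((2 * pi * f * t_ext + phase) / pi)
  a_ext <- amps[h_ext - hrange[1] + 1L]
  truth <- if (length(t_ext) >= 2) {
    m <- length(t_ext)
    data.frame(t_start = t_ext[-m], t_end = t_ext[-1],
               amplitude = a_ext[-m] + a_ext[-1],
               peak_omega = 2 * pi * f * pmax(a_ext[-m], a_ext[-1]))
  } else data.frame(t_start = numeric(0), t_end = numeric(0),
                    amplitude = numeric(0), peak_omega = numeric(0))
  list(rec = rec, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d left / %d right swings @ %.2f Hz, amplitude ASI %.1f%%\n",
              nrow(x$left), nrow(x$right), x$swing_freq, x$asi_amplitude))
  invisible(x)
}
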