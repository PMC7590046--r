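---
title: "Quantifying arm swing from a wrist-worn gyroscope: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arm swing from a wrist-worn gyroscope: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armswing)
```

## The measurement problem

During walking, the arms swing rhythmically at roughly 1 Hz, mostly in the
sagittal plane. Reduced amplitude, left/right asymmetry and loss of
coordination of this swing are early and clinically meaningful markers in
movement disorders such as Parkinson's disease. A single gyroscope strapped
to each forearm can capture the swing continuously, but the raw signal
confounds the swing with sensor mounting orientation, integration drift,
turning of the body, tremor and noise. `armswing` turns that raw signal
into interpretable per-swing events and summary parameters.

An arm swing is treated as a rotational half-cycle of the arm with a
periodicity between 0.3 and 3 Hz and a minimum angular excursion of 5
degrees. The pipeline works entirely in deg/s and degrees.

## Pipeline

**Filtering.** Each axis passes through a second-order Butterworth low-pass
(3 Hz cutoff) applied forward and backward — zero phase, so extrema times
are preserved, at the cost of an effective fourth-order magnitude response.
Tremor (typically 4–6 Hz) and sensor noise are removed here. The R
`signal::filtfilt` applies no end-of-record transient handling, so the
series is extended by odd reflection at both ends (about `3 fs / cutoff`
samples) and trimmed after filtering; a constant input then passes exactly.

**Swing-axis projection.** Arm swing is a rotation about a transverse axis,
but the sensor's x/y axes sit at an arbitrary rotation about the forearm.
A principal component analysis of the mean-centred (x, y) channels finds
the swing direction; the projection onto the first component is the scalar
swing-direction angular velocity. The longitudinal z-axis is excluded
outright, which makes the pipeline exactly invariant to turning: adding any
z-axis content changes no downstream value by a single bit. PCA is computed
once per analyzed bout, and the channels are mean-centred first (standard
PCA; after the low-pass the means are near zero anyway, but the choice is
recorded here rather than left implicit). The principal direction's sign is
arbitrary, so it is fixed by convention — the larger-magnitude loading is
made positive, with ties resolved toward x. "Forward" and "backward" swing
labels inherit this convention; they are consistent within a recording but
are not an anatomical guarantee.

**Angle and detrending.** The swing angle is the cumulative trapezoidal
integral of the swing-direction angular velocity, starting at zero. Gyro
bias makes this drift, so a symmetric moving average with a window of
`2q + 1` samples, `q = round(fs / 2)` (1.005 s at 200 Hz), is subtracted.
The window's end weights are halved (`1/(4q)` at the ends, `1/(2q)`
inside), which makes the weights sum to exactly one and annihilates linear
drift exactly at interior samples. Near the bout edges the angle is
extended by edge replication so all series keep full length; the edge
region (first and last `q` samples) is the least trustworthy part of the
bout. Note the detrender is effectively a high-pass whose first null sits
at ~1 Hz: a 1 Hz swing passes essentially unattenuated (gain 1.0000 at
fs = 200), but slower swings are noticeably reduced — gain is about 0.89 at
0.9 Hz and 0.36 at 0.5 Hz. This is an inherent property of the published
operating point, not an implementation artifact, and it means measured
amplitudes of slow swings underestimate the physical excursion.

**Periodicity gating.** Three-second rectangular windows advancing by a
quarter window slide over the detrended angle. Per window, the discrete
Fourier spectrum yields the dominant non-DC frequency and the fraction of
non-DC power inside the closed band [0.3, 3] Hz. A window is valid when at
least 90% of its power is in-band and its dominant frequency is in-band.
The DC term is excluded from both numerator and denominator: the detrended
angle is near zero-mean and the gate is meant to measure periodicity, which
an arbitrary DC offset should not dilute. A 3-s rectangular window has a
frequency resolution of 1/3 Hz, so a 0.9 Hz swing reports the 1.0 Hz bin.
Trailing partial windows are dropped rather than zero-padded. Samples
covered by no valid window are excluded from event detection; if no window
is valid the bout has no periodic arm movement and no swing parameters are
produced.

**Extrema and swings.** Local maxima and minima of the detrended angle are
detected in 3-s windows with 50% overlap, each kind separately, requiring a
topographic prominence of at least 2 degrees and a minimum same-kind
separation of 60% of the window's own cycle time (from its dominant
frequency). Duplicate detections from overlapping windows are merged by
sample index; two same-kind detections closer than the distance rule are
taken to be one physical peak and the larger magnitude wins (the tie rule
is this package's choice). Alternation is then enforced: of two adjacent
same-kind extrema the smaller magnitude is discarded, repeatedly, so maxima
and minima strictly alternate. Consecutive extrema delimit swings; the
amplitude is the sum of the two bounding extremum magnitudes, and the peak
angular velocity is the largest-magnitude value of the swing-direction
angular velocity within the closed swing interval (earliest sample on an
exact tie — the text underdetermines this case, so the tie-break is
recorded here).

**Retention filters**, in order, first tripped reason recorded: swings
longer than twice the mean cycle time; swings whose bounding extremum
exceeds 3 times the 80th percentile (linear interpolation between order
statistics) of all detected extremum magnitudes — movements like scratching
the head; amplitude below 5 degrees; peak angular velocity below 10 deg/s.

**Per-arm parameters.** Mean amplitude and mean |peak angular velocity|
(overall, forward, backward) over retained swings; percent of the bout
covered by the union of retained swing intervals; frequency (mean dominant
frequency over valid windows); regularity.

**Regularity** is the mean over 4.5-s windows (99% overlap, i.e. a hop of
1% of the window — 9 samples at 200 Hz) of the maximum of the normalized
autocorrelation of the Tukey-tapered (cosine fraction 0.3) detrended angle.
Two choices need recording. First, the lag search range is
[1/3 s, 2.25 s]: every signal has autocorrelation 1 at lag 0, so lags
shorter than the fastest admissible swing period (1/3 s, from the 3 Hz band
edge) must be excluded for the maximum to mean anything; the upper limit is
half the window. Second, the normalization is the *unbiased* estimator
(`N/(N−m)` scaling relative to the lag-0 energy), the convention of the
stride-regularity autocorrelation literature this metric follows. The
biased estimator would cap a perfectly periodic 1 Hz signal at ~0.78
(shrinking linearly with lag), making the interpretation "1 = every swing
identical to its neighbours" unreachable; the unbiased estimator restores
it (0.993 measured on a pure 60-s sinusoid) at the cost of a bound that can
marginally exceed 1 on pathological segments, so the mean is clipped to
[0, 1].

**Bilateral parameters.** Direction changes are the bounding extremum times
of retained swings. A swing is *simultaneous* when any of its direction
changes falls within 500 ms of a direction change of the other arm;
percent-simultaneous is the union duration of simultaneous swings of both
arms over the bout. When at least 60% of the bout is simultaneous, the
asymmetry index `ASI = (L − R) / max(L, R) × 100` is computed for mean
amplitude and mean peak velocity over simultaneous swings only (0% =
symmetric; the magnitude is also reported), together with the coordination:
per simultaneous swing, the cross-correlation of the two arms' swing
velocities over the swing interval extended by 0.5 s on each side,
normalized by the root energies of the overlapping segments, is minimized
over lags of ±0.5 s; the score is |minimum| and coordination is the mean
score clipped to [0, 1]. Exactly anti-phase arms give exactly 1; the
symmetric ± lag reading of the lag range, and per-overlap normalization
(which keeps |r| ≤ 1 by Cauchy–Schwarz), are the recorded interpretation.
A caveat inherent to the definition: at swing frequencies ≥ 1 Hz the
±0.5 s lag range spans at least half a period, so in-phase and anti-phase
arms both score near 1.

Both arms must be on a synchronized common time base; the reader refuses
non-uniform time and performs no resampling.

## The synthetic generator

`generate_recording()` emulates what the pipeline needs to see without any
recorded data: per arm, an angle `A_k sin(2πft + φ)` whose half-amplitude
`A_k` is redrawn each half-cycle (lognormal, configurable CV — jitter at
zero crossings keeps the angle continuous and the ground truth exact), with
the swing-plane velocity as its exact derivative distributed over x/y by a
mounting rotation, plus constant bias, white noise, a tremor sinusoid above
the low-pass cutoff (5 Hz default), and an optional z-axis turning profile.
Ground truth (swing intervals, amplitudes as sums of bounding extremum
magnitudes, peak velocities, amplitude ASI) follows from the generating
equations to 1e-9.

Presets encode three study conditions at the typical 0.9 Hz swing
frequency: `healthy_slow` (~16° swing amplitude, as in slow healthy
walking), `healthy_fast` (~36°, brisk walking), and `parkinsonian`
(~17° averaged over arms, a 36% amplitude asymmetry, strong per-cycle
jitter, 5 Hz tremor, more noise). Amplitude values follow the published
group values for those conditions; jitter CVs (0.08 healthy, 0.35
parkinsonian) and noise levels (1 and 3 deg/s) are this package's choice of
realistic magnitudes.

What the generator does *not* emulate: pendulum biomechanics, double
support transients, stride-to-stride timing variability, gait initiation
and termination, sensor saturation. Passing the recovery tests therefore
shows the algorithm is internally consistent and robust to the modelled
confounds — not that it reproduces any particular clinical cohort.

## Numerical choices and degenerate inputs

- Sampling must be uniform to 1e-6 relative; fs ≥ 20 Hz; bouts ≥ 3 s.
- Missing-value runs up to 0.25 s are linearly interpolated on read; longer
  gaps abort with a gap report rather than fabricating signal.
- A motionless arm (no x/y variance) yields "no swing axis" and an empty
  swing list; a bout with no valid spectral window yields
  `no_periodic_movement` and no swing parameters.
- Flat spectra (constant windows) report no dominant frequency and a
  band-power fraction of 0.
- The extremum-outlier percentile uses linear interpolation (R type 7).
- Test and verification problem sizes are 20–60 s bouts at 200 Hz, with
  parameter sweeps over 37 amplitudes and ~100 frequencies; these sizes
  make every boundary measurable at the sweep grids' resolution.

## Known limitations

- Amplitudes of swings much slower than 1 Hz are attenuated by the ~1-s
  moving-average detrend (see above); comparisons across very different
  cadences inherit this bias. A consequence worth spelling out: for pure
  sinusoidal swings the 5° amplitude filter always binds before the
  10 deg/s velocity filter, at every amplitude/frequency combination —
  by the time a slow swing's detrended amplitude clears 5°, its peak
  velocity is already well above 10 deg/s.
- The 1/3 Hz spectral resolution quantizes the reported frequency.
- Walking-bout and turning detection are out of scope: the input is assumed
  to be a walking bout already.
- With a single sensor, simultaneity, asymmetry and coordination cannot be
  computed; the report says so explicitly.
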