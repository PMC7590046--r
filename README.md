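# armswing

Quantifies arm swing during walking from the raw 3-axis angular velocity of
a wrist- or forearm-worn gyroscope — for movement scientists and digital
biomarker work where reduced, asymmetric or poorly coordinated arm swing is
the signal of interest (most prominently in Parkinson's disease).

## What it computes

From each arm's gyroscope trace (deg/s, fixed rate, z-axis along the
forearm), the pipeline derives:

1. **Swing-direction angular velocity** ω<sub>PCA1</sub>: a zero-phase
   second-order Butterworth low-pass (3 Hz) on every axis, then the
   projection of the (x, y) channels onto their first principal component.
   The longitudinal z-axis is excluded, so body turns cannot contaminate
   the swing signal and the result is invariant to how the sensor is
   rotated about the forearm.
2. **Detrended swing angle** α<sub>detrend</sub> = α − m̂<sub>α</sub>:
   cumulative trapezoidal integration of ω<sub>PCA1</sub>, minus a ~1-s
   symmetric moving average (window 2q+1 samples, q = round(fs/2), end
   weights halved) that removes integration drift.
3. **Per-swing events**: sliding 3-s spectral windows gate the bout
   (≥ 90% of non-DC power in 0.3–3 Hz); angle extrema with prominence ≥ 2°
   and same-kind separation ≥ 60% of the cycle time delimit swings;
   retention requires duration ≤ 2 cycle times, no outlier extremum
   (> 3 × the 80th percentile), amplitude ≥ 5° and peak angular velocity
   ≥ 10 °/s.
4. **Per-arm parameters**: amplitude, peak angular velocity (overall /
   forward / backward), % of walk with swinging, frequency, regularity
   (windowed autocorrelation).
5. **Bilateral parameters**: % of walk with simultaneous swings
   (direction changes within 500 ms), the asymmetry index
   ASI = (L − R)/max(L, R) × 100 and the coordination (|minimum| of the
   normalized left–right cross-correlation over lags ±0.5 s), both
   computed only when ≥ 60% of the bout is simultaneous.

A synthetic bilateral generator with exact ground truth
(`generate_recording()`, presets `healthy_slow`, `healthy_fast`,
`parkinsonian`) and Bland–Altman style agreement statistics
(`agreement()`, `match_swings()`) make the whole pipeline verifiable
without any recorded data. See `vignettes/armswing-methods.Rmd` for the
model, its assumptions and the design choices.

## Worked example

```r
library(armswing)

g <- generate_recording(synth_preset("parkinsonian", seed = 7))
rep <- analyze_bout(g$left, g$right)
print(rep)
#> <armswing_report> status ok, 60.0 s @ 200 Hz
#> -- left arm --
#> <arm_summary>
#>   swings retained       107
#>   amplitude             19.1 deg
#>   peak angular velocity 64.1 deg/s (fwd 63.3 / bwd 64.8)
#>   % of walk swinging    99.0
#>   frequency             1.00 Hz
#>   regularity            0.94
#> -- right arm --
#> <arm_summary>
#>   swings retained       107
#>   amplitude             12.1 deg
#>   ...
#> <bilateral_summary>
#>   % simultaneous       99.0 (eligible: TRUE)
#>   ASI amplitude        36.7 % (|36.7|)
#>   ASI peak velocity    35.8 % (|35.8|)
#>   coordination         0.96
```

The left arm swings ~19° per half-cycle at ~64 °/s, the right arm markedly
less (12°, 41 °/s), giving a 36.7% amplitude asymmetry — recovering the
generator's configured 37% ground-truth asymmetry. Both arms swing
simultaneously for essentially the whole bout (eligible for bilateral
metrics), and the near-anti-phase rhythm yields a coordination of 0.96.
The reported 1.0 Hz frequency is the nearest 1/3 Hz spectral bin to the
generated 0.9 Hz swing.

Real recordings enter through `read_gyro_csv()` (CSV with time + x/y/z
columns; rad/s converted on request), then `analyze_bout(left, right)`.
`write_report()` / `write_swing_csv()` export the summary JSON and the
per-swing table. A thin command-line wrapper with `analyze`, `simulate`
and `validate` commands is installed at
`system.file("cli", "armswing.R", package = "armswing")`.

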