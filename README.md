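# spikesync

Offline synchronization of physiological recordings (EEG, EMG, and similar)
that were acquired on **independent device clocks**, using trains of
artificial fiducial pulses ("spikes") delivered to all devices.

## The problem

In mobile brain/body imaging, EEG and EMG are recorded by separate amplifiers
whose clocks only nominally agree. A relative sampling-rate discrepancy
δ between two "1000 Hz" devices makes them drift apart by δ·t: at δ = 10⁻⁴
that is 10 ms per 100 s — enough to invalidate brain–muscle connectivity
analyses, which are sensitive to shifts of about 10 ms. Clinical hardware
often provides no shared trigger port, no streaming API, and no spare
amplifier channels, so the only universally available strategy is to inject a
known analog pulse train into every device and align the recordings offline.

spikesync implements that strategy end to end:

* **Detect** the pulses in a raw analog trace with an amplitude threshold —
  either a percentile of the spike-free noise distribution (default: 99th) or
  a fraction of the maximum peak amplitude (5/10/20%, levels A/B/C).
* **Align** the detected onsets t to a reference event series r with an
  affine clock map `t_ref = a + b·t`:
  - **PRE–POST**: shift so the *median* misalignment of the first `n` pulses
    is zero, then linearly time-warp so the median over the last `n` pulses
    is zero (both medians are nulled exactly, not approximately);
  - **PRE-only**: shift only (`b = 1`), i.e. trust the manufacturers'
    nominal rates — useful precisely because it exposes how quickly that
    trust fails.
  Traces are then resampled onto the reference clock by linear interpolation.
* **Quantify** the residual misalignment `r − (a + b·t)` of the internal
  (non-anchor) pulses: mean, standard deviation (**jitter**), linear
  **trend** (ms/ms), **range**, and a Shapiro–Wilk Gaussianity verdict; plus
  planning bounds — maximum recording duration for a misalignment budget,
  required sampling-rate agreement `|f1 − f2| < tol/T`, and the maximum
  usable pulse rate `1/occupancy`.
* **Simulate** complete two-device sessions (`simulate_recording()`) with
  known clock offset, drift, per-pulse jitter, background noise and a
  hardware-filtered pulse waveform, so every estimator is validated against
  ground truth.

## Worked example

A 10-minute synthetic session at the canonical conditions — 1000 Hz, one
pulse every 2 s (300 pulses), clock drift 10⁻⁴, per-pulse jitter 1.7 ms,
0.01 mV background noise:

```r
library(spikesync)

rec <- simulate_recording(seed = 42)   # reference events + analog trace
det <- detect_pulses(rec$trace)        # 99th-percentile noise threshold
fit <- sync_fit(rec$events, det$onsets, method = "prepost", n_pre = 10, n_post = 10)
summary(fit)
#> Fiducial-pulse clock alignment
#>   method: prepost (n_pre = 10, n_post = 10), 300 paired pulses
#>   map:    t_ref = -0.000706826 + 0.999900871896 * t_local
#>   jitter (sd) 1.85 ms | range [-4.6, 4.44] ms | trend -1.34e-06 ms/ms
#>   anchor medians: PRE 0 ms, POST 1.14e-10 ms
#>   implied rate discrepancy: 9.91e-05 (relative)
#>   unmatched events: 0 reference, 0 target
#> <misalignment_report> 280 internal spikes
#>   mean -0.1258 ms | jitter (sd) 1.847 ms | range [-4.603, 4.439] ms
#>   trend -1.34e-06 ms/ms | sd about trend 1.837 ms
#>   Shapiro-Wilk W = 0.9929, p = 0.205 -> Gaussian at alpha = 0.05
```

Reading the output: the fitted scale `b = 0.99990…` recovers the injected
10⁻⁴ rate discrepancy; after the PRE–POST warp the 280 internal pulses sit
within a [−4.6, 4.4] ms band with 1.85 ms jitter (the injected 1.7 ms plus
detection effects) and essentially no remaining trend, and their distribution
passes the Gaussianity check. The anchor medians are zero by construction.

The same session aligned PRE-only shows why nominal rates cannot be trusted:

```r
pre <- sync_fit(rec$events, det$onsets, method = "pre", n_pre = 10)
abs(pre$report$trend)                      # 0.0001 ms/ms  (the clock drift)
time_to_misalignment(pre$report$trend, 10) # 99.8 s to accumulate 10 ms
estimate_max_duration(fit$report$trend, fit$report$jitter_sd, bound = 5)
#> 1030 s  -- PRE-POST-aligned recording stays in [-5, 5] ms for ~17 min
required_rate_precision(T = 600, tol = 1e-3)
#> 1.666667e-06  -- rate agreement (Hz) needed to hold 1 ms over 10 min
max_pulse_rate(0.2)
#> 5  -- pulses spread over 200 ms by the hardware filter cap the train rate
```

`sweep_anchor_n()` tabulates the misalignment for n = 1…10 anchors (with a
one-way ANOVA across groups), `sweep_detection_threshold()` re-runs detection
at the A/B/C thresholds, `resample_trace()` warps the raw trace onto the
reference clock, and `run_pipeline()` chains everything from a YAML/JSON
configuration. A thin command-line wrapper with `simulate`, `detect`,
`align`, `report` and `sweep` subcommands is installed at
`inst/cli/spikesync.R`.

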