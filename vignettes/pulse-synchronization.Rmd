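---
title: "Fiducial-pulse synchronization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-pulse synchronization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesync)
```

## The problem

Mobile brain/body imaging protocols record EEG and EMG (and other
physiological streams) on separate devices, each with its own clock and its
own *nominal* sampling rate. Two clocks nominally at 1000 Hz that truly differ
by a relative rate discrepancy $\delta$ drift apart by $\delta \cdot t$; at
$\delta = 10^{-4}$ that is 10 ms per 100 s — enough to corrupt brain–muscle
connectivity estimates, which are sensitive to shifts of the order of 10 ms.
When no shared trigger port, streaming API or common amplifier is available —
the common situation with certified clinical hardware — the fallback is to
inject an artificial *fiducial pulse train* into both devices and align the
recordings offline.

spikesync implements that fallback end to end:

1. **Detection** of the analog pulses in the raw trace
   (`detect_pulses()`, `detect_spikes()`, `estimate_noise_threshold()`).
2. **Alignment** of the detected onsets to the reference event series by an
   affine clock map $t_\mathrm{ref} = a + b\,t_\mathrm{local}$
   (`sync_fit()`, `fit_prepost_alignment()`, `fit_pre_alignment()`), and
   resampling of the trace onto the reference grid (`resample_trace()`).
3. **Quality metrics** on the residual misalignment of the internal pulses —
   jitter, trend, range, Gaussianity — plus planning bounds
   (`summarize_misalignment()`, `estimate_max_duration()`,
   `required_rate_precision()`, `max_pulse_rate()`).
4. A **synthetic-recording generator** with known ground truth
   (`simulate_recording()`), so the whole chain is testable without hardware.

## The alignment model

Let $r_1 < \dots < r_m$ be the paired reference onsets and $t_1 < \dots <
t_m$ the corresponding target onsets (pairing below). The *misalignment* of
pulse $i$ under a map $(a, b)$ is

$$ e_i(a,b) = r_i - (a + b\,t_i), $$

reported in milliseconds, positive when the target lags. The sign convention
is ours; all internal computation is in seconds and only reports are in ms.

**PRE–POST alignment** chooses $(a, b)$ so that the *median* of $e_i$ over
the first $n_\mathrm{pre}$ pairs is zero and the median over the last
$n_\mathrm{post}$ pairs is zero — first a shift nulls the PRE median, then a
linear time-warp nulls the POST median. Medians over several anchor pulses
(up to $n = 10$) make the anchors robust to the per-pulse detection jitter of
the analog stream. **PRE-only alignment** fixes $b = 1$ and nulls only the
PRE median; it stands for the strategy of trusting the manufacturers' nominal
rates, and any true rate discrepancy then appears as a near-linear residual
trend — `time_to_misalignment()` converts that trend into the time at which
cumulative desynchronization reaches a given bound.

### Why the solve is exact

Both anchor medians are piecewise-linear functions of $b$ (the ranking of
$r_i - b\,t_i$ changes only at isolated values of $b$), and their difference
is strictly monotone because the POST anchor times exceed the PRE anchor
times. The fit therefore iterates on the *median-achieving anchor points*:
given $b$, find the element (odd $n$) or pair of elements (even $n$)
achieving each median, solve the resulting two-anchor linear system in closed
form, and repeat until the active anchors are stable; a bracketing `uniroot`
step backs this up in the (rare) event of cycling. The result nulls both
anchor medians to floating-point precision — the test suite asserts
$< 10^{-12}$ s — rather than to the first-order approximation a fixed
anchor-time formula would give. With $n_\mathrm{pre} = n_\mathrm{post} = 1$
this reduces to making the first and last pulse coincide exactly.

Degenerate inputs are refused with classed errors: fewer pairs than anchors
(`insufficient_anchors`), coincident PRE/POST anchor times
(`degenerate_span`), fewer than 3 internal pulses (`insufficient_data`).

### Pairing

Events are matched one-to-one and order-preservingly after removing the
coarse offset (difference of first events). Among all monotone matchings with
per-pair lag at most `max_lag`, a dynamic program selects the one with the
largest pair count and, among those, the smallest total absolute lag; this is
the exact optimum of the matching criterion, computed in $O(mn)$, and spurious
or missing detections simply fall out as unmatched events. The default
`max_lag` of 1 s is half the canonical 2 s pulse period, which makes the
matching unambiguous for a clean train.

### Resampling

`resample_trace()` evaluates the trace at the pre-image times
$(t_\mathrm{out} - a)/b$ of a uniform reference-clock grid, by linear
interpolation. Fitting happens entirely in the event domain and the trace is
warped once afterwards, so interpolation error never contaminates the fit.
Output samples beyond the input span are zero-padded by default
(`edge = "crop"` drops them instead), and the output grid is aligned to
multiples of `1/out_rate` in the reference clock.

## Detection

The detector thresholds the deviation from baseline, where the baseline is
the median of the full trace — robust because pulses occupy a small fraction
of a sparse train. The default polarity is `absolute`, since the
hardware-filtered waveform swings to both polarities and its first excursion
is negative-going.

Two threshold rules are provided:

* **Noise percentile** (default): the 99th percentile of the *signed*
  deviation over the spike-free portions of the trace, found by a two-pass
  procedure (provisional detection at 50% of the global maximum deviation,
  excision of ±200 ms around each provisional onset, percentile of the rest).
  We use the signed rather than rectified deviation — on symmetric noise the
  rectified 99th percentile is systematically higher
  ($2.58\sigma$ vs $2.33\sigma$ for Gaussian noise); the choice is exposed in
  the documentation and the rectified variant is one `abs()` away.
* **Fraction of peak**: 5%, 10% or 20% of the maximum detected peak
  amplitude (levels A/B/C), for studying how threshold choice degrades
  timing.

**Debounce.** A percentile threshold exceeds, by construction, a fixed
fraction of noise-only samples (2% per sample for the absolute deviation at
the signed 99th percentile), so a literal first-crossing detector would fire
constantly between pulses and its refractory would then mask true onsets. A
crossing therefore only opens a pulse if the signal holds the threshold for
`min_above` (default 5 ms), and a pulse only closes after the signal stays
below threshold equally long — so the brief zero-crossing between the
waveform's trough and rebound does not split a pulse, and isolated noise
blips open nothing. At 5 samples and 1000 Hz the expected number of false
events in a 10-minute Gaussian-noise recording is
$6\times 10^5 \cdot 0.02^5 \approx 0.002$. The reported onset is the first
sample of the qualifying run (matching acquisition-grid resolution);
`interpolate = TRUE` refines it to the sub-sample linear crossing point.
`n_rejected` counts debounced onsets suppressed because they fell within the
200 ms refractory dead time of an accepted onset.

## Misalignment metrics

`summarize_misalignment()` reports, over the *internal* pulses (all matched
pulses excluding the PRE/POST anchors):

* `mean` and `jitter_sd` — the mean and sample standard deviation of the
  residuals; the standard deviation is the *jitter*.
* `trend` — the ordinary-least-squares slope of residual (ms) on elapsed
  time (ms), in ms/ms. OLS is the minimal choice for a quantity that is
  displayed and read off as a linear drift; the scatter about the fitted
  line is reported alongside (`resid_about_line_sd`).
* `range` — min and max residual.
* a Shapiro–Wilk Gaussianity verdict at $\alpha = 0.05$, computed on at most
  `max_test_n = 5000` residuals (seeded subsample above that; the test is
  unreliable at larger sizes). Constant residuals skip the test with a
  degenerate flag.

`compare_groups()` wraps the classical one-way ANOVA
(`stats::oneway.test(var.equal = TRUE)`) for comparing residual sets across
settings such as $n = 1,\dots,10$; `sweep_anchor_n()` builds that table. The
type-I error rate of the comparison is verified by simulation in the test
suite.

`estimate_max_duration()` converts a trend and a jitter level into a maximum
recording duration, $T_{\max} = (\mathrm{bound} - z\,\sigma)/|\mathrm{trend}|$:
the misalignment budget is first charged $z$ standard deviations for jitter
(default $z = 1.96$, two-sided 95% coverage) and the remainder is spent by
drift. The reservation term is our formalization — exposed and configurable —
of the informal practice of keeping the *whole* residual distribution inside
the admissible band; `time_to_misalignment()` is the same arithmetic with no
jitter reserve.

## The synthetic generator

`simulate_recording()` emulates the two-device protocol under a
`clock_model`: the target clock starts `offset` seconds after the reference
and runs fast by $1+\delta$, so a reference-time event $s$ is recorded at
local time $(s - \mathrm{offset})(1+\delta) + \varepsilon$, with
$\varepsilon \sim N(0, \sigma_j^2)$ i.i.d. per pulse. Defaults are the
canonical study conditions: 1000 Hz, one pulse every 2 s for 600 s
(300 pulses), 3.2 mV pulse scale (a 3 mV figure also circulates for the same
setup; we use the text value), background noise of 0.01 mV, $\delta =
10^{-4}$ (the regime in which nominal-rate alignment accumulates 10 ms of
error within about 100 s) and $\sigma_j = 1.7$ ms (the jitter scale a
well-executed session exhibits). Gaussian per-pulse jitter is consistent with
residual distributions that pass their Gaussianity check.

The waveform template reproduces the observed post-filter morphology
explicitly rather than by filtering a rectangle, because the morphology — not
the front end's transfer function — is what is actually reported for such
hardware: a negative-going descent over 50 ms (a brief steep dip to −0.09 by
1 ms, then a shallow decline to −0.85), a 3 ms drop to −1, a 3 ms bounce to
+1, an exponential settle below 1% of peak by 150 ms, and exact zero beyond
the 200 ms occupancy. A first-order high-pass alternative
(`shape = "highpass"`) is provided for sensitivity checks. The 200 ms
occupancy is what caps the usable pulse rate at 5 Hz
(`max_pulse_rate(0.2)`), and the generator refuses overlapping trains.

The two-leg descent is a deliberate mechanism, not decoration: a 5% threshold
crosses the steep initial leg, giving sub-millisecond, amplitude-insensitive
onset delays, while 10% and 20% thresholds cross the shallow leg, where the
±20% slow sinusoidal amplitude modulation (one cycle per session,
`amplitude_drift`) translates into several milliseconds of systematic
onset-delay variation. This reproduces, with realistic effect sizes, the
characteristic degradation of jitter, range and trend as the detection
threshold rises. The sine phase is chosen so the modulation has a nonzero
linear component over the session, which is what couples threshold level to
the residual *trend*.

Timing and sample noise come from two independently seeded streams, so one
can be varied while the other is held fixed; identical seeds give
bit-identical recordings.

**What the generator does not emulate:** physiological signal content (gait
cycles, cortical rhythms, movement artifacts), non-Gaussian or non-stationary
noise, waveform *shape* changes over time (only amplitude scaling), nonlinear
clock wander, and dropped samples. Tests passing on this generator therefore
demonstrate correctness of the estimators under the stated clock model, not
robustness to every pathology of real hardware; the quantile-based detector
and median-based anchors are expected, but not here proven, to tolerate
moderate departures.

## Numerical and design choices

* Exact active-set median solve for PRE–POST (above); `uniroot` fallback at
  tolerance `.Machine$double.eps^0.75`.
* Pairing ties (equal total lag) resolve by preferring skip-reference over
  skip-target in the DP backtrack; with continuous timing noise ties are
  measure-zero.
* Event-domain fitting; single trace warp afterwards.
* Onsets at sample resolution by default; the threshold-sweep and
  jitter-recovery validations enable sub-sample interpolation so that
  threshold effects are not confounded with the ±0.5 ms quantization noise of
  the 1 kHz grid.
* Empty event series pair to an empty pairing with a warning; an all-zero
  trace yields a degenerate zero threshold; detection on a crossing-free
  trace returns an empty result rather than an error.
* Report serialization keeps full double precision
  (`jsonlite`, `digits = NA`); CSV writers use 17 significant digits so
  round trips are lossless.

## Problem sizes in the test suite

The suite validates on the full canonical session (600 s, 1000 Hz,
300 pulses; the complete pipeline runs in roughly a second), 100-seed
replicate loops for drift recovery in the event domain ($\delta \in \{10^{-5},
10^{-4}, 10^{-3}\}$), 1000 replicates for the ANOVA type-I error rate, and
50-event series for brute-force oracle comparisons (grid-search alignment
oracle, exhaustive monotone-matching oracle). These sizes were chosen so each
statistical check has the power it needs while the suite stays comfortably
interactive.

## Limitations

* The time-warp is strictly affine; slow nonlinear clock wander leaves a
  structured residual (visible as a trend or curvature) that this package
  measures but does not correct. Piecewise or spline warping is out of scope.
* Pairwise streams only; multi-stream merging is the caller's composition.
* No template-matching detection: amplitude thresholds are the point of the
  method, and waveform non-stationarity would undermine a fixed template.
* Whether a reference system quantizes its event stamps to the sample grid
  varies by vendor; rather than assume, the generator exposes
  `quantize_reference` and the estimators are validated under both settings.
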