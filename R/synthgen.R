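#' Clock model for a synthetic target device
#'
#' Ground-truth relation between the reference clock and the target device
#' clock. The target clock starts `offset` seconds after the reference clock
#' and runs fast by a factor `1 + drift`, so a reference time `t` reads
#' `(t - offset) * (1 + drift)` on the target clock. Each recorded pulse onset
#' additionally receives i.i.d. Gaussian timing noise of standard deviation
#' `jitter_sd`.
#'
#' Defaults place the generator in the regime a 10-minute two-device session
#' typically exhibits: a relative rate discrepancy of 1e-4 (a 10e-5 ms/ms
#' trend, 60 ms of drift over 10 min) and 1.7 ms per-pulse jitter.
#'
#' @param offset target clock start minus reference clock start (s).
#' @param drift relative rate discrepancy (dimensionless); `1 + drift > 0`.
#' @param jitter_sd per-pulse timing jitter (s), >= 0.
#' @return A list of class `clock_model`.
#' @export
clock_model <- function(offset = 0, drift = 1e-4, jitter_sd = 1.7e-3) {
  if (1 + drift <= 0) sync_error("1 + drift must be positive", "invalid_argument")
  if (jitter_sd < 0) sync_error("jitter_sd must be non-negative", "invalid_argument")
  structure(list(offset = offset, drift = drift, jitter_sd = jitter_sd),
            class = "clock_model")
}

#' Hardware-filtered pulse waveform template
#'
#' Piecewise-smooth emulation of what a short square pulse looks like after a
#' high-passed analog front end: a negative-going descent lasting
#' `descent_duration` — a brief steep initial leg to `knee_level` by
#' `knee_frac * descent_duration`, then a shallow slow decline to
#' `shoulder_level` — followed by a sharp drop to the trough (-1 normalized),
#' a bounce to +1, and an exponential settle to below 1% of peak by
#' `settle_by`, identically zero beyond `occupancy`. Peak absolute value is 1
#' before mV scaling. Low detection thresholds cross the steep initial leg
#' (sub-millisecond, amplitude-insensitive onset delay); higher thresholds
#' cross the shallow leg, where the slow amplitude modulation translates into
#' several milliseconds of onset-delay spread — the mechanism by which higher
#' thresholds inflate jitter, range and trend.
#'
#' `amplitude_drift` applies one slow sinusoidal cycle of multiplicative
#' amplitude modulation across the session (default +-20%), emulating the
#' observed variation of recorded pulse amplitude over a recording.
#'
#' `shape = "highpass"` swaps in a first-order high-pass filtered rectangle of
#' width `pulse_width` and time constant `hp_tau`, for sensitivity checks
#' against the explicit piecewise morphology.
#'
#' @param descent_duration slow-descent duration (s).
#' @param knee_frac position of the descent knee as a fraction of
#'   `descent_duration`.
#' @param knee_level,shoulder_level,trough_level,rebound_level normalized
#'   levels (trough < 0 < rebound).
#' @param drop_duration,rebound_duration durations (s) of the sharp drop and
#'   the bounce.
#' @param settle_by time (s) by which the settle falls below 1% of peak.
#' @param occupancy total time (s) the waveform deviates from baseline.
#' @param peak_mv amplitude scale (mV).
#' @param amplitude_drift depth of the slow sinusoidal amplitude modulation.
#' @param shape `"piecewise"` (default) or `"highpass"`.
#' @param hp_tau,pulse_width high-pass time constant and source pulse width
#'   (s), used by `shape = "highpass"`.
#' @return A list of class `waveform_template`.
#' @export
waveform_template <- function(descent_duration = 0.05, knee_frac = 0.02,
                              knee_level = -0.09, shoulder_level = -0.85,
                              trough_level = -1, rebound_level = 1,
                              drop_duration = 0.003, rebound_duration = 0.003,
                              settle_by = 0.15, occupancy = 0.2,
                              peak_mv = 3.2, amplitude_drift = 0.2,
                              shape = c("piecewise", "highpass"),
                              hp_tau = 0.03, pulse_width = 0.004) {
  shape <- match.arg(shape)
  if (trough_level >= 0 || rebound_level <= 0)
    sync_error("levels must bracket 0 (trough < 0 < rebound)", "invalid_argument")
  if (descent_duration < 0 || drop_duration < 0 || rebound_duration <= 0)
    sync_error("segment durations must be non-negative (rebound positive)",
               "invalid_argument")
  t_peak <- descent_duration + drop_duration + rebound_duration
  if (!(occupancy > settle_by && settle_by > t_peak))
    sync_error("need occupancy > settle_by > descent + drop + rebound",
               "invalid_argument")
  structure(list(descent_duration = descent_duration, knee_frac = knee_frac,
                 knee_level = knee_level, shoulder_level = shoulder_level,
                 trough_level = trough_level, rebound_level = rebound_level,
                 drop_duration = drop_duration,
                 rebound_duration = rebound_duration,
                 settle_by = settle_by, occupancy = occupancy,
                 peak_mv = peak_mv, amplitude_drift = amplitude_drift,
                 shape = shape, hp_tau = hp_tau, pulse_width = pulse_width),
            class = "waveform_template")
}

# continuous normalized waveform as a vectorized function of time since onset
waveform_fun <- function(template) {
  tp <- template
  if (tp$shape == "highpass") {
    w <- tp$pulse_width; tau <- tp$hp_tau
    drop <- 1 - exp(-w / tau)
    return(function(t) {
      v <- numeric(length(t))
      i1 <- t >= 0 & t < w
      i2 <- t >= w & t < tp$occupancy
      v[i1] <- exp(-t[i1] / tau)
      v[i2] <- -drop * exp(-(t[i2] - w) / tau)
      v
    })
  }
  d <- tp$descent_duration
  t_knee <- tp$knee_frac * d
  t2 <- d
  t3 <- d + tp$drop_duration
  t4 <- t3 + tp$rebound_duration
  tau <- (tp$settle_by - t4) / log(abs(tp$rebound_level) / 0.01)
  norm <- max(abs(tp$trough_level), abs(tp$rebound_level))
  function(t) {
    v <- numeric(length(t))
    if (d > 0) {
      i1 <- t >= 0 & t < t_knee
      v[i1] <- tp$knee_level * t[i1] / t_knee
      i2 <- t >= t_knee & t < t2
      v[i2] <- tp$knee_level +
        (tp$shoulder_level - tp$knee_level) * (t[i2] - t_knee) / (t2 - t_knee)
      i3 <- t >= t2 & t < t3
      v[i3] <- tp$shoulder_level +
        (tp$trough_level - tp$shoulder_level) * (t[i3] - t2) / (t3 - t2)
    } else {
      # degenerate immediate drop: the waveform opens at the trough
      i3 <- t >= 0 & t < t3
      v[i3] <- tp$trough_level
      if (t3 == 0) {
        i0 <- t == 0
        v[i0] <- tp$trough_level
      }
    }
    i4 <- t >= t3 & t < t4
    v[i4] <- tp$trough_level +
      (tp$rebound_level - tp$trough_level) * (t[i4] - t3) / (t4 - t3)
    i5 <- t >= t4 & t < tp$occupancy
    v[i5] <- tp$rebound_level * exp(-(t[i5] - t4) / tau)
    v / norm
  }
}

#' Render the pulse waveform at a sampling rate
#'
#' Evaluates the continuous waveform template at `0, 1/rate, 2/rate, ...` over
#' its occupancy. Because rendering samples a continuous function, renders at
#' refined rates agree exactly with coarser renders at shared sample times.
#'
#' @param template a [waveform_template()].
#' @param rate sampling rate (Hz), > 0.
#' @return Numeric vector of normalized amplitudes (`occupancy * rate`
#'   samples, peak absolute value 1).
#' @export
render_waveform <- function(template, rate) {
  stopifnot(inherits(template, "waveform_template"))
  if (rate <= 0) sync_error("rate must be positive", "invalid_argument")
  n <- as.integer(round(template$occupancy * rate))
  if (n < 4)
    sync_error("fewer than 4 samples across the waveform occupancy: rate too low",
               "resolution_error")
  waveform_fun(template)((0:(n - 1)) / rate)
}

#' Additive background-noise model
#'
#' @param sd standard deviation of the additive white Gaussian background
#'   noise (mV), >= 0.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd = 0.01) {
  if (sd < 0) sync_error("noise sd must be non-negative", "invalid_argument")
  structure(list(sd = sd), class = "noise_model")
}

#' Generate a paired synthetic recording
#'
#' Simulates the full two-device protocol: a reference device annotates one
#' event per delivered pulse (every `period` seconds), while a target device
#' records an analog trace on its own clock containing the hardware-filtered
#' pulse waveform at drifted, jittered onset times plus background noise.
#' The returned ground truth carries everything needed for parameter-recovery
#' tests.
#'
#' Two independently seeded random streams are used (pulse timing, sample
#' noise), so one can be held fixed while the other varies; identical seeds
#' give bit-identical output.
#'
#' @param train a [pulse_train_spec()].
#' @param clock a [clock_model()].
#' @param wave a [waveform_template()].
#' @param noise a [noise_model()].
#' @param rate nominal sampling rate of both devices (Hz).
#' @param quantize_reference if `TRUE`, reference event times are quantized to
#'   the `1/rate` grid (some acquisition software stores events on the sample
#'   grid); default `FALSE` keeps them exact.
#' @param seed integer seed.
#' @return A list of class `sync_recording`: `events` (reference
#'   [event_series()]), `trace` (target [sampled_trace()]), `truth` (list with
#'   `pulse_times_reference`, `pulse_times_target_clock`, `offset`, `drift`,
#'   `jitter`, `amplitude_factor`, `seed`).
#' @export
simulate_recording <- function(train = pulse_train_spec(),
                               clock = clock_model(),
                               wave = waveform_template(),
                               noise = noise_model(),
                               rate = 1000, quantize_reference = FALSE,
                               seed = 1L) {
  stopifnot(inherits(train, "pulse_train_spec"), inherits(clock, "clock_model"),
            inherits(wave, "waveform_template"), inherits(noise, "noise_model"))
  if (rate <= 0) sync_error("rate must be positive", "invalid_argument")
  if (train$period <= wave$occupancy)
    sync_error("pulse period must exceed the waveform occupancy (pulses would overlap)",
               "overlap_error")
  n_pulse <- as.integer(floor(train$session_duration / train$period))
  with_local_seed(seed, {
    stream_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

    ref_exact <- (seq_len(n_pulse) - 1) * train$period
    ref <- if (quantize_reference) round(ref_exact * rate) / rate else ref_exact

    jitter <- with_local_seed(stream_seeds[1], {
      if (clock$jitter_sd > 0) stats::rnorm(n_pulse, 0, clock$jitter_sd)
      else numeric(n_pulse)
    })
    local_onsets <- (ref_exact - clock$offset) * (1 + clock$drift) + jitter

    n_samp <- as.integer(round(train$session_duration * rate))
    values <- with_local_seed(stream_seeds[2], {
      if (noise$sd > 0) stats::rnorm(n_samp, 0, noise$sd) else numeric(n_samp)
    })
    amp_factor <- 1 + wave$amplitude_drift *
      sin(2 * pi * ref_exact / train$session_duration)
    wf <- waveform_fun(wave)
    for (k in seq_len(n_pulse)) {
      on <- local_onsets[k]
      i0 <- max(1L, as.integer(ceiling(on * rate)) + 1L)
      i1 <- min(n_samp, as.integer(floor((on + wave$occupancy) * rate)) + 1L)
      if (i1 < i0) next
      tt <- (seq.int(i0, i1) - 1) / rate - on
      values[i0:i1] <- values[i0:i1] + wave$peak_mv * amp_factor[k] * wf(tt)
    }
    structure(list(
      events = event_series(ref, clock_label = "reference"),
      trace = sampled_trace(values, rate_nominal = rate, start_time = 0,
                            label = "target"),
      truth = list(pulse_times_reference = ref_exact,
                   pulse_times_target_clock = local_onsets,
                   offset = clock$offset, drift = clock$drift,
                   jitter = jitter, amplitude_factor = amp_factor,
                   seed = as.integer(seed), stream_seeds = stream_seeds)),
      class = "sync_recording")
  })
}

#' @export
print.sync_recording <- function(x, ...) {
  cat(sprintf("<sync_recording> %d pulses; drift %g, jitter sd %g s, seed %d\n",
              length(x$events$times), x$truth$drift,
              stats::sd(c(x$truth$jitter, 0)), x$truth$seed))
  print(x$trace)
  invisible(x)
}
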