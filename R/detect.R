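#' Pulse-detection configuration
#'
#' Two thresholding modes are supported. `"noise_percentile"` uses a
#' percentile (default the 99th) of the signed deviation from baseline over
#' the pulse-free portions of the trace, estimated by [estimate_noise_threshold()].
#' `"fraction_of_peak"` uses a fraction of the maximum detected peak amplitude
#' (conventionally 5 / 10 / 20 %, labelled A / B / C), via [fraction_threshold()].
#'
#' `min_above` is a debounce: a threshold crossing only opens a pulse if the
#' signal stays at or above threshold for this long, and a pulse only ends
#' once the signal stays below threshold for the same duration. Without it, a
#' percentile threshold fires by construction on a fixed fraction of
#' noise-only samples. Set `min_above = 0` for the literal first-crossing
#' rule.
#'
#' @param mode thresholding mode (see Details).
#' @param percentile percentile (0-100, exclusive) of the spike-free deviation
#'   distribution, for `"noise_percentile"`.
#' @param fraction fraction (0-1, exclusive) of maximum peak amplitude, for
#'   `"fraction_of_peak"`.
#' @param refractory dead time after an accepted onset (s); crossings of new
#'   pulses within it are suppressed and counted.
#' @param polarity which deviation from baseline is thresholded: `"absolute"`
#'   (default; hardware-filtered pulses swing both ways and the first
#'   excursion is negative-going), `"positive"` or `"negative"`.
#' @param min_above debounce duration (s); see Details.
#' @param bootstrap_frac provisional threshold for the first pass of
#'   [estimate_noise_threshold()], as a fraction of the global maximum
#'   absolute deviation.
#' @param excise_halfwidth half-width (s) of the window excised around each
#'   provisional pulse when estimating the noise threshold; defaults to the
#'   200 ms waveform occupancy.
#' @param interpolate if `TRUE`, onsets are refined to sub-sample resolution
#'   by linear interpolation between the bracketing samples; by default the
#'   onset is the threshold-crossing sample time.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(mode = c("noise_percentile", "fraction_of_peak"),
                             percentile = 99, fraction = 0.05,
                             refractory = 0.2,
                             polarity = c("absolute", "positive", "negative"),
                             min_above = 0.005, bootstrap_frac = 0.5,
                             excise_halfwidth = 0.2, interpolate = FALSE) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (percentile <= 0 || percentile >= 100)
    sync_error("percentile must lie strictly between 0 and 100", "invalid_argument")
  if (fraction <= 0 || fraction >= 1)
    sync_error("fraction must lie strictly between 0 and 1", "invalid_argument")
  if (refractory <= 0)
    sync_error("refractory must be positive", "invalid_argument")
  if (min_above < 0 || bootstrap_frac <= 0 || bootstrap_frac >= 1 ||
      excise_halfwidth <= 0)
    sync_error("invalid detection configuration", "invalid_argument")
  structure(list(mode = mode, percentile = percentile, fraction = fraction,
                 refractory = refractory, polarity = polarity,
                 min_above = min_above, bootstrap_frac = bootstrap_frac,
                 excise_halfwidth = excise_halfwidth,
                 interpolate = isTRUE(interpolate)),
            class = "detection_config")
}

polarity_signal <- function(values, baseline, polarity) {
  dev <- values - baseline
  switch(polarity,
         absolute = abs(dev),
         positive = dev,
         negative = -dev)
}

#' Estimate the noise-percentile detection threshold
#'
#' Two-pass estimate of the configured percentile of the signed deviation from
#' baseline over the *spike-free* portions of a trace: (1) provisional
#' detection at a high bootstrap threshold (a fraction of the global maximum
#' absolute deviation); (2) excision of a window of `excise_halfwidth` on
#' either side of each provisional onset; (3) the percentile of
#' `amplitude - baseline` over the remaining samples, where the baseline is
#' the median of the full trace. The percentile is of the signed deviation;
#' a rectified (absolute-deviation) percentile would be systematically higher
#' on symmetric noise.
#'
#' @param trace a non-empty [sampled_trace()].
#' @param config a [detection_config()].
#' @return Threshold in mV. An all-zero (flat) trace returns 0 with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
estimate_noise_threshold <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (length(trace$values) == 0)
    sync_error("cannot estimate a noise threshold from an empty trace",
               "invalid_argument")
  baseline <- median(trace$values)
  dev <- trace$values - baseline
  peak <- max(abs(dev))
  if (peak == 0) {
    warning("flat trace: noise threshold is degenerate (0)")
    return(structure(0, degenerate = TRUE))
  }
  boot <- config$bootstrap_frac * peak
  prov <- detect_spikes(trace, config, threshold = boot)
  keep <- rep(TRUE, length(trace$values))
  if (length(prov$onsets$times) > 0) {
    rate <- trace$rate_nominal
    half <- config$excise_halfwidth
    for (on in prov$onsets$times) {
      i0 <- max(1L, floor((on - half - trace$start_time) * rate) + 1L)
      i1 <- min(length(keep), ceiling((on + half - trace$start_time) * rate) + 1L)
      if (i1 >= i0) keep[i0:i1] <- FALSE
    }
  }
  if (mean(keep) <= 0.05)
    sync_error("pulse excision removed >= 95% of samples: train too dense for the trace length",
               "noise_estimation_error")
  unname(stats::quantile(dev[keep], config$percentile / 100, type = 7))
}

#' Detect pulse onsets by amplitude threshold
#'
#' Scans the polarity-selected deviation from baseline (median of the full
#' trace) for threshold crossings. An onset is the time of the first sample at
#' or above threshold of a debounced excursion (see [detection_config()]);
#' onsets of new pulses within the refractory dead time of the previous
#' accepted onset are suppressed and counted in `n_rejected`. The per-pulse
#' peak amplitude is the maximum deviation within the refractory window after
#' the onset.
#'
#' @param trace a [sampled_trace()].
#' @param config a [detection_config()].
#' @param threshold detection threshold (mV), > 0.
#' @return A list of class `detection_result`: `onsets` ([event_series()]),
#'   `threshold_used`, `peak_amplitudes`, `n_rejected`, `baseline`.
#' @export
detect_spikes <- function(trace, config = detection_config(), threshold) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (!is_finite_num(threshold) || length(threshold) != 1 || threshold <= 0)
    sync_error("threshold must be a single positive number", "invalid_argument")
  n <- length(trace$values)
  rate <- trace$rate_nominal
  empty <- function() structure(
    list(onsets = event_series(numeric(0), clock_label = trace$label),
         threshold_used = threshold, peak_amplitudes = numeric(0),
         n_rejected = 0L, baseline = if (n > 0) median(trace$values) else NA_real_),
    class = "detection_result")
  if (n == 0) return(empty())
  baseline <- median(trace$values)
  sig <- polarity_signal(trace$values, baseline, config$polarity)
  above <- sig >= threshold
  if (!any(above)) return(empty())
  runs <- rle(above)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  m_deb <- max(1L, as.integer(round(config$min_above * rate)))
  refr_n <- as.integer(round(config$refractory * rate))

  onset_idx <- integer(0)
  n_rejected <- 0L
  last_onset <- -Inf
  active <- FALSE
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k]) {
      if (!active && runs$lengths[k] >= m_deb) {
        i <- run_start[k]
        t_i <- trace$start_time + (i - 1) / rate
        if (t_i - last_onset >= config$refractory) {
          onset_idx <- c(onset_idx, i)
          last_onset <- t_i
        } else {
          n_rejected <- n_rejected + 1L
        }
        active <- TRUE
      }
      # sub-debounce blips while idle are ignored; continuation while active
    } else if (active && runs$lengths[k] >= m_deb) {
      active <- FALSE
    }
  }
  if (length(onset_idx) == 0) return(empty())

  onset_t <- trace$start_time + (onset_idx - 1) / rate
  if (config$interpolate) {
    adj <- vapply(onset_idx, function(i) {
      if (i <= 1L) return(0)
      d <- sig[i] - sig[i - 1L]
      if (d <= 0) return(0)
      frac <- (threshold - sig[i - 1L]) / d
      (max(0, min(1, frac)) - 1) / rate
    }, numeric(1))
    onset_t <- onset_t + adj
  }
  peaks <- vapply(onset_idx, function(i) {
    max(sig[i:min(n, i + refr_n - 1L)])
  }, numeric(1))
  structure(list(onsets = event_series(onset_t, clock_label = trace$label),
                 threshold_used = threshold, peak_amplitudes = peaks,
                 n_rejected = n_rejected, baseline = baseline),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d onsets (threshold %.4g mV, %d rejected by refractory)\n",
              length(x$onsets$times), x$threshold_used, x$n_rejected))
  invisible(x)
}

#' Fraction-of-peak threshold
#'
#' Threshold at a fraction of the maximum detected peak amplitude, for the
#' conventional 5% (A) / 10% (B) / 20% (C) threshold sweep.
#'
#' @param result a [detect_spikes()] result with at least one pulse.
#' @param fraction fraction of the maximum peak amplitude (0-1, exclusive).
#' @return Threshold in mV.
#' @export
fraction_threshold <- function(result, fraction) {
  stopifnot(inherits(result, "detection_result"))
  if (fraction <= 0 || fraction >= 1)
    sync_error("fraction must lie strictly between 0 and 1", "invalid_argument")
  if (length(result$peak_amplitudes) < 1)
    sync_error("no detected pulses: cannot take a fraction of the peak amplitude",
               "invalid_argument")
  fraction * max(result$peak_amplitudes)
}

#' Detect pulses end-to-end under a configuration
#'
#' Convenience wrapper chaining threshold estimation and detection. For
#' `mode = "noise_percentile"` the threshold is the noise-percentile estimate;
#' for `mode = "fraction_of_peak"` a provisional pass at the bootstrap
#' threshold (`bootstrap_frac` of the global maximum absolute deviation)
#' measures peak amplitudes, then detection is re-run at `fraction * max(peak)`.
#'
#' @param trace a [sampled_trace()].
#' @param config a [detection_config()].
#' @return A [detect_spikes()] result.
#' @export
detect_pulses <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (config$mode == "noise_percentile") {
    thr <- estimate_noise_threshold(trace, config)
    if (isTRUE(attr(thr, "degenerate")))
      sync_error("flat trace: no pulses to detect", "noise_estimation_error")
    return(detect_spikes(trace, config, threshold = as.numeric(thr)))
  }
  peak <- max(abs(trace$values - median(trace$values)))
  if (peak == 0)
    sync_error("flat trace: no pulses to detect", "noise_estimation_error")
  prov <- detect_spikes(trace, config, threshold = config$bootstrap_frac * peak)
  detect_spikes(trace, config, threshold = fraction_threshold(prov, config$fraction))
}
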