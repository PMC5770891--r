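#' @keywords internal
"_PACKAGE"

# classed error helper so callers can condition on failure modes
sync_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spikesync_error", "error")))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' Uniformly sampled analog trace
#'
#' Container for a single-channel analog recording in its own device clock.
#' Sample `k` (1-based) lies at time `start_time + (k - 1) / rate_nominal`.
#' The rate is the *nominal* (manufacturer-advertised) sampling rate; the true
#' rate in another device's clock may differ, which is exactly the clock drift
#' this package estimates and corrects.
#'
#' @param values numeric vector of amplitudes (mV); all finite.
#' @param rate_nominal nominal sampling rate (Hz), > 0.
#' @param start_time time of the first sample in the local clock (s).
#' @param label free-text channel/device label.
#' @return An object of class `sampled_trace`.
#' @seealso [event_series()], [resample_trace()], [detect_spikes()]
#' @export
sampled_trace <- function(values, rate_nominal, start_time = 0, label = "") {
  values <- as.numeric(values)
  if (!is_finite_num(values) && length(values) > 0)
    sync_error("trace amplitudes must all be finite", "invalid_argument")
  if (!is_finite_num(rate_nominal) || length(rate_nominal) != 1 || rate_nominal <= 0)
    sync_error("rate_nominal must be a single positive number", "invalid_argument")
  if (!is_finite_num(start_time) || length(start_time) != 1)
    sync_error("start_time must be a single finite number", "invalid_argument")
  structure(
    list(values = values, rate_nominal = as.numeric(rate_nominal),
         start_time = as.numeric(start_time), label = as.character(label)[1]),
    class = "sampled_trace"
  )
}

#' Sample times of a trace
#'
#' @param trace a [sampled_trace()].
#' @return numeric vector of sample times (s, local clock).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$start_time + (seq_along(trace$values) - 1) / trace$rate_nominal
}

#' @export
print.sampled_trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<sampled_trace> %s: %d samples @ %g Hz, t = [%g, %g] s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n, x$rate_nominal, x$start_time,
              if (n > 0) x$start_time + (n - 1) / x$rate_nominal else x$start_time))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$values)

#' Ordered series of pulse-onset times
#'
#' Event onsets (s) in one device clock, strictly increasing. This is the form
#' in which an EEG system exports annotated trigger events, and the form
#' returned by pulse detection on an analog trace.
#'
#' @param times strictly increasing numeric vector of onset times (s); may be
#'   empty.
#' @param clock_label free-text label of the clock/device the times live in.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, clock_label = "") {
  times <- as.numeric(times)
  if (length(times) > 0) {
    if (!is_finite_num(times))
      sync_error("event times must all be finite", "invalid_argument")
    if (length(times) > 1 && any(diff(times) <= 0))
      sync_error("event times must be strictly increasing", "invalid_argument")
  }
  structure(list(times = times, clock_label = as.character(clock_label)[1]),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<event_series> %s: %d events%s\n",
              if (nzchar(x$clock_label)) x$clock_label else "(unlabelled)", n,
              if (n > 0) sprintf(", t = [%g, %g] s", x$times[1], x$times[n]) else ""))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

#' Pulse-train delivery specification
#'
#' Describes the fiducial-pulse protocol: one short pulse every `period`
#' seconds for `session_duration` seconds. Defaults match a 10-minute session
#' with a 4 ms, 3.2 mV pulse every 2 s (300 pulses).
#'
#' @param period inter-pulse interval (s).
#' @param pulse_width electrical pulse width at the source (s).
#' @param pulse_amplitude source pulse amplitude (mV).
#' @param session_duration total recording duration (s).
#' @return A list of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(period = 2, pulse_width = 0.004,
                             pulse_amplitude = 3.2, session_duration = 600) {
  if (period <= 0 || pulse_width <= 0 || session_duration <= 0)
    sync_error("period, pulse_width and session_duration must be positive",
               "invalid_argument")
  structure(list(period = period, pulse_width = pulse_width,
                 pulse_amplitude = pulse_amplitude,
                 session_duration = session_duration),
            class = "pulse_train_spec")
}
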