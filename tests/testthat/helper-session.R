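# Shared synthetic sessions, generated once per test run.
.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache)) {
    assign(key, force(expr), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# the canonical 10-min, 1000 Hz, 300-pulse session at the default study
# conditions (drift 1e-4, jitter 1.7 ms, noise 0.01 mV)
default_session <- function() cached("default42", simulate_recording(seed = 42))

default_detection <- function() {
  cached("det42", detect_pulses(default_session()$trace))
}

# event-domain synthetic target series (no trace rendering): the ground-truth
# drifted/jittered onsets, for fast alignment-level tests
event_domain_target <- function(rec) {
  event_series(rec$truth$pulse_times_target_clock, clock_label = "target (truth)")
}
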