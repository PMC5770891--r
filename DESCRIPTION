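Package: spikesync
Title: Fiducial-Pulse Synchronization of Independently Clocked Physiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline synchronization of physiological data streams (for example
    EEG and EMG) recorded on independent device clocks, using trains of
    artificial fiducial pulses delivered to both devices. Detects analog
    synchronization pulses in a raw trace with percentile or fraction-of-peak
    amplitude thresholds, aligns the stream to a reference event series by a
    median-anchored shift plus linear time-warp (PRE-POST alignment) or a
    shift-only PRE alignment, linearly resamples traces onto the reference
    clock, and quantifies residual misalignment (jitter, trend, range,
    Gaussianity) together with recording-planning bounds on duration, sampling
    rate precision and pulse rate. Includes a synthetic-recording generator
    with known clock drift, per-pulse jitter and a hardware-filtered pulse
    waveform for validation without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
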