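#' Default run configuration
#'
#' Nested configuration for the full simulate-detect-align-report chain,
#' mirroring the component constructors field for field. Unknown keys in a
#' user configuration are rejected by [validate_run_config()].
#'
#' @param seed integer seed for the simulation.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    rate = 1000,
    quantize_reference = FALSE,
    train = unclass(pulse_train_spec()),
    clock = unclass(clock_model()),
    wave = unclass(waveform_template()),
    noise = unclass(noise_model()),
    detect = unclass(detection_config()),
    align = list(method = "prepost", n_pre = 10, n_post = 10, max_lag = 1),
    stat = unclass(stat_config()),
    sweep = list(n = NULL, fractions = NULL)
  ), class = "run_config")
}

#' Validate and complete a run configuration
#'
#' Merges a (possibly partial) nested list over [default_run_config()],
#' rejecting unknown keys at any level.
#'
#' @param cfg nested list.
#' @return A complete `run_config`.
#' @export
validate_run_config <- function(cfg) {
  template <- default_run_config()
  merge <- function(tmpl, user, where) {
    if (is.null(user)) return(tmpl)
    if (!is.list(user))
      sync_error(sprintf("config section '%s' must be a mapping", where),
                 "invalid_argument")
    unknown <- setdiff(names(user), names(tmpl))
    if (length(unknown) > 0)
      sync_error(sprintf("unknown config key%s in '%s': %s",
                         if (length(unknown) > 1) "s" else "", where,
                         paste(unknown, collapse = ", ")),
                 "invalid_argument")
    for (nm in names(user)) {
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]]))) {
        tmpl[[nm]] <- merge(tmpl[[nm]], user[[nm]], paste0(where, "$", nm))
      } else {
        tmpl[[nm]] <- user[[nm]]
      }
    }
    tmpl
  }
  out <- merge(unclass(template), unclass(cfg), "config")
  if (out$align$method == "prepost" &&
      (out$align$n_pre < 1 || out$align$n_post < 1))
    sync_error("prepost alignment needs n_pre >= 1 and n_post >= 1",
               "invalid_argument")
  if (out$align$method == "pre" && out$align$n_pre < 1)
    sync_error("pre alignment needs n_pre >= 1", "invalid_argument")
  structure(out, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                sync_error(sprintf("unsupported config extension '.%s'", ext),
                           "format_error"))
  validate_run_config(cfg)
}

config_objects <- function(cfg) {
  list(train = do.call(pulse_train_spec, cfg$train),
       clock = do.call(clock_model, cfg$clock),
       wave = do.call(waveform_template, cfg$wave),
       noise = do.call(noise_model, cfg$noise),
       detect = do.call(detection_config, cfg$detect),
       stat = do.call(stat_config, cfg$stat))
}

#' Sweep the number of anchor spikes
#'
#' Re-fits the alignment for each `n` (used both PRE and POST) and tabulates
#' the misalignment summary; a one-way ANOVA across the residual groups is
#' attached as attribute `"anova"`.
#'
#' @param reference,target [event_series()] objects.
#' @param n integer vector of anchor counts.
#' @param max_lag pairing tolerance (s).
#' @param stat a [stat_config()].
#' @return data.frame with one row per `n`.
#' @export
sweep_anchor_n <- function(reference, target, n = 1:10, max_lag = 1,
                           stat = stat_config()) {
  fits <- lapply(n, function(k)
    sync_fit(reference, target, method = "prepost", n_pre = k, n_post = k,
             max_lag = max_lag, stat = stat))
  tab <- do.call(rbind, lapply(seq_along(n), function(i) {
    r <- fits[[i]]$report
    data.frame(n = n[i], n_internal = r$n_internal,
               mean_ms = r$mean, abs_mean_ms = abs(r$mean),
               jitter_ms = r$jitter_sd, trend_ms_per_ms = r$trend,
               range_lo_ms = r$range[1], range_hi_ms = r$range[2],
               shapiro_p = r$shapiro_p)
  }))
  attr(tab, "anova") <- compare_groups(lapply(fits, function(f) f$report$residuals),
                                       stat)
  tab
}

#' Sweep the detection threshold fraction
#'
#' Re-detects pulse onsets at each fraction-of-peak threshold (conventionally
#' 5/10/20%, labelled A/B/C), re-fits the alignment, and tabulates detection
#' delay and misalignment summaries.
#'
#' @param trace target [sampled_trace()].
#' @param reference reference [event_series()].
#' @param fractions numeric vector of peak fractions.
#' @param config a [detection_config()] (its `fraction` field is overridden).
#' @param n_pre,n_post,max_lag alignment settings.
#' @param stat a [stat_config()].
#' @return data.frame with one row per fraction.
#' @export
sweep_detection_threshold <- function(trace, reference,
                                      fractions = c(0.05, 0.10, 0.20),
                                      config = detection_config(mode = "fraction_of_peak"),
                                      n_pre = 10, n_post = 10, max_lag = 1,
                                      stat = stat_config()) {
  peak <- max(abs(trace$values - median(trace$values)))
  prov <- detect_spikes(trace, config, threshold = config$bootstrap_frac * peak)
  labels <- if (length(fractions) <= 26) LETTERS[seq_along(fractions)]
            else as.character(seq_along(fractions))
  rows <- lapply(seq_along(fractions), function(i) {
    thr <- fraction_threshold(prov, fractions[i])
    det <- detect_spikes(trace, config, threshold = thr)
    fit <- sync_fit(reference, det$onsets, method = "prepost",
                    n_pre = n_pre, n_post = n_post, max_lag = max_lag,
                    stat = stat)
    # raw detection delay (onset minus reference event), before alignment;
    # shared clock offset/drift cancels when comparing fractions
    pt <- paired_times(reference, det$onsets, fit$pairing)
    r <- fit$report
    data.frame(label = labels[i], fraction = fractions[i], threshold_mv = thr,
               n_detected = length(det$onsets$times),
               mean_delay_s = mean(pt$t - pt$r),
               jitter_ms = r$jitter_sd, trend_ms_per_ms = r$trend,
               range_lo_ms = r$range[1], range_hi_ms = r$range[2],
               range_width_ms = diff(r$range))
  })
  do.call(rbind, rows)
}

#' Run the full synchronization pipeline
#'
#' Chains simulate, detect, align and report under one configuration, with
#' optional anchor-count and threshold sweeps, and optionally writes the
#' report JSON and sweep CSVs to a directory.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]); partial lists are completed and validated.
#' @param out_dir optional output directory (created if needed).
#' @return A list of class `sync_run`: `recording`, `detection`, `fit`,
#'   `report` (schema of [report_schema()]), `n_sweep`, `threshold_sweep`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  cfg <- validate_run_config(config)
  obj <- config_objects(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sync_error(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 "pipeline_error")
    })
  }
  rec <- stage("simulate", simulate_recording(
    train = obj$train, clock = obj$clock, wave = obj$wave, noise = obj$noise,
    rate = cfg$rate, quantize_reference = isTRUE(cfg$quantize_reference),
    seed = cfg$seed))
  det <- stage("detect", detect_pulses(rec$trace, obj$detect))
  fit <- stage("align", sync_fit(
    rec$events, det$onsets,
    method = if (cfg$align$method == "pre") "pre" else "prepost",
    n_pre = cfg$align$n_pre, n_post = cfg$align$n_post,
    max_lag = cfg$align$max_lag, stat = obj$stat))
  report <- report_schema(fit)
  n_sweep <- NULL
  if (!is.null(cfg$sweep$n))
    n_sweep <- stage("sweep_n", sweep_anchor_n(
      rec$events, det$onsets, n = cfg$sweep$n, max_lag = cfg$align$max_lag,
      stat = obj$stat))
  thr_sweep <- NULL
  if (!is.null(cfg$sweep$fractions))
    thr_sweep <- stage("sweep_threshold", sweep_detection_threshold(
      rec$trace, rec$events, fractions = cfg$sweep$fractions,
      config = obj$detect, n_pre = cfg$align$n_pre, n_post = cfg$align$n_post,
      max_lag = cfg$align$max_lag, stat = obj$stat))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    if (!is.null(n_sweep))
      utils::write.csv(n_sweep, file.path(out_dir, "n_sweep.csv"),
                       row.names = FALSE)
    if (!is.null(thr_sweep))
      utils::write.csv(thr_sweep, file.path(out_dir, "threshold_sweep.csv"),
                       row.names = FALSE)
  }
  structure(list(recording = rec, detection = det, fit = fit, report = report,
                 n_sweep = n_sweep, threshold_sweep = thr_sweep),
            class = "sync_run")
}

#' @export
print.sync_run <- function(x, ...) {
  cat("<sync_run>\n")
  print(x$fit)
  invisible(x)
}
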