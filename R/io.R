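fmt17 <- function(x) sprintf("%.17g", x)

#' Read and write event CSV files
#'
#' Events are stored as a single-column CSV with header `time_s`, one onset
#' per row, strictly increasing. Writing uses 17 significant digits so that
#' a write/read round trip reproduces the doubles exactly.
#'
#' @param path file path.
#' @param series an [event_series()].
#' @param clock_label label attached to the series on read.
#' @return `read_events` returns an [event_series()]; `write_events` returns
#'   `path` invisibly.
#' @export
read_events <- function(path, clock_label = basename(path)) {
  lines <- readLines(path)
  if (length(lines) == 0) return(event_series(numeric(0), clock_label))
  if (trimws(lines[1]) != "time_s")
    sync_error(sprintf("expected header 'time_s' in %s, found '%s'", path, lines[1]),
               "format_error")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(event_series(numeric(0), clock_label))
  times <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(times))
  if (length(bad) > 0)
    sync_error(sprintf("non-numeric event time at data row %d of %s", bad[1], path),
               "format_error")
  if (length(times) > 1) {
    nm <- which(diff(times) <= 0)
    if (length(nm) > 0)
      sync_error(sprintf("event times not strictly increasing at data row %d of %s",
                         nm[1] + 1L, path), "format_error")
  }
  event_series(times, clock_label)
}

#' @rdname read_events
#' @export
write_events <- function(series, path) {
  stopifnot(inherits(series, "event_series"))
  writeLines(c("time_s", fmt17(series$times)), path)
  invisible(path)
}

trace_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read and write trace CSV files
#'
#' Two dialects are supported. The explicit-time dialect has columns
#' `time_s,amplitude_mv` with a uniform time grid (the rate is derived from
#' the step). The implicit-grid dialect has a single `amplitude_mv` column and
#' a JSON sidecar (`<path minus extension>.json`) with fields `rate_hz`,
#' `start_time_s` and `label`. Values round trip exactly at 17 significant
#' digits.
#'
#' @param path CSV file path.
#' @param sidecar sidecar path for the implicit dialect; defaults to the CSV
#'   path with a `.json` extension.
#' @param rate optional expected rate (Hz); an error names both values if the
#'   file disagrees.
#' @param trace a [sampled_trace()].
#' @param dialect which dialect to write.
#' @return `read_trace` returns a [sampled_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, sidecar = NULL, rate = NULL) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (identical(names(df), c("time_s", "amplitude_mv"))) {
    tt <- df$time_s
    if (length(tt) < 2)
      sync_error("explicit-time trace needs at least 2 samples", "format_error")
    steps <- diff(tt)
    step <- stats::median(steps)
    if (step <= 0 || any(abs(steps - step) > 1e-6 * step))
      sync_error(sprintf("non-uniform time steps in %s: cannot infer a sampling rate",
                         path), "format_error")
    file_rate <- 1 / step
    if (!is.null(rate) && abs(file_rate - rate) > 1e-6 * rate)
      sync_error(sprintf("rate mismatch: file %s implies %g Hz but %g Hz was requested",
                         path, file_rate, rate), "format_error")
    return(sampled_trace(df$amplitude_mv, file_rate, start_time = tt[1],
                         label = basename(path)))
  }
  if (identical(names(df), "amplitude_mv")) {
    sc_path <- if (is.null(sidecar)) trace_sidecar_path(path) else sidecar
    if (!file.exists(sc_path))
      sync_error(sprintf("implicit-grid trace %s requires sidecar %s (missing)",
                         path, sc_path), "format_error")
    sc <- jsonlite::fromJSON(sc_path)
    if (is.null(sc$rate_hz))
      sync_error(sprintf("sidecar %s lacks rate_hz", sc_path), "format_error")
    if (!is.null(rate) && abs(sc$rate_hz - rate) > 1e-6 * rate)
      sync_error(sprintf("rate mismatch: sidecar %s says %g Hz but %g Hz was requested",
                         sc_path, sc$rate_hz, rate), "format_error")
    return(sampled_trace(df$amplitude_mv, sc$rate_hz,
                         start_time = if (is.null(sc$start_time_s)) 0 else sc$start_time_s,
                         label = if (is.null(sc$label)) basename(path) else sc$label))
  }
  sync_error(sprintf("unrecognized trace columns in %s: %s", path,
                     paste(names(df), collapse = ",")), "format_error")
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, dialect = c("implicit", "explicit"),
                        sidecar = NULL) {
  stopifnot(inherits(trace, "sampled_trace"))
  dialect <- match.arg(dialect)
  if (dialect == "explicit") {
    writeLines(c("time_s,amplitude_mv",
                 paste(fmt17(trace_times(trace)), fmt17(trace$values), sep = ",")),
               path)
  } else {
    writeLines(c("amplitude_mv", fmt17(trace$values)), path)
    sc_path <- if (is.null(sidecar)) trace_sidecar_path(path) else sidecar
    jsonlite::write_json(list(rate_hz = trace$rate_nominal,
                              start_time_s = trace$start_time,
                              label = trace$label),
                         sc_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a report as JSON
#'
#' Numbers are serialized at full double precision.
#'
#' @param report a list (e.g. from [run_pipeline()] or [report_schema()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Structured report from a fitted alignment
#'
#' Flattens a [sync_fit()] into the canonical report structure:
#' `model` (a, b, method, n_pre, n_post), `metrics` (mean_ms, jitter_ms,
#' trend_ms_per_ms, range_ms, shapiro), and `n_internal`.
#'
#' @param fit a [sync_fit()] object.
#' @return A nested list ready for [write_report_json()].
#' @export
report_schema <- function(fit) {
  stopifnot(inherits(fit, "sync_fit"))
  r <- fit$report
  list(model = list(a = fit$model$a, b = fit$model$b,
                    method = fit$model$method,
                    n_pre = fit$model$n_pre, n_post = fit$model$n_post),
       metrics = list(mean_ms = r$mean, jitter_ms = r$jitter_sd,
                      trend_ms_per_ms = r$trend,
                      range_ms = c(r$range[1], r$range[2]),
                      shapiro = list(stat = r$shapiro_stat, p = r$shapiro_p,
                                     gaussian = r$is_gaussian)),
       anchors = fit$anchors,
       n_internal = r$n_internal)
}
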