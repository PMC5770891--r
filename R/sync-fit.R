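#' Fit a clock alignment between two event streams
#'
#' The central fitting function of the package: given a reference event series
#' (e.g. EEG trigger annotations) and a target series (e.g. pulse onsets
#' detected in an EMG trace), it pairs the events, fits the affine clock map
#' (PRE-POST shift + linear time-warp, or PRE-only shift), and summarizes the
#' residual misalignment of the internal spikes.
#'
#' @param reference an [event_series()] in the reference clock.
#' @param target an [event_series()] in the target clock.
#' @param method `"prepost"` (shift so the median misalignment of the first
#'   `n_pre` pulses is zero, then warp so the median over the last `n_post` is
#'   zero) or `"pre"` (shift only, relying on nominal sampling rates).
#' @param n_pre,n_post number of leading/trailing anchor pulses.
#' @param max_lag pairing tolerance (s); default 1, half the canonical 2 s
#'   pulse period.
#' @param stat a [stat_config()].
#' @return An object of class `sync_fit` with components `model`
#'   ([alignment_model()]), `pairing`, `report` ([summarize_misalignment()]
#'   output), `anchors` (achieved PRE/POST anchor medians, ms), `mapped_target`
#'   and the input series. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' rec <- simulate_recording(seed = 7)
#' det <- detect_pulses(rec$trace)
#' fit <- sync_fit(rec$events, det$onsets)
#' fit
#' coef(fit)
#' @export
sync_fit <- function(reference, target, method = c("prepost", "pre"),
                     n_pre = 10, n_post = n_pre, max_lag = 1,
                     stat = stat_config()) {
  method <- match.arg(method)
  pairing <- pair_events(reference, target, max_lag)
  model <- if (method == "prepost") {
    fit_prepost_alignment(reference, target, pairing,
                          n_pre = n_pre, n_post = n_post)
  } else {
    fit_pre_alignment(reference, target, pairing, n = n_pre)
  }
  mapped <- transform_events(target, model)
  pt <- paired_times(reference, mapped, pairing)
  m <- length(pt$r)
  pre_med <- median((pt$r - pt$t)[seq_len(model$n_pre)]) * 1000
  post_med <- if (model$n_post > 0) {
    median((pt$r - pt$t)[seq.int(m - model$n_post + 1, m)]) * 1000
  } else NA_real_
  ms <- misalignment_series(reference, mapped, pairing, model)
  report <- summarize_misalignment(ms$times, ms$residuals, stat)
  structure(list(model = model, pairing = pairing, report = report,
                 anchors = list(pre_median_ms = pre_med,
                                post_median_ms = post_med),
                 reference = reference, target = target,
                 mapped_target = mapped, call = match.call()),
            class = "sync_fit")
}

#' @export
print.sync_fit <- function(x, ...) {
  cat("Fiducial-pulse clock alignment\n")
  cat(sprintf("  method: %s (n_pre = %d, n_post = %d), %d paired pulses\n",
              x$model$method, x$model$n_pre, x$model$n_post,
              n_pairs(x$pairing)))
  cat(sprintf("  map:    t_ref = %.6g + %.12g * t_local\n",
              x$model$a, x$model$b))
  cat(sprintf("  jitter (sd) %.3g ms | range [%.3g, %.3g] ms | trend %.3g ms/ms\n",
              x$report$jitter_sd, x$report$range[1], x$report$range[2],
              x$report$trend))
  invisible(x)
}

#' @export
summary.sync_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.sync_fit")
}

#' @export
print.summary.sync_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  anchor medians: PRE %.3g ms, POST %s ms\n",
              f$anchors$pre_median_ms,
              if (is.na(f$anchors$post_median_ms)) "-"
              else sprintf("%.3g", f$anchors$post_median_ms)))
  cat(sprintf("  implied rate discrepancy: %.3g (relative)\n", 1 / f$model$b - 1))
  cat(sprintf("  unmatched events: %d reference, %d target\n",
              f$pairing$n_unmatched_reference, f$pairing$n_unmatched_target))
  print(f$report)
  invisible(x)
}

#' @export
coef.sync_fit <- function(object, ...) {
  c(offset = object$model$a, scale = object$model$b)
}

#' Map times through a fitted alignment
#'
#' @param object a [sync_fit()] object.
#' @param newdata numeric times or an [event_series()] in the target clock;
#'   defaults to the target series used in the fit.
#' @param ... unused.
#' @return Times in the reference clock, in the same form as `newdata`.
#' @export
predict.sync_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$target
  if (inherits(newdata, "event_series"))
    return(transform_events(newdata, object$model))
  object$model$a + object$model$b * as.numeric(newdata)
}

#' @export
fitted.sync_fit <- function(object, ...) {
  object$mapped_target$times[object$pairing$pairs[, "target"]]
}

#' @export
residuals.sync_fit <- function(object, ...) {
  structure(object$report$residuals, times = object$report$times)
}

#' Plot residual misalignment against time
#'
#' @param x a [sync_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sync_fit <- function(x, ...) {
  r <- x$report
  graphics::plot(r$times, r$residuals, pch = 16, cex = 0.5,
                 xlab = "reference time (s)", ylab = "misalignment (ms)",
                 main = sprintf("%s alignment: jitter %.2g ms",
                                x$model$method, r$jitter_sd), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(h = r$range, col = "red", lty = 2)
  el <- (r$times - r$times[1]) * 1000
  graphics::lines(r$times, r$mean + r$trend * (el - mean(el)), col = "blue")
  invisible(x)
}
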