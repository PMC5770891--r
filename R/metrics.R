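#' Statistical configuration for misalignment summaries
#'
#' @param alpha significance level for the Shapiro-Wilk Gaussianity verdict
#'   and the ANOVA comparison (default 0.05).
#' @param max_test_n cap on the Shapiro-Wilk sample size (default 5000;
#'   common implementations are unreliable above that). Larger residual sets
#'   are subsampled without replacement, reproducibly via `seed`.
#' @param seed seed for the subsampling stream.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, max_test_n = 5000, seed = 1L) {
  if (alpha <= 0 || alpha >= 1)
    sync_error("alpha must lie strictly between 0 and 1", "invalid_argument")
  if (max_test_n < 3)
    sync_error("max_test_n must be at least 3", "invalid_argument")
  structure(list(alpha = alpha, max_test_n = as.integer(max_test_n),
                 seed = as.integer(seed)),
            class = "stat_config")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-pulse misalignment of the internal spikes
#'
#' Residual misalignment `reference - mapped target` (ms) for every matched
#' pulse *excluding* the `n_pre` leading and `n_post` trailing anchor pulses
#' used to fit the model. Only these internal ("middle") spikes carry
#' information about residual desynchronization; the anchors are zero-median
#' by construction.
#'
#' @param reference [event_series()] of reference onsets.
#' @param mapped_target [event_series()] of target onsets *already mapped*
#'   through the alignment model (see [transform_events()]).
#' @param pairing the [pair_events()] matching used for the fit.
#' @param model the fitted [alignment_model()] (supplies `n_pre`, `n_post`).
#' @return A list with `times` (reference-clock times, s) and `residuals`
#'   (ms), positive when the target lags the reference.
#' @export
misalignment_series <- function(reference, mapped_target, pairing, model) {
  stopifnot(inherits(model, "alignment_model"))
  pt <- paired_times(reference, mapped_target, pairing)
  m <- length(pt$r)
  lo <- model$n_pre + 1L
  hi <- m - model$n_post
  if (hi - lo + 1L < 3L)
    sync_error("fewer than 3 internal pulses remain after removing anchors",
               "insufficient_data")
  idx <- lo:hi
  list(times = pt$r[idx], residuals = (pt$r[idx] - pt$t[idx]) * 1000)
}

#' Summarize residual misalignment
#'
#' Computes the canonical misalignment summary: mean, sample standard
#' deviation ("jitter"), ordinary-least-squares trend of residual (ms) on
#' elapsed time (ms), min/max range, and a Shapiro-Wilk Gaussianity verdict at
#' `alpha`. The standard deviation of the residuals about the fitted trend
#' line is reported alongside (`resid_about_line_sd`).
#'
#' @param times reference-clock times (s) of the internal pulses.
#' @param residuals misalignment residuals (ms).
#' @param stat a [stat_config()].
#' @return A list of class `misalignment_report`.
#' @export
summarize_misalignment <- function(times, residuals, stat = stat_config()) {
  if (length(residuals) < 3)
    sync_error("need at least 3 residuals", "insufficient_data")
  if (length(times) != length(residuals))
    sync_error("times and residuals must have equal length", "invalid_argument")
  elapsed_ms <- (times - times[1]) * 1000
  mu <- mean(residuals)
  sdv <- stats::sd(residuals)
  fit <- stats::lm(residuals ~ elapsed_ms)
  trend <- unname(stats::coef(fit)[2])
  about_line <- sqrt(sum(stats::residuals(fit)^2) / max(1, length(residuals) - 2))
  rng <- range(residuals)
  degenerate <- sdv == 0
  if (degenerate) {
    sw_stat <- NA_real_; sw_p <- NA_real_; gaussian <- NA
  } else {
    x <- residuals
    if (length(x) > stat$max_test_n)
      x <- with_local_seed(stat$seed, sample(x, stat$max_test_n))
    sw <- stats::shapiro.test(x)
    sw_stat <- unname(sw$statistic); sw_p <- sw$p.value
    gaussian <- sw_p >= stat$alpha
  }
  structure(list(times = times, residuals = residuals,
                 mean = mu, jitter_sd = sdv, trend = trend,
                 resid_about_line_sd = about_line,
                 range = rng, shapiro_stat = sw_stat, shapiro_p = sw_p,
                 is_gaussian = gaussian, alpha = stat$alpha,
                 n_internal = length(residuals), degenerate = degenerate),
            class = "misalignment_report")
}

#' @export
print.misalignment_report <- function(x, ...) {
  cat(sprintf("<misalignment_report> %d internal spikes\n", x$n_internal))
  cat(sprintf("  mean %.4g ms | jitter (sd) %.4g ms | range [%.4g, %.4g] ms\n",
              x$mean, x$jitter_sd, x$range[1], x$range[2]))
  cat(sprintf("  trend %.4g ms/ms | sd about trend %.4g ms\n",
              x$trend, x$resid_about_line_sd))
  if (x$degenerate) {
    cat("  Gaussianity: skipped (constant residuals)\n")
  } else {
    cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.3g -> %s at alpha = %g\n",
                x$shapiro_stat, x$shapiro_p,
                if (isTRUE(x$is_gaussian)) "Gaussian" else "non-Gaussian",
                x$alpha))
  }
  invisible(x)
}

#' One-way ANOVA across residual groups
#'
#' Compares residual sets obtained under different settings (for example, the
#' number of anchor spikes `n` from 1 to 10) with a classical one-way analysis
#' of variance.
#'
#' @param groups list of at least 2 numeric vectors, each of length >= 2.
#' @param stat a [stat_config()]; `alpha` sets the rejection level.
#' @return A list with `F`, `p`, `reject` (p < alpha) and `degenerate`
#'   (all values identical across all groups).
#' @export
compare_groups <- function(groups, stat = stat_config()) {
  if (!is.list(groups) || length(groups) < 2)
    sync_error("need at least 2 groups", "invalid_argument")
  if (any(vapply(groups, length, 1L) < 2))
    sync_error("each group needs at least 2 values", "invalid_argument")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(values) == 0)
    return(list(F = NA_real_, p = NA_real_, reject = FALSE, degenerate = TRUE))
  tst <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(tst$statistic), p = tst$p.value,
       reject = is.finite(tst$p.value) && tst$p.value < stat$alpha,
       degenerate = FALSE)
}

#' Maximum recording duration for a misalignment budget
#'
#' Given a linear residual trend and a jitter level, estimates how long a
#' recording can run before misalignment leaves the admissible band:
#' `T_max = (bound - z * jitter_sd) / |trend|`, converted to seconds. The
#' formula treats the budget as a drift allowance after reserving `z` standard
#' deviations for jitter; `z` is configurable (default 1.96, a two-sided 95%
#' coverage factor).
#'
#' @param trend residual trend (ms of misalignment per ms of elapsed time).
#' @param jitter_sd jitter (ms).
#' @param bound admissible absolute misalignment (ms); default 5, i.e. the
#'   \[-5, 5\] ms band regarded as safe for connectivity-grade analyses.
#' @param z coverage factor for the jitter reserve.
#' @return Maximum duration (s); `Inf` when the trend is zero.
#' @export
estimate_max_duration <- function(trend, jitter_sd = 0, bound = 5, z = 1.96) {
  if (bound <= 0 || jitter_sd < 0)
    sync_error("bound must be positive and jitter_sd non-negative", "invalid_argument")
  if (bound <= z * jitter_sd)
    sync_error("misalignment budget is exhausted by jitter alone (bound <= z * jitter_sd)",
               "infeasible_budget")
  if (trend == 0) return(Inf)
  ((bound - z * jitter_sd) / abs(trend)) / 1000
}

#' Time for cumulative desynchronization to reach a bound
#'
#' @param trend residual trend (ms/ms).
#' @param bound misalignment bound (ms), > 0.
#' @return Time (s); `Inf` when the trend is zero.
#' @export
time_to_misalignment <- function(trend, bound) {
  if (bound <= 0) sync_error("bound must be positive", "invalid_argument")
  if (trend == 0) return(Inf)
  (bound / abs(trend)) / 1000
}

#' Required sampling-rate agreement between two devices
#'
#' For two devices to stay within a cumulative misalignment `tol` over a
#' recording of duration `T` on nominal rates alone, their true sampling rates
#' must satisfy `|f1 - f2| * T < tol`, i.e. `|f1 - f2| < tol / T`.
#'
#' @param T recording duration (s), > 0.
#' @param tol admissible cumulative misalignment (s), default 1e-3 (1 ms).
#' @return Strict upper bound on `|f1 - f2|` (Hz).
#' @export
required_rate_precision <- function(T, tol = 1e-3) {
  if (T <= 0 || tol <= 0)
    sync_error("T and tol must be positive", "invalid_argument")
  tol / T
}

#' Maximum usable pulse-delivery rate
#'
#' Hardware filtering spreads each pulse over a finite occupancy; pulses must
#' not overlap, so the delivery rate is bounded by `1 / occupancy` (5 Hz for
#' the canonical 200 ms occupancy).
#'
#' @param waveform_occupancy time (s) for a recorded pulse to return to
#'   baseline, > 0.
#' @return Maximum pulse rate (Hz).
#' @export
max_pulse_rate <- function(waveform_occupancy) {
  if (waveform_occupancy <= 0)
    sync_error("waveform occupancy must be positive", "invalid_argument")
  1 / waveform_occupancy
}
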