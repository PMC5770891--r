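#' Affine local-to-reference clock map
#'
#' The alignment model maps a time `t` in the target (local) clock to the
#' reference clock as `t_ref = a + b * t`. `b` close to 1 absorbs the relative
#' clock drift between the two devices; `a` absorbs the start offset and any
#' constant detection delay. PRE-only alignment fixes `b = 1` (shift only,
#' trusting the nominal sampling rates).
#'
#' @param a offset (s).
#' @param b scale (dimensionless), > 0.
#' @param method `"prepost"` or `"pre_only"`.
#' @param n_pre,n_post number of leading/trailing anchor pulses used in the
#'   fit (`n_post = 0` for PRE-only).
#' @return An object of class `alignment_model`.
#' @export
alignment_model <- function(a, b = 1, method = c("prepost", "pre_only"),
                            n_pre = 0L, n_post = 0L) {
  method <- match.arg(method)
  if (!is_finite_num(a) || !is_finite_num(b) || b <= 0)
    sync_error("alignment model needs finite a and b > 0", "invalid_argument")
  if (method == "pre_only" && (b != 1 || n_post != 0))
    sync_error("pre_only alignment requires b = 1 and n_post = 0", "invalid_argument")
  structure(list(a = as.numeric(a), b = as.numeric(b), method = method,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post)),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model> %s: t_ref = %.9g + %.12g * t_local (n_pre = %d, n_post = %d)\n",
              x$method, x$a, x$b, x$n_pre, x$n_post))
  invisible(x)
}

paired_times <- function(reference, target, pairing) {
  list(r = reference$times[pairing$pairs[, "reference"]],
       t = target$times[pairing$pairs[, "target"]])
}

# median of r - b * t together with the "anchor point" achieving it:
# the weighted (element or midpoint-of-two) reference/target times whose
# combination equals the median. Both are linear in b while the ranking of
# r - b*t is unchanged, which is what makes an exact closed-form solve possible.
median_anchor <- function(r, t, b) {
  d <- r - b * t
  n <- length(d)
  o <- order(d)
  if (n %% 2 == 1) {
    j <- o[(n + 1) / 2]
    list(R = r[j], T = t[j], med = d[j])
  } else {
    j <- o[n / 2 + 0:1]
    list(R = mean(r[j]), T = mean(t[j]), med = mean(d[j]))
  }
}

#' Fit a PRE-POST alignment (shift + linear time-warp)
#'
#' Fits the affine map `t_ref = a + b * t` so that the *median* misalignment
#' (`reference - mapped target`) over the first `n_pre` matched pulses is zero
#' and the median over the last `n_post` matched pulses is zero. Using medians
#' of several anchor pulses makes the fit robust to per-pulse detection jitter
#' on the analog stream.
#'
#' Both anchor medians are piecewise-linear functions of the scale `b`, so the
#' fit is solved exactly: iterate on the pair of median-achieving anchor
#' points, solving the two-anchor linear system in closed form at each step
#' (a `uniroot` bracketing step is used as a fallback if the active anchors
#' cycle). By construction the returned model leaves both anchor medians zero
#' to floating-point precision.
#'
#' @param reference,target [event_series()] objects.
#' @param pairing an [pair_events()] result; if `NULL`, computed with the
#'   default `max_lag`.
#' @param n_pre,n_post number of leading/trailing anchor pairs (each >= 1).
#' @param max_lag pairing tolerance used when `pairing` is `NULL`.
#' @return An [alignment_model()] with `method = "prepost"`.
#' @examples
#' ref <- event_series(seq(0, 58, by = 2))
#' tgt <- event_series((ref$times - 0.5) / 1.0001)
#' fit_prepost_alignment(ref, tgt, n_pre = 3, n_post = 3)
#' @export
fit_prepost_alignment <- function(reference, target, pairing = NULL,
                                  n_pre = 10, n_post = n_pre, max_lag = 1) {
  if (is.null(pairing)) pairing <- pair_events(reference, target, max_lag)
  m <- n_pairs(pairing)
  if (n_pre < 1 || n_post < 1)
    sync_error("n_pre and n_post must each be >= 1", "invalid_argument")
  if (n_pre + n_post > m)
    sync_error(sprintf("need at least n_pre + n_post = %d matched pairs, have %d",
                       n_pre + n_post, m), "insufficient_anchors")
  pt <- paired_times(reference, target, pairing)
  pre <- seq_len(n_pre)
  post <- seq.int(m - n_post + 1, m)
  r_pre <- pt$r[pre];  t_pre <- pt$t[pre]
  r_post <- pt$r[post]; t_post <- pt$t[post]

  gap <- function(b) {
    median(r_pre - b * t_pre) - median(r_post - b * t_post)
  }
  tol_g <- 1e-12 * max(1, max(abs(pt$r)))
  b <- 1
  converged <- FALSE
  for (it in 1:100) {
    P <- median_anchor(r_pre, t_pre, b)
    Q <- median_anchor(r_post, t_post, b)
    if (abs(P$T - Q$T) < 1e-12 * max(1, abs(P$T)))
      sync_error("PRE and POST anchor times coincide: degenerate span",
                 "degenerate_span")
    b_new <- (P$R - Q$R) / (P$T - Q$T)
    if (!is.finite(b_new) || b_new <= 0)
      sync_error("alignment scale is not positive; check the pairing",
                 "degenerate_span")
    b <- b_new
    if (abs(gap(b)) <= tol_g) { converged <- TRUE; break }
  }
  if (!converged) {
    # bracket the unique root of the piecewise-linear gap and polish once
    lo <- 0.5; hi <- 2
    for (k in 1:30) {
      if (gap(lo) * gap(hi) <= 0) break
      lo <- lo / 2; hi <- hi * 2
    }
    b <- stats::uniroot(gap, c(lo, hi), tol = .Machine$double.eps^0.75)$root
    P <- median_anchor(r_pre, t_pre, b)
    Q <- median_anchor(r_post, t_post, b)
    if (abs(P$T - Q$T) > 1e-12 * max(1, abs(P$T))) {
      b_exact <- (P$R - Q$R) / (P$T - Q$T)
      if (is.finite(b_exact) && b_exact > 0 && abs(gap(b_exact)) <= abs(gap(b)))
        b <- b_exact
    }
  }
  a <- median(r_pre - b * t_pre)
  alignment_model(a, b, "prepost", n_pre = n_pre, n_post = n_post)
}

#' Fit a PRE-only alignment (shift only)
#'
#' Aligns the target stream by a pure shift so that the median misalignment
#' over the first `n` matched pulses is zero, then trusts the nominal sampling
#' rates (`b = 1`). This is the strategy of relying on the manufacturer-stated
#' rate; any true rate discrepancy shows up as a near-linear residual trend.
#'
#' @inheritParams fit_prepost_alignment
#' @param n number of leading anchor pairs.
#' @return An [alignment_model()] with `method = "pre_only"`.
#' @export
fit_pre_alignment <- function(reference, target, pairing = NULL, n = 10,
                              max_lag = 1) {
  if (is.null(pairing)) pairing <- pair_events(reference, target, max_lag)
  m <- n_pairs(pairing)
  if (n < 1) sync_error("n must be >= 1", "invalid_argument")
  if (n > m)
    sync_error(sprintf("need at least n = %d matched pairs, have %d", n, m),
               "insufficient_anchors")
  pt <- paired_times(reference, target, pairing)
  a <- median(pt$r[seq_len(n)] - pt$t[seq_len(n)])
  alignment_model(a, 1, "pre_only", n_pre = n, n_post = 0L)
}

#' Apply an alignment model to an event series
#'
#' Maps each event time `t` to `a + b * t`. Ordering is preserved since
#' `b > 0`.
#'
#' @param events an [event_series()].
#' @param model an [alignment_model()].
#' @return A new [event_series()] in the reference clock.
#' @export
transform_events <- function(events, model) {
  stopifnot(inherits(events, "event_series"), inherits(model, "alignment_model"))
  event_series(model$a + model$b * events$times,
               clock_label = paste0(events$clock_label, " (aligned)"))
}

#' Invert an alignment model
#'
#' @param model an [alignment_model()].
#' @return The inverse affine map as an `alignment_model` (method preserved
#'   for `prepost`; a PRE-only inverse is again shift-only).
#' @export
invert_alignment <- function(model) {
  stopifnot(inherits(model, "alignment_model"))
  alignment_model(-model$a / model$b, 1 / model$b,
                  method = if (model$method == "pre_only") "pre_only" else "prepost",
                  n_pre = model$n_pre,
                  n_post = if (model$method == "pre_only") 0L else model$n_post)
}

#' Resample a trace onto the reference clock
#'
#' Produces a uniformly sampled trace on the reference-clock grid
#' `k / out_rate` by linear interpolation of the input at the pre-image times
#' `(t_out - a) / b`. Reference times before the first or after the last input
#' sample are zero-padded by default (set `edge = "crop"` to drop them
#' instead).
#'
#' @param trace a [sampled_trace()] in the target (local) clock.
#' @param model an [alignment_model()] mapping local to reference time.
#' @param out_rate output sampling rate (Hz), > 0.
#' @param t_start,t_end optional reference-clock window; defaults to the grid
#'   points covering the mapped input span. `t_start` is snapped up and
#'   `t_end` down onto the output grid.
#' @param edge `"zero"` (default) pads samples outside the input span with
#'   zeros; `"crop"` drops them.
#' @return A [sampled_trace()] on the reference clock.
#' @export
resample_trace <- function(trace, model, out_rate = trace$rate_nominal,
                           t_start = NULL, t_end = NULL,
                           edge = c("zero", "crop")) {
  stopifnot(inherits(trace, "sampled_trace"), inherits(model, "alignment_model"))
  edge <- match.arg(edge)
  if (!is_finite_num(out_rate) || out_rate <= 0)
    sync_error("out_rate must be positive", "invalid_argument")
  if (length(trace$values) == 0)
    return(sampled_trace(numeric(0), out_rate, 0, trace$label))
  tt <- trace_times(trace)
  span <- model$a + model$b * c(tt[1], tt[length(tt)])
  eps <- 1e-9 / out_rate
  if (is.null(t_start)) t_start <- span[1]
  if (is.null(t_end)) t_end <- span[2]
  k0 <- ceiling(t_start * out_rate - eps)
  k1 <- floor(t_end * out_rate + eps)
  if (k1 < k0)
    return(sampled_trace(numeric(0), out_rate, 0, trace$label))
  out_t <- (k0:k1) / out_rate
  pre <- (out_t - model$a) / model$b
  if (edge == "crop") {
    keep <- pre >= tt[1] - eps & pre <= tt[length(tt)] + eps
    if (!any(keep))
      return(sampled_trace(numeric(0), out_rate, 0, trace$label))
    first <- which(keep)[1]
    out_t <- out_t[keep]; pre <- pre[keep]
    k0 <- k0 + first - 1
  }
  vals <- stats::approx(tt, trace$values, xout = pre, method = "linear",
                        yleft = 0, yright = 0, ties = "ordered")$y
  sampled_trace(vals, out_rate, start_time = k0 / out_rate, label = trace$label)
}
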