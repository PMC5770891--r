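test_that("identical and offset series pair one-to-one", {
  ref <- event_series(seq(0, 598, by = 2))
  p <- pair_events(ref, ref, max_lag = 1)
  expect_equal(nrow(p$pairs), 300)
  expect_equal(p$pairs[, "reference"], p$pairs[, "target"])

  tgt <- event_series(c(0.5, 2.5, 4.5))
  p2 <- pair_events(event_series(c(0, 2, 4)), tgt, max_lag = 1)
  expect_equal(unname(p2$pairs), cbind(1:3, 1:3))
  expect_equal(p2$n_unmatched_reference, 0)
})

test_that("pairing with dropped events matches the brute-force optimum", {
  ref <- c(0, 2, 4, 6)
  tgt <- c(0.5, 4.49, 6.5)
  p <- pair_events(event_series(ref), event_series(tgt), max_lag = 1)
  expect_equal(unname(p$pairs), cbind(c(1L, 3L, 4L), c(1L, 2L, 3L)))
  expect_equal(p$n_unmatched_reference, 1)
  expect_equal(unname(p$pairs), unname(oracle_match(ref, tgt, max_lag = 1)))
})

test_that("pairing equals the brute-force optimum on perturbed trains", {
  for (seed in 1:10) {
    set.seed(seed)
    n_r <- sample(4:9, 1)
    ref <- cumsum(runif(n_r, 0.5, 2.5))
    keep <- runif(n_r) > 0.2
    tgt <- sort(ref[keep] + rnorm(sum(keep), 0, 0.15)) + 0.3
    if (sum(keep) < 2) next
    p <- pair_events(event_series(ref), event_series(tgt), max_lag = 0.8)
    o <- oracle_match(ref, tgt, max_lag = 0.8)
    expect_equal(nrow(p$pairs), nrow(o))
    expect_equal(unname(p$pairs), unname(o))
  }
})

test_that("degenerate pairing inputs are handled", {
  ref <- event_series(c(0, 2))
  expect_error(pair_events(ref, ref, max_lag = 0), class = "invalid_argument")
  expect_warning(p <- pair_events(ref, event_series(numeric(0))),
                 "empty")
  expect_equal(nrow(p$pairs), 0)
  expect_equal(p$n_unmatched_reference, 2)
})

test_that("prepost fit recovers identity and exact affine maps", {
  ref <- event_series(seq(0, 598, by = 2))
  fit <- fit_prepost_alignment(ref, ref, n_pre = 10, n_post = 10)
  expect_equal(fit$a, 0)
  expect_equal(fit$b, 1)

  a_true <- 0.5; b_true <- 1.0001
  tgt <- event_series((ref$times - a_true) / b_true)
  for (n in c(1, 3, 10)) {
    fit <- fit_prepost_alignment(ref, tgt, n_pre = n, n_post = n)
    mapped <- transform_events(tgt, fit)
    expect_lt(max(abs(mapped$times - ref$times)), 1e-9)
    expect_lt(abs(fit$a - a_true), 1e-9)
    expect_lt(abs(fit$b - b_true) / b_true, 1e-9)
  }
})

test_that("noise-free recovery of injected maps is exact to 1e-9 relative", {
  ref <- event_series(seq(0, 598, by = 2))
  for (b_true in c(1 - 1e-3, 1 + 1e-4, 1 + 1e-3)) {
    for (a_true in c(-0.5, 0.072)) {
      tgt <- event_series((ref$times - a_true) / b_true)
      fit <- fit_prepost_alignment(ref, tgt, n_pre = 5, n_post = 5)
      expect_lt(abs(fit$b - b_true) / b_true, 1e-9)
      expect_lt(abs(fit$a - a_true) / max(1, abs(a_true)), 1e-9)
    }
  }
})

test_that("prepost anchor medians are zero by construction", {
  for (seed in 1:20) {
    set.seed(seed)
    n_ev <- sample(15:40, 1)
    ref <- event_series(seq(0, by = 2, length.out = n_ev))
    a_true <- runif(1, -1, 1)
    b_true <- 1 + runif(1, -5e-4, 5e-4)
    jit <- rnorm(n_ev, 0, 1.7e-3)
    tgt <- event_series(sort((ref$times - a_true) / b_true + jit))
    n_pre <- sample(c(1, 2, 3, 4, 5), 1)
    n_post <- sample(c(1, 2, 3, 4, 5), 1)
    fit <- fit_prepost_alignment(ref, tgt, n_pre = n_pre, n_post = n_post)
    mapped <- fit$a + fit$b * tgt$times
    res <- ref$times - mapped
    m <- length(res)
    expect_lt(abs(median(res[seq_len(n_pre)])), 1e-12)
    expect_lt(abs(median(res[seq.int(m - n_post + 1, m)])), 1e-12)
  }
})

test_that("prepost fit agrees with the 2-D grid-search oracle", {
  set.seed(7)
  ref <- event_series(seq(0, by = 2, length.out = 50))
  tgt <- event_series(sort(ref$times + rnorm(50, 0, 1.7e-3) - 0.2))
  fit <- fit_prepost_alignment(ref, tgt, n_pre = 10, n_post = 10)
  pt_r <- ref$times; pt_t <- tgt$times
  o <- oracle_grid_fit(pt_r, pt_t, n_pre = 10, n_post = 10,
                       a_center = median(pt_r - pt_t), b_center = 1,
                       a_half = 0.05, b_half = 5e-4, n_grid = 81, rounds = 5)
  expect_lt(abs(fit$a - o$a), 10 * o$a_res)
  expect_lt(abs(fit$b - o$b), 10 * o$b_res)
})

test_that("prepost fit rejects impossible anchor requests", {
  ref <- event_series(seq(0, 18, by = 2))
  expect_error(fit_prepost_alignment(ref, ref, n_pre = 6, n_post = 6),
               class = "insufficient_anchors")
  expect_error(fit_prepost_alignment(ref, ref, n_pre = 0, n_post = 1),
               class = "invalid_argument")
})

test_that("pre-only fit is a median shift with unit scale", {
  ref <- event_series(seq(0, 598, by = 2))
  fit <- fit_pre_alignment(ref, ref, n = 10)
  expect_equal(fit$a, 0)
  expect_equal(fit$b, 1)
  expect_equal(fit$method, "pre_only")

  # a constant 72 ms delivery delay is recovered exactly
  tgt <- event_series(ref$times - 0.072)
  fit <- fit_pre_alignment(ref, tgt, n = 5)
  expect_equal(fit$a, 0.072)

  expect_error(fit_pre_alignment(ref, tgt, n = 301),
               class = "insufficient_anchors")
})

test_that("pre-only residuals grow linearly under pure drift", {
  delta <- 1e-4
  ref <- event_series(seq(0, 598, by = 2))
  tgt <- event_series(ref$times * (1 + delta))
  fit <- fit_pre_alignment(ref, tgt, n = 10)
  mapped <- transform_events(tgt, fit)
  res <- ref$times - mapped$times
  # closed form: residual at reference time t is -delta * (t - t_anchor)
  t_anchor <- -fit$a / delta
  expect_lt(max(abs(res - (-delta) * (ref$times - t_anchor))), 1e-9)
})

test_that("event transforms shift, scale and round-trip", {
  ev <- event_series(c(0, 2, 4))
  m_id <- alignment_model(0, 1)
  expect_equal(transform_events(ev, m_id)$times, ev$times)
  expect_equal(transform_events(ev, alignment_model(1, 1))$times, c(1, 3, 5))
  expect_equal(transform_events(event_series(c(1, 2)), alignment_model(0, 2))$times,
               c(2, 4))
  for (seed in 1:5) {
    set.seed(seed)
    m <- alignment_model(runif(1, -5, 5), 1 + runif(1, -1e-3, 1e-3))
    ev2 <- event_series(sort(runif(20, 0, 600)))
    back <- transform_events(transform_events(ev2, m), invert_alignment(m))
    expect_lt(max(abs(back$times - ev2$times)), 1e-12)
  }
})

test_that("resampling is exact for identity, shift and linear signals", {
  set.seed(3)
  x <- rnorm(1000)
  tr <- sampled_trace(x, 1000, start_time = 0)
  out <- resample_trace(tr, alignment_model(0, 1), out_rate = 1000)
  expect_identical(out$values, x)
  expect_identical(out$start_time, 0)

  # shift by 5 whole sample periods, window held to the input span: the
  # content moves and the freed edge is zero-padded
  out <- resample_trace(tr, alignment_model(5 / 1000, 1), out_rate = 1000,
                        t_start = 0, t_end = 999 / 1000)
  expect_identical(out$values[1:5], rep(0, 5))
  expect_equal(out$values[6:1000], x[1:995], tolerance = 1e-12)

  # a ramp is represented exactly by linear interpolation
  tt <- (0:2000) / 1000
  ramp <- sampled_trace(tt, 1000, start_time = 0)
  b <- 1 + 1e-4
  out <- resample_trace(ramp, alignment_model(0, b), out_rate = 1000)
  interior <- seq(2, length(out$values) - 1)
  got <- out$values[interior]
  want <- trace_times(out)[interior] / b
  expect_lt(max(abs(got - want)), 1e-9)

  empty <- resample_trace(sampled_trace(numeric(0), 1000), alignment_model(0, 1))
  expect_equal(length(empty$values), 0)
})

test_that("type constructors enforce their invariants", {
  expect_error(event_series(c(1, 1)), class = "invalid_argument")
  expect_error(event_series(c(0, NA)), class = "invalid_argument")
  expect_error(sampled_trace(1:3, rate_nominal = 0), class = "invalid_argument")
  expect_error(alignment_model(0, -1), class = "invalid_argument")
  expect_error(alignment_model(0, 1.1, method = "pre_only"),
               class = "invalid_argument")
  expect_error(pulse_train_spec(period = 0), class = "invalid_argument")
})
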