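test_that("internal residuals exclude the anchor pulses", {
  rec <- simulate_recording(seed = 5)
  tgt <- event_domain_target(rec)
  pairing <- pair_events(rec$events, tgt)
  model <- fit_prepost_alignment(rec$events, tgt, pairing, n_pre = 10, n_post = 10)
  mapped <- transform_events(tgt, model)
  ms <- misalignment_series(rec$events, mapped, pairing, model)
  expect_length(ms$residuals, 280)
  expect_length(ms$times, 280)

  # perfectly aligned streams give all-zero residuals
  p0 <- pair_events(rec$events, rec$events)
  m0 <- fit_prepost_alignment(rec$events, rec$events, p0, 10, 10)
  ms0 <- misalignment_series(rec$events, transform_events(rec$events, m0), p0, m0)
  expect_equal(ms0$residuals, rep(0, 280))

  tiny <- event_series(seq(0, 8, by = 2))
  pt <- pair_events(tiny, tiny)
  mt <- fit_prepost_alignment(tiny, tiny, pt, n_pre = 2, n_post = 2)
  expect_error(misalignment_series(tiny, tiny, pt, mt),
               class = "insufficient_data")
})

test_that("summary statistics are exact on constructed residuals", {
  times <- seq(20, 580, by = 2)
  rep0 <- summarize_misalignment(times, rep(0, length(times)))
  expect_equal(rep0$mean, 0)
  expect_equal(rep0$jitter_sd, 0)
  expect_equal(rep0$trend, 0)
  expect_equal(rep0$range, c(0, 0))
  expect_true(rep0$degenerate)
  expect_true(is.na(rep0$is_gaussian))

  # residuals exactly 1e-4 * elapsed-ms: trend recovered exactly, no scatter
  res <- 1e-4 * (times - times[1]) * 1000
  repl <- summarize_misalignment(times, res)
  expect_equal(repl$trend, 1e-4, tolerance = 1e-12)
  expect_lt(repl$resid_about_line_sd, 1e-9)

  expect_error(summarize_misalignment(1:2, 1:2), class = "insufficient_data")
})

test_that("jitter estimate and Gaussianity verdict behave at sigma = 1.7 ms, n = 280", {
  set.seed(42)
  times <- seq(20, 578, by = 2)
  res <- rnorm(280, 0, 1.7)
  repj <- summarize_misalignment(times, res)
  ci <- sd_chisq_interval(1.7, 280)
  expect_gt(repj$jitter_sd, ci[1])
  expect_lt(repj$jitter_sd, ci[2])

  verdicts <- vapply(1:100, function(s) {
    set.seed(s)
    isTRUE(summarize_misalignment(times, rnorm(280, 0, 1.7))$is_gaussian)
  }, logical(1))
  expect_gte(mean(verdicts), 0.90)
})

test_that("large residual sets are subsampled reproducibly for Shapiro-Wilk", {
  set.seed(9)
  n <- 6000
  times <- seq_len(n)
  res <- rnorm(n)
  r1 <- summarize_misalignment(times, res)
  r2 <- summarize_misalignment(times, res)
  expect_identical(r1$shapiro_p, r2$shapiro_p)
  expect_false(is.na(r1$shapiro_p))
})

test_that("one-way ANOVA agrees with the sum-of-squares formula and flags effects", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  out <- compare_groups(g)
  # independent hand computation of the classical F statistic
  all_v <- unlist(g)
  means <- vapply(g, mean, numeric(1))
  ssb <- sum(lengths(g) * (means - mean(all_v))^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_hand <- (ssb / (length(g) - 1)) / (ssw / (length(all_v) - length(g)))
  expect_equal(out$F, f_hand, tolerance = 1e-12)

  set.seed(2)
  big <- compare_groups(list(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1)))
  expect_true(big$reject)

  same <- compare_groups(list(rep(1, 3), rep(1, 4)))
  expect_true(same$degenerate)
  expect_error(compare_groups(list(1:3)), class = "invalid_argument")
})

test_that("planning bounds reproduce their closed forms", {
  expect_equal(estimate_max_duration(trend = 0, jitter_sd = 0.5), Inf)
  expect_equal(estimate_max_duration(trend = 10e-5, jitter_sd = 0, bound = 5), 50)
  expect_equal(estimate_max_duration(trend = 10e-5, jitter_sd = 0, bound = 10), 100)
  expect_error(estimate_max_duration(trend = 1e-4, jitter_sd = 3, bound = 5),
               class = "infeasible_budget")

  expect_equal(time_to_misalignment(1e-4, 20), 200)
  expect_equal(time_to_misalignment(1e-4, 60), 600)
  expect_equal(time_to_misalignment(0, 5), Inf)

  expect_equal(required_rate_precision(600), 1e-3 / 600)
  expect_equal(required_rate_precision(300), 1e-3 / 300)
  for (T in c(60, 600, 1200)) {
    expect_equal(required_rate_precision(T, 1e-3) * T, 1e-3)
  }

  expect_equal(max_pulse_rate(0.2), 5)
  expect_equal(max_pulse_rate(1), 1)
  expect_equal(max_pulse_rate(0.15), 1 / 0.15)
})

test_that("trend estimator recovers pure drift exactly and under jitter", {
  ref <- event_series(seq(0, 598, by = 2))
  # noiseless drift: |trend| equals delta to 1e-6 relative
  for (delta in c(1e-5, 1e-4, 1e-3)) {
    tgt <- event_series(ref$times * (1 + delta))
    fit <- sync_fit(ref, tgt, method = "pre", n_pre = 10)
    expect_lt(abs(abs(fit$report$trend) - delta) / delta, 1e-6)
  }
})

test_that("drift is recovered within 3 standard errors across 100 seeds", {
  for (delta in c(1e-5, 1e-4, 1e-3)) {
    trends <- vapply(1:100, function(s) {
      rec <- simulate_recording(clock = clock_model(drift = delta),
                                noise = noise_model(sd = 0),
                                seed = s)
      tgt <- event_domain_target(rec)
      abs(sync_fit(rec$events, tgt, method = "pre", n_pre = 10)$report$trend)
    }, numeric(1))
    se <- sd(trends) / sqrt(length(trends))
    expect_lt(abs(mean(trends) - delta), 3 * se)
  }
})

test_that("PRE-POST residual bound never exceeds the PRE-only bound under drift", {
  for (s in 1:5) {
    for (delta in c(1e-5, 1e-4, 1e-3)) {
      rec <- simulate_recording(clock = clock_model(drift = delta), seed = s)
      tgt <- event_domain_target(rec)
      pp <- sync_fit(rec$events, tgt, method = "prepost")
      po <- sync_fit(rec$events, tgt, method = "pre")
      expect_lte(max(abs(pp$report$residuals)), max(abs(po$report$residuals)))
    }
  }
})

test_that("mean absolute misalignment decreases with the number of anchor spikes", {
  # averaged over replicate synthetic sessions, the n = 1..10 sweep shows the
  # inverse relation between anchor count and residual bias
  abs_means <- matrix(NA_real_, 20, 10)
  for (s in 1:20) {
    rec <- simulate_recording(seed = s)
    tgt <- event_domain_target(rec)
    sw <- sweep_anchor_n(rec$events, tgt, n = 1:10)
    abs_means[s, ] <- sw$abs_mean_ms
  }
  avg <- colMeans(abs_means)
  expect_lt(cor(1:10, avg), 0)
  expect_lt(avg[10], avg[1])
})
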