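# Independent brute-force oracles used to freeze expected values.

# All monotone matchings of target onto reference with per-pair |lag| (after
# coarse offset removal) <= max_lag; returns the matching maximizing pair
# count, then minimizing total |lag|. Exponential enumeration: tiny inputs only.
oracle_match <- function(ref, tgt, max_lag) {
  coarse <- ref[1] - tgt[1]
  s <- tgt + coarse
  m <- length(ref); n <- length(s)
  # a monotone k-matching is a k-subset of references paired in order with a
  # k-subset of targets; enumerate all subset pairs, largest k first
  for (k in seq.int(min(m, n), 1)) {
    best_lag <- Inf
    best_pairs <- NULL
    ref_sets <- utils::combn(m, k, simplify = FALSE)
    tgt_sets <- utils::combn(n, k, simplify = FALSE)
    for (ri in ref_sets) {
      for (ti in tgt_sets) {
        lags <- abs(s[ti] - ref[ri])
        if (all(lags <= max_lag)) {
          tot <- sum(lags)
          if (tot < best_lag) {
            best_lag <- tot
            best_pairs <- cbind(ri, ti)
          }
        }
      }
    }
    if (!is.null(best_pairs)) {
      colnames(best_pairs) <- c("reference", "target")
      return(best_pairs)
    }
  }
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("reference", "target")))
}

# 2-D grid search minimizing |median PRE residual| + |median POST residual|,
# with iterative refinement; returns the optimum and the final resolution.
oracle_grid_fit <- function(r, t, n_pre, n_post, a_center = 0, b_center = 1,
                            a_half = 1, b_half = 5e-4, n_grid = 41,
                            rounds = 6) {
  m <- length(r)
  pre <- seq_len(n_pre)
  post <- seq.int(m - n_post + 1, m)
  score <- function(a, b) {
    d <- r - a - b * t
    abs(median(d[pre])) + abs(median(d[post]))
  }
  for (round in seq_len(rounds)) {
    as <- seq(a_center - a_half, a_center + a_half, length.out = n_grid)
    bs <- seq(b_center - b_half, b_center + b_half, length.out = n_grid)
    sc <- outer(as, bs, Vectorize(score))
    ix <- which(sc == min(sc), arr.ind = TRUE)[1, ]
    a_center <- as[ix[1]]; b_center <- bs[ix[2]]
    a_half <- 2 * a_half / (n_grid - 1)
    b_half <- 2 * b_half / (n_grid - 1)
  }
  list(a = a_center, b = b_center, a_res = a_half, b_res = b_half)
}

# first sample whose absolute deviation from baseline reaches the threshold
oracle_first_crossing <- function(values, threshold) {
  which(abs(values - median(values)) >= threshold)[1]
}

# chi-square 95% interval for a sample sd around a true sd, given n
sd_chisq_interval <- function(true_sd, n) {
  true_sd * sqrt(qchisq(c(0.025, 0.975), n - 1) / (n - 1))
}
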