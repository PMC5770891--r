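#' Match pulse events across two clocks
#'
#' Builds a monotone one-to-one matching between a reference event series and
#' a target series. The coarse clock offset (difference of the first events)
#' is removed, then the optimal order-preserving matching is computed: among
#' all monotone matchings whose per-pair lag does not exceed `max_lag`, the one
#' with the largest number of pairs and, among those, the smallest total
#' absolute lag. Unmatched events on either side are dropped and counted.
#'
#' For a clean train with period `P`, any `max_lag < P/2` guarantees an
#' unambiguous matching; the default of 1 s is half the default 2 s period.
#'
#' @param reference,target [event_series()] objects, each sorted (enforced by
#'   construction).
#' @param max_lag pairing tolerance (s), > 0, applied after coarse-offset
#'   removal.
#' @return An object of class `event_pairing`: list with `pairs` (two-column
#'   integer matrix of reference/target indices), `max_lag`, `coarse_offset`,
#'   `n_unmatched_reference`, `n_unmatched_target`.
#' @export
pair_events <- function(reference, target, max_lag = 1) {
  stopifnot(inherits(reference, "event_series"), inherits(target, "event_series"))
  if (!is_finite_num(max_lag) || length(max_lag) != 1 || max_lag <= 0)
    sync_error("max_lag must be a single positive number", "invalid_argument")
  r <- reference$times
  t <- target$times
  if (length(r) == 0 || length(t) == 0) {
    warning("empty event series: returning an empty pairing")
    return(structure(list(pairs = matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("reference", "target"))),
                          max_lag = max_lag, coarse_offset = NA_real_,
                          n_unmatched_reference = length(r),
                          n_unmatched_target = length(t)),
                     class = "event_pairing"))
  }
  coarse <- r[1] - t[1]
  s <- t + coarse
  m <- length(r); n <- length(s)

  # dynamic program over (reference prefix, target prefix); state = (pairs
  # matched, total |lag|), lexicographic max on count then min on lag.
  cnt <- matrix(0L, m + 1, n + 1)
  cost <- matrix(0, m + 1, n + 1)
  move <- matrix(0L, m + 1, n + 1)  # 1 = skip ref, 2 = skip target, 3 = match
  for (i in seq_len(m)) {
    lag_i <- abs(s - r[i])
    for (j in seq_len(n)) {
      # skip reference i
      bc <- cnt[i, j + 1]; bw <- cost[i, j + 1]; mv <- 1L
      # skip target j
      if (cnt[i + 1, j] > bc || (cnt[i + 1, j] == bc && cost[i + 1, j] < bw)) {
        bc <- cnt[i + 1, j]; bw <- cost[i + 1, j]; mv <- 2L
      }
      # match i-j
      if (lag_i[j] <= max_lag) {
        mc <- cnt[i, j] + 1L; mw <- cost[i, j] + lag_i[j]
        if (mc > bc || (mc == bc && mw < bw)) {
          bc <- mc; bw <- mw; mv <- 3L
        }
      }
      cnt[i + 1, j + 1] <- bc; cost[i + 1, j + 1] <- bw; move[i + 1, j + 1] <- mv
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- m; j <- n
  while (i > 0 && j > 0) {
    mv <- move[i + 1, j + 1]
    if (mv == 3L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (mv == 1L) i <- i - 1 else j <- j - 1
  }
  colnames(pairs) <- c("reference", "target")
  structure(list(pairs = pairs, max_lag = max_lag, coarse_offset = coarse,
                 n_unmatched_reference = m - nrow(pairs),
                 n_unmatched_target = n - nrow(pairs)),
            class = "event_pairing")
}

#' @export
print.event_pairing <- function(x, ...) {
  cat(sprintf("<event_pairing> %d pairs (max_lag %g s, coarse offset %s s); unmatched: %d reference, %d target\n",
              nrow(x$pairs), x$max_lag,
              if (is.na(x$coarse_offset)) "NA" else format(x$coarse_offset),
              x$n_unmatched_reference, x$n_unmatched_target))
  invisible(x)
}

n_pairs <- function(pairing) nrow(pairing$pairs)
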