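# Independent brute-force oracles used to cross-check the implementation.

# Per-sample sort-and-middle moving median with asymmetric edge shrink.
naive_moving_median <- function(values, k) {
  n <- length(values)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    median(values[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Linear scan over the posture sequence, collecting maximal runs.
naive_segment <- function(lying, time) {
  n <- length(lying)
  starts <- 1L
  for (i in 2:n) if (lying[i] != lying[i - 1]) starts <- c(starts, i)
  ends <- c(starts[-1] - 1L, n)
  data.frame(
    posture = ifelse(lying[starts], "lying", "standing"),
    start = as.numeric(time[starts]),
    end = as.numeric(c(time[starts[-1]], time[n])),
    row_start = starts,
    row_end = ends
  )
}

# Relabel-then-rescan oracle for the minimum-duration correction: expand the
# bout list back to a sample-level posture vector, flip short interior lying
# runs to standing, and re-run run-length encoding.
naive_min_duration <- function(lying, time, min_lying) {
  b <- naive_segment(lying, time)
  interior <- seq_len(nrow(b)) > 1 & seq_len(nrow(b)) < nrow(b)
  drop <- b$posture == "lying" & interior & (b$end - b$start) < min_lying
  out <- lying
  for (i in which(drop)) out[b$row_start[i]:b$row_end[i]] <- FALSE
  naive_segment(out, time)
}

# Small deterministic series: standing/lying square wave in the up channel.
toy_series <- function(pattern, rate = 1, id = "c1",
                       t0 = as.POSIXct("2026-01-05", tz = "UTC")) {
  lying <- unlist(lapply(seq_along(pattern), function(i) {
    rep(pattern[[i]]$lying, pattern[[i]]$n)
  }))
  n <- length(lying)
  tibble::tibble(
    id = id,
    time = t0 + seq(0, by = 1 / rate, length.out = n),
    acc_fwd = 0,
    acc_up = ifelse(lying, 0, 1),
    acc_right = ifelse(lying, 1, 0)
  )
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

rotate_series <- function(data, R) {
  m <- t(R %*% t(as.matrix(data[c("acc_fwd", "acc_up", "acc_right")])))
  out <- data
  out$acc_fwd <- m[, 1]; out$acc_up <- m[, 2]; out$acc_right <- m[, 3]
  out
}
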