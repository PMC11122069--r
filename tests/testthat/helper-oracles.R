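# Independent oracles and fixture builders shared across test files.

# Generator config with every stochastic corruption switched off.
quiet_cfg <- function(...) {
  generator_config(gyro_noise_sd = 0, accel_noise_sd = 0,
                   impulse_prob = 0, time_warp_strength = 0, ...)
}

# Near-degenerate draw ranges to pin duration/amplitude while satisfying
# the config invariant that ranges are non-degenerate.
pinned <- function(x) c(x, x + 1e-9)

# Brute-force sliding median: explicit edge-replication padding and a
# sort-based middle-of-window rule, written without stats::median.
brute_median_filter <- function(x, l) {
  n <- length(x)
  if (l %% 2 == 1) { pl <- (l - 1) / 2; pr <- pl } else { pl <- l / 2; pr <- l / 2 - 1 }
  xp <- c(rep(x[1], pl), x, rep(x[n], pr))
  out <- numeric(n)
  for (t in seq_len(n)) {
    w <- sort(xp[t:(t + l - 1)])
    out[t] <- if (l %% 2 == 1) w[(l + 1) / 2] else (w[l / 2] + w[l / 2 + 1]) / 2
  }
  out
}

# Exhaustive DTW: minimum over ALL monotone, contiguous warp paths from
# (1,1) to (n,m) of the summed pointwise distances, by full recursive
# enumeration (no dynamic programming, no memoization).
brute_dtw_distance <- function(d) {
  n <- nrow(d); m <- ncol(d)
  rec <- function(i, j) {
    if (i == n && j == m) return(d[i, j])
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    d[i, j] + best
  }
  rec(1, 1)
}

# Literal brute-force endpoint detector: median-filter the gyro channels,
# take the magnitude, then at every sample re-test the start rule, the
# (strengthened) whole-window quiet end rule via an explicit all() over the
# trailing window, and the open-interval duration gate. Returns a 2-column
# matrix of 0-based half-open [start, end) indices.
brute_detect <- function(x, cfg, pp) {
  fs <- sampling_rate(x)
  w <- seconds_to_samples(cfg$t_interval_s, fs)
  l <- seconds_to_samples(pp$t_win_s, fs)
  g <- apply(unclass(x)[, c("gx", "gy", "gz")], 2, brute_median_filter, l = l)
  mag <- sqrt(rowSums(g^2))
  n <- length(mag)
  segs <- NULL
  t <- 1
  while (t <= n) {
    if (mag[t] > cfg$ang_min) {
      tstart <- t
      tend <- NA
      u <- t + 1
      while (u <= n) {
        if (u > w && all(mag[(u - w):u] < cfg$ang_min)) { tend <- u; break }
        u <- u + 1
      }
      if (is.na(tend)) break
      dur <- (tend - tstart) / fs
      if (dur > cfg$t_min_s && dur < cfg$t_max_s)
        segs <- rbind(segs, c(tstart - 1, tend - 1))
      t <- tend + 1
    } else t <- t + 1
  }
  if (is.null(segs)) matrix(integer(0), ncol = 2) else segs
}

segs_to_matrix <- function(segs) {
  if (length(segs) == 0) return(matrix(integer(0), ncol = 2))
  t(vapply(segs, function(s) c(s$start, s$end), numeric(2)))
}

# A six-channel sequence with a rectangular |gz| pulse of given duration,
# centred in quiet gravity baseline.
rect_pulse_stream <- function(dur_s, amp = 0.5, fs = 100, lead_s = 4) {
  lead <- round(lead_s * fs); np <- round(dur_s * fs)
  m <- matrix(0, nrow = 2 * lead + np, ncol = 6,
              dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  m[, "az"] <- 1
  m[(lead + 1):(lead + np), "gz"] <- amp
  imu_sequence(m, fs)
}

# Random multichannel sequence for DTW oracle checks.
rand_seq <- function(n, nch = 6) matrix(rnorm(n * nch), nrow = n)
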