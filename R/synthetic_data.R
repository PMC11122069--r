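# Seeded synthetic gesture generator: labeled 6-channel segments and
# continuous streams with ground truth, emulating the biphasic
# rotate-and-return angular-velocity pulse of each head-gesture class.

# Axis x sign design: each class puts its biphasic pulse on one gyro axis
# with a class-specific first-lobe sign; the mapping is a bijection onto the
# six classes, so the clean prototypes are mutually identifiable.
GESTURE_AXIS <- c(nod = "gz", tilt_up = "gz",
                  shake_left = "gx", shake_right = "gx",
                  tilt_left = "gy", tilt_right = "gy")
GESTURE_SIGN <- c(nod = -1, tilt_up = 1,
                  shake_left = 1, shake_right = -1,
                  tilt_left = 1, tilt_right = -1)
ACCEL_FOR_GYRO <- c(gx = "ax", gy = "ay", gz = "az")

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_rng_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-generator configuration
#'
#' The defaults define the simulated recording conditions: 100 Hz sampling,
#' gesture durations uniform in 0.8–1.6 s, peak amplitudes uniform in
#' 0.8–2.5 rad/s, Gaussian lobes of width 0.12 x duration, Gaussian sensor
#' noise (0.05 rad/s gyro, 0.02 g accelerometer), sparse salt-and-pepper
#' impulses (probability 0.002 per sample, 3 rad/s), smooth monotone
#' time-warp jitter of strength 0.15, and inter-gesture quiet gaps of
#' 0.8–2.0 s in streams.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_range,amplitude_range,gap_range Uniform draw ranges:
#'   seconds, rad/s, seconds.
#' @param lobe_width_frac Gaussian lobe sigma as a fraction of duration.
#' @param gyro_noise_sd,accel_noise_sd Gaussian noise s.d. (rad/s, g).
#' @param impulse_prob,impulse_magnitude Salt-and-pepper impulse probability
#'   per sample and magnitude (rad/s), applied to one random gyro channel.
#' @param time_warp_strength Strength of the smooth monotone re-timing
#'   (0 disables; values below ~0.6 keep the warp strictly monotone).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(fs = 100,
                             duration_range = c(0.8, 1.6),
                             amplitude_range = c(0.8, 2.5),
                             lobe_width_frac = 0.12,
                             gyro_noise_sd = 0.05,
                             accel_noise_sd = 0.02,
                             impulse_prob = 0.002,
                             impulse_magnitude = 3,
                             time_warp_strength = 0.15,
                             gap_range = c(0.8, 2.0)) {
  stopifnot(fs > 0, length(duration_range) == 2, length(amplitude_range) == 2,
            length(gap_range) == 2)
  if (diff(duration_range) <= 0 || diff(amplitude_range) <= 0 ||
      diff(gap_range) <= 0 || duration_range[1] <= 0 ||
      amplitude_range[1] <= 0 || gap_range[1] <= 0)
    stop("generator ranges must be positive and non-degenerate")
  if (impulse_prob < 0 || impulse_prob > 1)
    stop("`impulse_prob` must lie in [0, 1]")
  if (lobe_width_frac <= 0) stop("`lobe_width_frac` must be > 0")
  if (gyro_noise_sd < 0 || accel_noise_sd < 0 || time_warp_strength < 0)
    stop("noise and warp strengths must be >= 0")
  structure(list(fs = fs, duration_range = duration_range,
                 amplitude_range = amplitude_range,
                 lobe_width_frac = lobe_width_frac,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 impulse_prob = impulse_prob,
                 impulse_magnitude = impulse_magnitude,
                 time_warp_strength = time_warp_strength,
                 gap_range = gap_range),
            class = "generator_config")
}

# One clean (noise-free, gravity-free) gesture pulse, drawn from the current
# RNG stream. Returns the n x 6 pulse matrix (zero baseline) and draw info.
gesture_pulse <- function(label, cfg) {
  label <- match.arg(label, GESTURES)
  dur <- runif(1, cfg$duration_range[1], cfg$duration_range[2])
  amp <- runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2])
  u <- runif(1, -1, 1)  # signed jitter draw
  n <- seconds_to_samples(dur, cfg$fs)
  # effective span (n - 1)/fs so the sample grid is symmetric about its
  # midpoint and the biphasic pulse integrates to zero on the grid
  Teff <- (n - 1) / cfg$fs
  t <- (seq_len(n) - 1) / cfg$fs
  tw <- t + cfg$time_warp_strength * u * (Teff / 4) * sin(2 * pi * t / Teff)
  sigma <- cfg$lobe_width_frac * Teff
  g1 <- exp(-(tw - 0.25 * Teff)^2 / (2 * sigma^2))
  g2 <- exp(-(tw - 0.75 * Teff)^2 / (2 * sigma^2))
  pulse <- matrix(0, nrow = n, ncol = 6,
                  dimnames = list(NULL, IMU_CHANNELS))
  axis <- GESTURE_AXIS[[label]]
  sgn <- GESTURE_SIGN[[label]]
  pulse[, axis] <- sgn * amp * (g1 - g2)
  # class-correlated small accelerometer bump on the paired accel axis
  pulse[, ACCEL_FOR_GYRO[[axis]]] <- sgn * 0.08 * amp *
    exp(-(tw - 0.5 * Teff)^2 / (2 * (2 * sigma)^2))
  list(pulse = pulse, n = n, duration = dur, amplitude = amp)
}

# Add Gaussian sensor noise and sparse gyro impulses in place.
add_sensor_noise <- function(mat, cfg) {
  n <- nrow(mat)
  if (n == 0L) return(mat)
  if (cfg$accel_noise_sd > 0)
    mat[, 1:3] <- mat[, 1:3] + rnorm(3 * n, sd = cfg$accel_noise_sd)
  if (cfg$gyro_noise_sd > 0)
    mat[, 4:6] <- mat[, 4:6] + rnorm(3 * n, sd = cfg$gyro_noise_sd)
  if (cfg$impulse_prob > 0) {
    hit <- which(runif(n) < cfg$impulse_prob)
    if (length(hit)) {
      ch <- 3L + sample(3L, length(hit), replace = TRUE)
      sg <- sample(c(-1, 1), length(hit), replace = TRUE)
      mat[cbind(hit, ch)] <- mat[cbind(hit, ch)] + sg * cfg$impulse_magnitude
    }
  }
  mat
}

#' Generate one synthetic labeled gesture segment
#'
#' The primary gyro channel of the class carries a biphasic pulse
#' `A * (G(t; mu1, sigma) - G(t; mu2, sigma))` (Gaussian lobes, lobe centers
#' at 1/4 and 3/4 of the duration) with the class's first-lobe sign, warped
#' by a smooth monotone re-timing; the paired accelerometer channel carries
#' a small class-correlated bump; gravity (1 g) sits on `az`; Gaussian noise
#' and sparse impulses are added last. Deterministic for fixed
#' `(label, cfg, seed)`.
#'
#' @param label One of [gesture_classes()].
#' @param cfg A `generator_config`.
#' @param seed Integer seed.
#' @return A `labeled_segment`.
#' @export
generate_gesture <- function(label, cfg = generator_config(), seed = 1) {
  with_rng_seed(seed, {
    core <- gesture_pulse(label, cfg)
    mat <- core$pulse
    mat[, "az"] <- mat[, "az"] + 1  # gravity, device near-level
    mat <- add_sensor_noise(mat, cfg)
    labeled_segment(imu_sequence(mat, fs = cfg$fs), label)
  })
}

#' Generate a class-balanced labeled dataset
#'
#' Emits `n_per_class` segments for each of the six classes (class-major
#' order). Per-segment seeds are drawn deterministically from the master
#' seed, so the dataset is a pure function of `(n_per_class, cfg, seed)`.
#'
#' @param n_per_class Segments per class, >= 1.
#' @param cfg A `generator_config`.
#' @param seed Master integer seed.
#' @return List of `6 * n_per_class` `labeled_segment` objects.
#' @export
generate_dataset <- function(n_per_class, cfg = generator_config(), seed = 1) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  total <- 6L * as.integer(n_per_class)
  seeds <- with_rng_seed(seed, sample.int(2147483646L, total))
  labels <- rep(GESTURES, each = n_per_class)
  lapply(seq_len(total), function(i)
    generate_gesture(labels[i], cfg, seed = seeds[i]))
}

#' Generate a continuous stream with embedded gestures and ground truth
#'
#' Gestures for the given label sequence are embedded, in order, into a
#' quiet baseline (gravity on `az`, otherwise zero) separated by quiet gaps
#' drawn from `cfg$gap_range`; Gaussian noise and impulses are then added
#' over the whole stream. Each ground-truth interval is the support of the
#' clean (pre-noise) pulse's angular-velocity magnitude above 0.01 rad/s —
#' truth is defined on the clean signal so detector scoring cannot reward
#' fitting noise.
#'
#' @param labels Non-empty character vector of gesture classes, in order.
#' @param cfg A `generator_config`.
#' @param seed Integer seed.
#' @return List with `stream` (an `imu_sequence`) and `truth` (data frame
#'   with columns `start`, `end` — 0-based half-open sample indices — and
#'   `label`), intervals disjoint and ordered.
#' @export
generate_stream <- function(labels, cfg = generator_config(), seed = 1) {
  if (length(labels) == 0L) stop("`labels` must be non-empty")
  labels <- vapply(labels, match.arg, character(1), choices = GESTURES)
  with_rng_seed(seed, {
    gaps <- runif(length(labels) + 1L, cfg$gap_range[1], cfg$gap_range[2])
    gap_n <- seconds_to_samples(gaps, cfg$fs)
    pulses <- lapply(labels, gesture_pulse, cfg = cfg)
    total <- sum(gap_n) + sum(vapply(pulses, `[[`, integer(1), "n"))
    mat <- matrix(0, nrow = total, ncol = 6,
                  dimnames = list(NULL, IMU_CHANNELS))
    truth <- data.frame(start = integer(length(labels)),
                        end = integer(length(labels)),
                        label = labels, stringsAsFactors = FALSE)
    off <- gap_n[1]  # 0-based offset of the next gesture
    for (i in seq_along(pulses)) {
      p <- pulses[[i]]
      rows <- (off + 1L):(off + p$n)
      mat[rows, ] <- mat[rows, ] + p$pulse
      mag <- sqrt(rowSums(p$pulse[, 4:6, drop = FALSE]^2))
      supp <- which(mag > 0.01)
      truth$start[i] <- off + min(supp) - 1L
      truth$end[i] <- off + max(supp)
      off <- off + p$n + gap_n[i + 1L]
    }
    mat[, "az"] <- mat[, "az"] + 1
    mat <- add_sensor_noise(mat, cfg)
    list(stream = imu_sequence(mat, fs = cfg$fs), truth = truth)
  })
}
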