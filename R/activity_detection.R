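# Endpoint (activity) detection on the angular-velocity magnitude, segment
# extraction, and detector parameter sweeps.

#' Endpoint-detector configuration
#'
#' @param ang_min Angular-velocity-magnitude threshold in rad/s; a gesture
#'   opens when the magnitude first exceeds it. Default 0.2.
#' @param t_interval_s Quiet-window duration in seconds: a gesture is
#'   declared ended once the magnitude has stayed below `ang_min` for this
#'   long (so the threshold crossing at the trough between the two pulse
#'   lobes does not split a gesture); also the minimum separation between
#'   consecutive gestures. Default 0.3.
#' @param t_min_s Minimum valid gesture duration (s); rejects sharp spike
#'   noise. Default 0.6.
#' @param t_max_s Maximum valid gesture duration (s); rejects abnormal or
#'   incomplete movements. Default 2.5.
#' @param strict_quiet_window If TRUE (default) the end rule requires the
#'   magnitude below `ang_min` on the entire window `[t - t_interval, t]`;
#'   if FALSE only the two endpoint samples `t` and `t - t_interval` are
#'   tested (the literal two-point rule, kept for comparison).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(ang_min = 0.2, t_interval_s = 0.3,
                             t_min_s = 0.6, t_max_s = 2.5,
                             strict_quiet_window = TRUE) {
  if (!is.finite(ang_min) || ang_min <= 0) stop("`ang_min` must be > 0")
  if (!is.finite(t_interval_s) || t_interval_s <= 0)
    stop("`t_interval_s` must be > 0")
  if (!is.finite(t_min_s) || !is.finite(t_max_s) ||
      t_min_s <= 0 || t_min_s >= t_max_s)
    stop("need 0 < t_min_s < t_max_s")
  structure(list(ang_min = ang_min, t_interval_s = t_interval_s,
                 t_min_s = t_min_s, t_max_s = t_max_s,
                 strict_quiet_window = isTRUE(strict_quiet_window)),
            class = "detection_config")
}

#' Angular-velocity magnitude
#'
#' `ang(t) = sqrt(gx(t)^2 + gy(t)^2 + gz(t)^2)` — the single decision signal
#' of the endpoint detector; it looks alike across gesture classes, which is
#' what makes it usable for class-agnostic activity detection.
#'
#' @param x An `imu_sequence` (non-empty).
#' @return Numeric vector of non-negative magnitudes, one per sample.
#' @export
angular_magnitude <- function(x) {
  stopifnot(inherits(x, "imu_sequence"))
  if (nrow(x) == 0L) stop("angular_magnitude: empty sequence")
  sqrt(rowSums(x[, c("gx", "gy", "gz"), drop = FALSE]^2))
}

# Median-filtered (and optionally normalized) magnitude used by the
# detector. Filtering is applied per gyro channel before the magnitude.
detection_signal <- function(x, pp) {
  fs <- sampling_rate(x)
  l <- seconds_to_samples(pp$t_win_s, fs)
  g <- x[, c("gx", "gy", "gz"), drop = FALSE]
  if (pp$normalize_for_detection) g <- normalize_arctan(g)
  gf <- apply(g, 2, median_filter, l = l)
  if (nrow(x) == 1L) gf <- matrix(gf, nrow = 1)
  sqrt(rowSums(gf^2))
}

#' Detect gesture segments in a continuous IMU stream
#'
#' Scans the median-filtered angular-velocity magnitude left to right. A
#' segment opens at the first sample whose magnitude exceeds `ang_min`
#' while no segment is open. An open segment closes at the first sample `t`
#' such that the magnitude stays below `ang_min` over the whole trailing
#' quiet window of `t_interval` seconds ending at `t` (or, with
#' `strict_quiet_window = FALSE`, such that just the two samples `t` and
#' `t - t_interval` are below). The closed candidate is kept iff its
#' duration lies strictly between `t_min` and `t_max`. While a segment is
#' open the start rule is not re-evaluated; scanning resumes after the end
#' sample, so returned segments are disjoint, ordered, and separated by at
#' least `t_interval` of sub-threshold signal. A candidate still open at the
#' end of the stream is discarded (its end cannot be confirmed).
#'
#' @param x An `imu_sequence` at least `t_interval` long.
#' @param cfg A `detection_config`.
#' @param pp A `preprocess_config` (its `t_win_s` and
#'   `normalize_for_detection` are used here).
#' @return List of `gesture_segment` (possibly empty). The returned `end`
#'   excludes the sample at which the quiet-window rule fired, so segments
#'   carry up to `t_interval` of trailing quiet and
#'   `duration = (end - start)/fs` equals the end-time minus start-time of
#'   the detection rules.
#' @export
detect_segments <- function(x, cfg = detection_config(),
                            pp = preprocess_config()) {
  stopifnot(inherits(x, "imu_sequence"), inherits(cfg, "detection_config"))
  n <- nrow(x)
  fs <- sampling_rate(x)
  w <- seconds_to_samples(cfg$t_interval_s, fs)
  if (n < w) stop("detection error: stream shorter than the quiet window")
  mag <- detection_signal(x, pp)
  below <- mag < cfg$ang_min
  # quiet_ok[t]: end rule may fire at sample t (1-based)
  quiet_ok <- rep(FALSE, n)
  if (n > w) {
    idx <- (w + 1L):n
    if (cfg$strict_quiet_window) {
      cs <- cumsum(below)
      quiet_ok[idx] <- (cs[idx] - c(0, cs)[idx - w]) == (w + 1L)
    } else {
      quiet_ok[idx] <- below[idx] & below[idx - w]
    }
  }
  dur_min <- cfg$t_min_s * fs
  dur_max <- cfg$t_max_s * fs
  segs <- list()
  t <- 1L
  while (t <= n) {
    if (mag[t] > cfg$ang_min) {
      t_start <- t
      t_end <- NA_integer_
      u <- t + 1L
      while (u <= n) {
        if (quiet_ok[u]) { t_end <- u; break }
        u <- u + 1L
      }
      if (is.na(t_end)) break  # never closed; drop
      d <- t_end - t_start
      if (d > dur_min && d < dur_max)
        segs[[length(segs) + 1L]] <- segment(t_start - 1L, t_end - 1L, fs)
      t <- t_end + 1L
    } else {
      t <- t + 1L
    }
  }
  segs
}

#' Extract detected segments from a stream
#'
#' @param x The source `imu_sequence`.
#' @param segs List of `gesture_segment` within bounds.
#' @return List of `imu_sequence`, one per segment, of length `end - start`.
#' @export
extract_segments <- function(x, segs) {
  stopifnot(inherits(x, "imu_sequence"))
  n <- nrow(x)
  lapply(segs, function(s) {
    if (s$end > n) stop("index error: segment [", s$start, ", ", s$end,
                        ") out of bounds for ", n, " samples")
    imu_sequence(x[(s$start + 1L):s$end, , drop = FALSE],
                 fs = sampling_rate(x))
  })
}

#' Sweep one detector parameter over a value grid
#'
#' Re-runs [detect_segments()] on the same stream once per grid value,
#' varying only the named parameter, and marks the values at which the
#' detected-segment count equals the expected count — the procedure used to
#' select `ang_min`, `t_min` and the filter window on recorded data.
#'
#' @param x The `imu_sequence` stream.
#' @param expected_count Ground-truth number of gestures in the stream.
#' @param which One of `"ang_min"`, `"t_interval_s"`, `"t_min_s"`,
#'   `"t_max_s"`, `"t_win_s"` (the last varies the preprocessing window).
#' @param grid Strictly increasing numeric vector of values to test.
#' @param cfg,pp Base configurations; only `which` is varied.
#' @return A data frame of class `detection_sweep` with columns `value`,
#'   `n_detected`, `correct`, and attributes `parameter` and
#'   `expected_count`.
#' @export
sweep_detection_parameter <- function(x, expected_count, which, grid,
                                      cfg = detection_config(),
                                      pp = preprocess_config()) {
  which <- match.arg(which, c("ang_min", "t_interval_s", "t_min_s",
                              "t_max_s", "t_win_s"))
  if (length(grid) == 0L || any(diff(grid) <= 0))
    stop("config error: grid must be non-empty and strictly increasing")
  counts <- vapply(grid, function(v) {
    cfg_v <- cfg; pp_v <- pp
    if (which == "t_win_s") pp_v$t_win_s <- v else cfg_v[[which]] <- v
    length(detect_segments(x, cfg_v, pp_v))
  }, integer(1))
  out <- data.frame(value = grid, n_detected = counts,
                    correct = counts == expected_count)
  attr(out, "parameter") <- which
  attr(out, "expected_count") <- expected_count
  class(out) <- c("detection_sweep", "data.frame")
  out
}

#' @export
print.detection_sweep <- function(x, ...) {
  ok <- x$value[x$correct]
  cat(sprintf("<detection_sweep> %s over [%g, %g], expected %d segments\n",
              attr(x, "parameter"), min(x$value), max(x$value),
              attr(x, "expected_count")))
  if (length(ok))
    cat(sprintf("  correct count at %d/%d values, range [%g, %g]\n",
                length(ok), nrow(x), min(ok), max(ok)))
  else cat("  correct count at no tested value\n")
  invisible(x)
}
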