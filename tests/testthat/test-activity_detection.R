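test_that("angular magnitude is the Euclidean norm of the gyro channels", {
  m <- rbind(c(0, 0, 1, 0, 0, 0),
             c(0, 0, 1, 3, 4, 0),
             c(0, 0, 1, 1, 1, 1))
  x <- imu_sequence(m, 100)
  expect_equal(angular_magnitude(x), c(0, 5, sqrt(3)))
  expect_true(all(angular_magnitude(x) >= 0))
  expect_error(angular_magnitude(imu_sequence(matrix(numeric(0), 0, 6))))
})

test_that("a single analytic biphasic pulse is detected with tight endpoints", {
  # gz(t) = sin(2*pi*(t - 1)/1.2) on [1.0, 2.2) s, fs = 100, quiet elsewhere
  n <- 400; t <- (0:(n - 1)) / 100
  m <- matrix(0, n, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  m[, "az"] <- 1
  sel <- t >= 1.0 & t < 2.2
  m[sel, "gz"] <- sin(2 * pi * (t[sel] - 1.0) / 1.2)
  x <- imu_sequence(m, 100)
  segs <- detect_segments(x)
  expect_length(segs, 1)
  s <- segs[[1]]
  expect_gte(s$start / 100, 1.00); expect_lte(s$start / 100, 1.05)
  expect_gte(s$end / 100, 2.2);  expect_lte(s$end / 100, 2.2 + 0.3 + 0.05)
  # and it matches the literal brute-force scan
  expect_equal(segs_to_matrix(segs),
               brute_detect(x, detection_config(), preprocess_config()))
})

test_that("quiet streams and unclosed or missing activity yield no segments", {
  quiet <- imu_sequence(matrix(rep(c(0, 0, 1, 0, 0, 0), each = 500), ncol = 6), 100)
  expect_length(detect_segments(quiet), 0)
  expect_error(detect_segments(imu_sequence(matrix(0, 5, 6), 100)),
               "shorter")
})

test_that("two pulses separated by less than t_interval merge into one segment", {
  # two 0.8 s sine pulses, 0.1 s quiet gap: the quiet-window end rule cannot
  # fire inside the gap, so one merged segment of ~1.7 + t_interval s results
  fs <- 100; t1 <- (0:79) / fs
  pulse <- sin(2 * pi * t1 / 0.8)
  gz <- c(rep(0, 200), pulse, rep(0, 10), pulse, rep(0, 200))
  m <- matrix(0, length(gz), 6,
              dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  m[, "az"] <- 1; m[, "gz"] <- gz
  x <- imu_sequence(m, fs)
  segs <- detect_segments(x)
  expect_length(segs, 1)
  expect_gt(segment_duration(segs[[1]]), 1.5)
  # widen the gap beyond t_interval and the pulses separate
  gz2 <- c(rep(0, 200), pulse, rep(0, 60), pulse, rep(0, 200))
  m2 <- matrix(0, length(gz2), 6,
               dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  m2[, "gz"] <- gz2; m2[, "az"] <- 1
  segs2 <- detect_segments(imu_sequence(m2, fs))
  expect_length(segs2, 2)
})

test_that("the duration gate rejects short spikes and overlong activity", {
  pp1 <- preprocess_config(t_win_s = 0.01)  # 1-sample window isolates the gate
  expect_length(detect_segments(rect_pulse_stream(0.1), detection_config(), pp1), 0)
  expect_length(detect_segments(rect_pulse_stream(3.0), detection_config(), pp1), 0)
  expect_length(detect_segments(rect_pulse_stream(1.0), detection_config(), pp1), 1)
})

test_that("detected segments are disjoint, ordered, gated, and match the brute-force oracle", {
  cfg <- detection_config(); pp <- preprocess_config()
  for (seed in 1:10) {
    set.seed(seed)
    labels <- sample(gesture_classes(), sample(2:4, 1), replace = TRUE)
    st <- generate_stream(labels, generator_config(), seed = 1000 + seed)
    segs <- detect_segments(st$stream, cfg, pp)
    got <- segs_to_matrix(segs)
    expect_equal(got, brute_detect(st$stream, cfg, pp),
                 info = paste("stream seed", seed))
    if (length(segs) > 1) {
      starts <- got[, 1]; ends <- got[, 2]
      expect_true(all(ends[-length(ends)] <= starts[-1]))
    }
    durs <- vapply(segs, segment_duration, numeric(1))
    expect_true(all(durs > cfg$t_min_s & durs < cfg$t_max_s))
    # determinism
    expect_identical(segs_to_matrix(detect_segments(st$stream, cfg, pp)), got)
  }
})

test_that("raising ang_min never increases the count of supra-threshold samples", {
  st <- generate_stream(rep(gesture_classes(), 2), seed = 17)
  l <- seconds_to_samples(0.3, 100)
  g <- apply(unclass(st$stream)[, c("gx","gy","gz")], 2, median_filter, l = l)
  mag <- sqrt(rowSums(g^2))
  thresholds <- seq(0.01, 0.42, by = 0.01)
  counts <- vapply(thresholds, function(a) sum(mag > a), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("extraction copies the right samples and checks bounds", {
  x <- imu_sequence(matrix(seq_len(600), ncol = 6), 100)
  out <- extract_segments(x, list(segment(10, 60, 100)))
  expect_length(out, 1)
  expect_identical(n_samples(out[[1]]), 50L)
  expect_equal(unclass(out[[1]]), unclass(x)[11:60, ], tolerance = 0,
               ignore_attr = "fs")
  expect_identical(extract_segments(x, list()), list())
  expect_error(extract_segments(x, list(segment(90, 120, 100))), "out of bounds")
})

test_that("parameter sweeps mark the correct-count values and validate their grid", {
  st <- generate_stream(rep(gesture_classes(), 2), seed = 8)
  expect_error(sweep_detection_parameter(st$stream, 12, "ang_min", numeric(0)))
  expect_error(sweep_detection_parameter(st$stream, 12, "ang_min", c(0.2, 0.1)))
  expect_error(sweep_detection_parameter(st$stream, 12, "bogus", c(0.1, 0.2)))

  grid <- seq(0.05, 0.42, by = 0.037)
  sw <- sweep_detection_parameter(st$stream, 12, "ang_min", grid)
  expect_s3_class(sw, "detection_sweep")
  expect_identical(sw$value, grid)
  # counts agree with running the detector directly at each grid value
  direct <- vapply(grid, function(a)
    length(detect_segments(st$stream, detection_config(ang_min = a))),
    integer(1))
  expect_identical(sw$n_detected, direct)
  expect_identical(sw$correct, direct == 12)
  # a single-point grid at the defaults recovers all planted gestures
  sw1 <- sweep_detection_parameter(st$stream, 12, "ang_min", 0.2)
  expect_identical(sw1$n_detected, 12L)
  expect_true(sw1$correct)
  # threshold above the global maximum of the magnitude detects nothing
  hi <- max(angular_magnitude(st$stream)) + 1
  sw_hi <- sweep_detection_parameter(st$stream, 12, "ang_min", hi)
  expect_identical(sw_hi$n_detected, 0L)
  expect_false(sw_hi$correct)
})

test_that("the marked correct-count set of an ang_min sweep is a contiguous grid interval", {
  st <- generate_stream(rep(gesture_classes(), 2), seed = 21)
  grid <- seq(0.02, 0.42, by = 0.02)
  sw <- sweep_detection_parameter(st$stream, 12, "ang_min", grid)
  marked <- which(sw$correct)
  expect_gt(length(marked), 0)
  expect_identical(marked, seq(min(marked), max(marked)))
})
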