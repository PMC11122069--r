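test_that("template averaging follows the median-length element-wise rule", {
  # single segment: template equals the segment
  set.seed(2)
  one <- imu_sequence(matrix(rnorm(42), ncol = 6), 100)
  tpl <- build_template(list(one), "nod")
  expect_identical(tpl$m, 7L)
  expect_equal(tpl$channels, unclass(one), ignore_attr = TRUE)
  expect_identical(tpl$n_sources, 1L)

  # lengths 3 and 5: m = 4; position 4 averages only the longer segment
  a <- matrix(1, 3, 6); b <- matrix(3, 5, 6)
  tpl2 <- build_template(list(a, b), "tilt_up")
  expect_identical(tpl2$m, 4L)
  expect_equal(unname(tpl2$channels[, 1]), c(2, 2, 2, 3))
  expect_true(all(apply(tpl2$channels, 1, function(r) length(unique(r)) == 1)))

  # even-count median of lengths rounds half down: lengths 3 and 4 -> m = 3
  tpl3 <- build_template(list(matrix(0, 3, 6), matrix(0, 4, 6)), "nod")
  expect_identical(tpl3$m, 3L)

  # identical segments average to themselves
  tpl4 <- build_template(rep(list(unclass(one)), 5), "shake_left")
  expect_equal(tpl4$channels, unclass(one), ignore_attr = TRUE)

  expect_error(build_template(list(), "nod"))
  expect_error(build_template(list(matrix(0, 3, 6), matrix(0, 3, 4)), "nod"),
               "channel count")
})

test_that("the pointwise distance matrix is the per-pair Euclidean metric", {
  v <- matrix(c(1, 0, 0, 0, 0, 0), 1)
  z <- matrix(0, 1, 6)
  ones <- matrix(1, 1, 6)
  expect_equal(dtw_distance_matrix(z, z), matrix(0, 1, 1))
  expect_equal(dtw_distance_matrix(v, z), matrix(1, 1, 1))
  expect_equal(dtw_distance_matrix(ones, z), matrix(sqrt(6), 1, 1))
  expect_equal(dtw_distance_matrix(ones, z, squared = TRUE), matrix(6, 1, 1))
  expect_error(dtw_distance_matrix(matrix(0, 2, 6), matrix(0, 2, 3)),
               "channel counts differ")
})

test_that("DTW alignment solves small analytic cases", {
  set.seed(5)
  s <- matrix(rnorm(24), ncol = 6)
  self <- dtw_align(s, s)
  expect_equal(self$distance, 0)
  expect_identical(self$k, nrow(s))
  expect_equal(self$path, cbind(i = 1:4, j = 1:4))
  expect_equal(self$normalized_distance, 0)

  # 1-channel S = (1,2,3), T = (1,3): absolute difference as pointwise cost
  r <- dtw_align(matrix(c(1, 2, 3)), matrix(c(1, 3)))
  expect_equal(r$distance, 1)
  expect_true(identical(unname(r$path), cbind(1:3, c(1L, 1L, 2L))) ||
              identical(unname(r$path), cbind(1:3, c(1L, 2L, 2L))))
  expect_equal(r$normalized_distance, 1 / 3)

  # single-cell grid
  r1 <- dtw_align(matrix(0), matrix(1))
  expect_equal(r1$distance, 1)
  expect_identical(r1$k, 1L)
})

test_that("DTW equals exhaustive minimization over all warp paths", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    s <- rand_seq(n); t <- rand_seq(m)
    r <- dtw_align(s, t)
    d <- dtw_distance_matrix(s, t)
    expect_equal(r$distance, brute_dtw_distance(d),
                 info = sprintf("n=%d m=%d rep=%d", n, m, rep))
  }
})

test_that("warp paths respect boundary, continuity, monotonicity, and length bounds", {
  set.seed(303)
  for (rep in 1:50) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    r <- dtw_align(rand_seq(n), rand_seq(m))
    p <- r$path
    expect_equal(unname(p[1, ]), c(1, 1))
    expect_equal(unname(p[nrow(p), ]), c(n, m))
    if (nrow(p) > 1) {
      steps <- diff(p)
      expect_true(all(steps >= 0 & steps <= 1))
      expect_true(all(rowSums(steps) >= 1))
    }
    expect_gte(r$k, max(n, m))
    expect_lte(r$k, n + m)      # printed bound
    expect_lte(r$k, n + m - 1)  # sharper bound
    # cumulative grid is consistent with the recursion's corner value
    expect_equal(r$distance, r$cumulative[n, m])
  }
})

test_that("DTW distance is symmetric, zero iff aligned-identical, and translation invariant", {
  set.seed(77)
  for (rep in 1:20) {
    s <- rand_seq(sample(2:10, 1)); t <- rand_seq(sample(2:10, 1))
    expect_equal(dtw_distance(s, t), dtw_distance(t, s))
    expect_equal(dtw_distance(s, s), 0)
    expect_gt(dtw_distance(s, t), 0)
    s2 <- s; t2 <- t
    s2[, 3] <- s2[, 3] + 4.2; t2[, 3] <- t2[, 3] + 4.2
    expect_equal(dtw_distance(s2, t2), dtw_distance(s, t))
  }
})

test_that("classification returns the nearest template with deterministic tie-breaking", {
  cfg <- quiet_cfg()
  pp <- preprocess_config()
  train <- lapply(gesture_classes(), function(lab)
    generate_gesture(lab, cfg, seed = 40 + match(lab, gesture_classes())))
  ts <- build_template_set(train, pp)
  expect_true(is_complete(ts))
  # each training segment is its own template (n_sources = 1): self-match
  for (s in train) {
    cls <- classify_gesture(s$data, ts, pp)
    expect_identical(cls$label, s$label)
    expect_equal(unname(cls$distances[s$label]), 0)
    expect_identical(names(cls$distances), sort(gesture_classes()))
  }
  # exact all-way tie: six identical templates -> lexicographically first
  flat <- lapply(gesture_classes(), function(lab)
    gesture_template(lab, matrix(0.1, 10, 6), 1))
  ts_flat <- template_set(flat, preprocess = preprocess_fingerprint(pp))
  tie <- classify_gesture(train[[3]]$data, ts_flat, pp)
  expect_identical(tie$label, sort(gesture_classes())[1])
  expect_equal(max(tie$distances) - min(tie$distances), 0)
})

test_that("classification refuses incomplete template sets and mismatched preprocessing", {
  cfg <- quiet_cfg()
  pp <- preprocess_config()
  train <- lapply(gesture_classes()[1:5], function(lab)
    generate_gesture(lab, cfg, seed = 7))
  ts5 <- build_template_set(train, pp)
  g <- generate_gesture("nod", cfg, seed = 1)
  expect_error(classify_gesture(g$data, ts5, pp), "incomplete")

  full <- build_template_set(c(train, list(generate_gesture("tilt_right", cfg, 8))), pp)
  expect_error(classify_gesture(g$data, full, preprocess_config(t_win_s = 0.2)),
               "fingerprint")
  expect_error(classify_gesture(g$data, full, preprocess_config(normalize = FALSE)),
               "fingerprint")
})

test_that("templates from more noisy copies recover the prototype better", {
  fixed <- generator_config(duration_range = pinned(1.2),
                            amplitude_range = pinned(1.5),
                            gyro_noise_sd = 0, accel_noise_sd = 0,
                            impulse_prob = 0, time_warp_strength = 0)
  proto <- generate_gesture("nod", fixed, seed = 1)$data
  noisy <- generator_config(duration_range = pinned(1.2),
                            amplitude_range = pinned(1.5))
  mae <- function(N) {
    segs <- lapply(seq_len(N), function(i)
      generate_gesture("nod", noisy, seed = 100 + i)$data)
    tpl <- build_template(segs, "nod")
    mean(abs(tpl$channels - unclass(proto)[seq_len(tpl$m), ]))
  }
  expect_lt(mae(50), mae(5))
})
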