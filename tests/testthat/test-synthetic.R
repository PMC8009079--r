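test_that("generate_segment honors the zero-noise constant case and its contracts", {
  sitting <- activity_profile("Sitting", gravity = c(0, 9.8, 0),
                              oscillations = list(), noise_sd = 0)
  seg <- generate_segment(sitting, 200, 20, seed = 1)
  expect_equal(dim(seg), c(200L, 3L))
  expect_true(all(seg[, 1] == 0))
  expect_true(all(seg[, 2] == 9.8))
  expect_true(all(seg[, 3] == 0))

  # length and clipping contract for an arbitrary noisy profile
  jog <- default_activity_profiles()$Jogging
  s <- generate_segment(jog, 200, 20, seed = 5)
  expect_equal(nrow(s), 200L)
  expect_true(all(s >= -20 & s <= 20))

  # determinism: same profile and seed twice -> bit-identical
  expect_identical(generate_segment(jog, 200, 20, seed = 9),
                   generate_segment(jog, 200, 20, seed = 9))
  expect_false(identical(generate_segment(jog, 200, 20, seed = 9),
                         generate_segment(jog, 200, 20, seed = 10)))

  expect_error(generate_segment(jog, 0, 20), "positive")
  expect_error(generate_segment(jog, 100, -5), "positive")
})

test_that("generate_dataset emits one contiguous segment per (user, activity)", {
  spec <- synth_spec(n_users = 2, segment_duration_s = 10, rate_hz = 20,
                     seed = 7)
  d <- generate_dataset(spec)
  expect_equal(nrow(d), 2 * 6 * 200)
  expect_setequal(unique(d$activity), har_activities())
  # timestamps strictly increasing within each user, at 50 ms spacing
  for (u in 1:2) {
    ts <- d$timestamp[d$user_id == u]
    expect_true(all(diff(ts) == 5e7))
  }
  # pure function of the spec
  expect_identical(d, generate_dataset(spec))
  d2 <- generate_dataset(synth_spec(n_users = 2, segment_duration_s = 10,
                                    seed = 8))
  expect_false(identical(d$x, d2$x))
})

test_that("profile and spec validation rejects out-of-bound configurations", {
  expect_error(activity_profile("A", noise_sd = -1), "non-negative")
  expect_error(
    synth_spec(profiles = list(activity_profile("A",
      oscillations = list(list(axis = 2, freq_hz = 15, amplitude = 1))))),
    "Nyquist")
  expect_error(
    synth_spec(profiles = list(activity_profile("A", gravity = c(0, 15, 0),
      oscillations = list(list(axis = 2, freq_hz = 2, amplitude = 8))))),
    "bound")
  expect_error(synth_spec(segment_duration_s = 0.33, rate_hz = 20), "whole")
})

test_that("default profiles are linearly separable on window mean/variance features", {
  spec <- synth_spec(n_users = 4, segment_duration_s = 30, seed = 11)
  d <- generate_dataset(spec)
  w <- extract_windows(d, size = 200, stride = 50)
  feats <- t(vapply(w, function(win)
    c(colMeans(win$data), apply(win$data, 2, var)), numeric(6)))
  labs <- vapply(w, `[[`, character(1), "label")
  users <- vapply(w, function(win) win$origin$user_id, integer(1))
  train <- users <= 2
  centroids <- sapply(har_activities(), function(a)
    colMeans(feats[train & labs == a, , drop = FALSE]))
  pred <- har_activities()[apply(feats[!train, ], 1, function(f)
    which.min(colSums((centroids - f)^2)))]
  expect_gt(mean(pred == labs[!train]), 0.9)
})

test_that("write/read round trip preserves samples to the written precision", {
  spec <- synth_spec(n_users = 1, segment_duration_s = 2, seed = 3)
  d <- generate_dataset(spec)
  f <- withr::local_tempfile(fileext = ".txt")
  write_wisdm(d, f)
  back <- read_wisdm(f)
  expect_equal(back$report$n_skipped, 0)
  expect_equal(nrow(back$samples), nrow(d))
  expect_equal(back$samples$user_id, d$user_id)
  expect_equal(back$samples$activity, d$activity)
  expect_equal(back$samples$x, d$x, tolerance = 1e-5)
  expect_equal(back$samples$y, d$y, tolerance = 1e-5)
  expect_equal(back$samples$z, d$z, tolerance = 1e-5)
})
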