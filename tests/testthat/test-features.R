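test_that("time-related metrics match their definitions on crafted events", {
  s <- plain_samples()
  fix <- make_fixations(durations = c(0.2, 0.3, 0.4),
                        x = c(100, 250, 400), y = c(100, 100, 100))
  sac <- make_saccades(amplitudes = c(3, 4), durations = c(0.05, 0.1))
  tc <- compute_time_related(s, fix, sac, empty_blinks())

  expect_length(tc, 23)
  expect_equal(unname(tc["mean_fixation_duration"]), 0.3)
  expect_equal(unname(tc["total_fixation_time"]), 0.9)
  expect_equal(unname(tc["max_fixation_time"]), 0.4)
  expect_equal(unname(tc["n_fixations"]), 3)
  expect_equal(unname(tc["fixations_per_second"]), 3 / 5)
  expect_equal(unname(tc["gaze_width"]), 300)

  expect_equal(unname(tc["total_saccade_length"]), 7)
  expect_equal(unname(tc["max_saccade_distance"]), 4)
  expect_equal(unname(tc["mean_saccade_length"]), 3.5)
  expect_equal(unname(tc["total_saccade_time"]), 0.15)
  expect_equal(unname(tc["mean_saccade_speed"]), mean(c(3 / 0.05, 4 / 0.1)))
  expect_equal(unname(tc["overall_saccade_speed"]), 7 / 0.15)

  # zero-blink guards
  expect_equal(unname(tc[c("n_blinks", "blink_rate", "longest_blink_duration",
                           "current_blink_duration", "closed_eye_time")]),
               rep(0, 5))
  expect_equal(unname(tc["mean_pupil_diameter"]), 4)
})

test_that("time-independent metrics match brute-force moment computations", {
  s <- plain_samples()
  fix <- make_fixations(durations = c(0.2, 0.3, 0.4),
                        x = c(100, 250, 400), y = c(100, 200, 300))
  sac <- make_saccades(amplitudes = c(3, 4))
  tic <- compute_time_independent(s, fix, sac, empty_blinks())

  expect_length(tic, 21)
  expect_equal(unname(tic["median_fixation_duration"]), 0.3)
  # population standard deviation of {0.2, 0.3, 0.4}
  expect_equal(unname(tic["fixation_duration_sd"]),
               sqrt(mean((c(0.2, 0.3, 0.4) - 0.3)^2)), tolerance = 1e-12)
  expect_equal(unname(tic["horizontal_range"]), 300)
  expect_equal(unname(tic["vertical_range"]), 200)
  expect_equal(unname(tic["fixation_time_ratio"]), 0.9 / 5)

  # symmetric durations: zero skewness; kurtosis from the raw moments
  d <- c(0.2, 0.3, 0.4)
  m2 <- mean((d - mean(d))^2); m4 <- mean((d - mean(d))^4)
  expect_equal(unname(tic["fixation_duration_skewness"]), 0, tolerance = 1e-9)
  expect_equal(unname(tic["fixation_duration_kurtosis"]), m4 / m2^2 - 3)

  # single saccade: skewness/kurtosis fall back to 0
  tic1 <- compute_time_independent(s, fix, make_saccades(5), empty_blinks())
  expect_equal(unname(tic1["saccade_distance_skewness"]), 0)
  expect_equal(unname(tic1["saccade_distance_kurtosis"]), 0)
})

test_that("every window yields 44 finite values whatever the event content", {
  manifest <- feature_manifest()
  expect_equal(nrow(manifest), 44)
  expect_equal(sum(manifest$group == "tc"), 23)
  expect_equal(sum(manifest$group == "tic"), 21)

  # degenerate window: no events at all
  s <- plain_samples()
  no_fix <- make_fixations(numeric(0), numeric(0), numeric(0))
  no_sac <- make_saccades(numeric(0))
  v <- c(compute_time_related(s, no_fix, no_sac, empty_blinks()),
         compute_time_independent(s, no_fix, no_sac, empty_blinks()))
  expect_length(v, 44)
  expect_true(all(is.finite(v)))

  # simulated windows, including blink-rich ones
  rec <- preprocess_recording(simulate_recording(
    scanpath_params(blink_rate = 40), duration = 120, seed = 31))
  w <- assign_labels(slide_windows(rec), rec$episodes)
  fm <- recording_features(rec, w)
  expect_equal(ncol(fm$features), 44)
  expect_true(all(is.finite(fm$features)))
  expect_identical(colnames(fm$features), manifest$name)
})

test_that("min-max normalisation maps endpoints, clips, and flags degeneracy", {
  p <- fit_minmax(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(unname(p$min), 2)
  expect_equal(unname(p$max), 6)
  expect_equal(unname(apply_minmax(matrix(4), p)[1, 1]), 0.5)
  expect_equal(unname(apply_minmax(matrix(2), p)[1, 1]), 0)
  expect_equal(unname(apply_minmax(matrix(6), p)[1, 1]), 1)
  expect_equal(unname(apply_minmax(matrix(8), p)[1, 1]), 1)   # clipped
  expect_equal(unname(apply_minmax(matrix(0), p)[1, 1]), 0)   # clipped

  pc <- fit_minmax(matrix(c(5, 5), ncol = 1))
  expect_true(pc$degenerate)
  expect_equal(unname(apply_minmax(matrix(5), pc)[1, 1]), 0)

  # order independence
  p2 <- fit_minmax(matrix(c(6, 2, 4), ncol = 1))
  expect_equal(p$min, p2$min)
  expect_equal(p$max, p2$max)

  expect_error(fit_minmax(matrix(numeric(0), ncol = 2)), "empty")

  # params fitted on the data itself attain both endpoints per feature
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  pf <- fit_minmax(X)
  N <- apply_minmax(X, pf)
  expect_true(all(N >= 0 & N <= 1))
  expect_equal(unname(apply(N, 2, min)), rep(0, 4))
  expect_equal(unname(apply(N, 2, max)), rep(1, 4))
})

test_that("sequence assembly follows the sliding rule and labels by final window", {
  X <- matrix(seq_len(8 * 44), 8, 44)
  lab <- c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L)
  sq <- assemble_sequences(X, lab)
  expect_equal(n_sequences(sq), 3)
  expect_equal(dim(sq$tc), c(3, 6, 23))
  expect_equal(dim(sq$tic), c(3, 6, 21))
  expect_equal(sq$labels, c(1L, 0L, 1L))       # labels of windows 6, 7, 8
  # content check: sequence 2 event 1 is window 2
  expect_equal(sq$tc[2, 1, ], X[2, 1:23])
  expect_equal(sq$tic[2, 1, ], X[2, 24:44])

  expect_equal(n_sequences(assemble_sequences(X[1:6, ], lab[1:6])), 1)
  expect_equal(n_sequences(assemble_sequences(X[1:5, ], lab[1:5])), 0)
})

test_that("sequence-level normalisation is leak-free and bounded", {
  sq <- toy_sequences(n = 30, seed = 4)
  train <- subset_sequences(sq, 1:20)
  valid <- subset_sequences(sq, 21:30)
  p <- fit_sequence_minmax(train)
  vn <- apply_sequence_minmax(valid, p)
  tn <- apply_sequence_minmax(train, p)
  expect_true(all(vn$tc >= 0 & vn$tc <= 1))
  expect_true(all(tn$tic >= 0 & tn$tic <= 1))
  # params depend on the training subset only
  p2 <- fit_sequence_minmax(subset_sequences(sq, 1:20))
  expect_identical(p, p2)
  p3 <- fit_sequence_minmax(sq)
  expect_false(identical(p$tc$max, p3$tc$max))
})

test_that("class balancing equalises labels and keeps sequences intact", {
  sq <- toy_sequences(n = 40, seed = 6)
  sq$labels <- c(rep(1L, 8), rep(0L, 32))
  b <- balance_sequences(sq, seed = 1)
  expect_equal(sum(b$labels == 1), 8)
  expect_equal(sum(b$labels == 0), 8)
})
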