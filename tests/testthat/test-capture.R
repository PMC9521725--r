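make_train <- function(s1_times, s2_time = NA_real_) {
  structure(list(s1_times = s1_times,
                 s1_interval = if (length(s1_times) > 1)
                   stats::median(diff(s1_times)) else 600,
                 s2_time = s2_time,
                 s2_coupling_interval = if (is.na(s2_time)) NA_real_ else
                   s2_time - s1_times[length(s1_times)],
                 has_s2 = !is.na(s2_time)),
            class = "pace_train")
}

test_that("segment extraction returns one equal-length window per beat and lead", {
  sim <- clean_sim(c(0, 20, 40))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  seg <- extract_beat_segments(sim$recording, tr)
  expect_length(seg$segments, 9)
  lens <- vapply(seg$segments, nrow, integer(1))
  expect_true(all(lens == lens[1]))
  expect_true(all(vapply(seg$segments, ncol, integer(1)) == 12))
})

test_that("a window extending past the recording end is marked unavailable", {
  n <- 1000
  surf <- matrix(rnorm(n * 2, sd = 0.01), n, 2,
                 dimnames = list(NULL, c("I", "II")))
  bip <- matrix(0, n, 1, dimnames = list(NULL, "B1"))
  pos <- matrix(0, 1, 3, dimnames = list("B1", NULL))
  rec <- deep_recording(1000, surf, bip, pos)
  tr <- make_train(c(100, 700, 950))   # last stimulus 50 ms before the end
  seg <- extract_beat_segments(rec, tr)
  expect_false(is.null(seg$segments[[1]]))
  expect_true(is.null(seg$segments[[3]]))
})

test_that("identical paced QRS complexes correlate perfectly and are all captured", {
  sim <- clean_sim(c(0, 20))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  cap <- confirm_capture(extract_beat_segments(sim$recording, tr))
  expect_equal(cap$score, rep(1, 9), tolerance = 1e-12)
  expect_true(all(cap$captured))
  expect_true(train_usable(cap))
})

test_that("a beat whose QRS is missing scores far below threshold and is flagged", {
  sim <- simulate_recording(sim_config(n_channels = 2, noise_sd = 0.01,
                                       capture_failure_beats = 4L,
                                       rng_seed = 5))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  cap <- confirm_capture(extract_beat_segments(sim$recording, tr))
  expect_lt(cap$score[4], 0.5)
  expect_false(cap$captured[4])
  expect_true(all(cap$captured[-4]))
  expect_true(train_usable(cap))  # beat 4 is not among the decisive beats
})

test_that("an unattainable threshold marks every beat not captured", {
  sim <- clean_sim(c(0, 20))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  seg <- extract_beat_segments(sim$recording, tr)
  cap <- confirm_capture(seg, deep_config(capture.threshold = 1.01))
  expect_false(any(cap$captured))
})

test_that("correlation scores stay in [-1, 1] and survive positive rescaling unchanged", {
  sim <- simulate_recording(sim_config(n_channels = 2, noise_sd = 0.05,
                                       capture_failure_beats = 2L,
                                       rng_seed = 8))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  cap <- confirm_capture(extract_beat_segments(sim$recording, tr))
  expect_true(all(cap$score >= -1 & cap$score <= 1, na.rm = TRUE))

  scaled <- sim$recording
  scaled$surface <- scaled$surface * 3.7
  cap2 <- confirm_capture(extract_beat_segments(scaled, tr))
  expect_equal(cap2$score, cap$score, tolerance = 1e-9)
  expect_identical(cap2$captured, cap$captured)
})

test_that("raising the threshold never converts a beat to captured", {
  sim <- simulate_recording(sim_config(n_channels = 2, noise_sd = 0.1,
                                       rng_seed = 21))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  seg <- extract_beat_segments(sim$recording, tr)
  prev <- rep(TRUE, 9)
  for (thr in c(0.5, 0.8, 0.9, 0.99)) {
    cap <- confirm_capture(seg, deep_config(capture.threshold = thr))
    expect_true(all(!cap$captured | prev))  # captured now => captured before
    prev <- cap$captured
  }
})

test_that("fewer than two usable S1 segments is a typed capture-indeterminate outcome", {
  n <- 900
  surf <- matrix(rnorm(n, sd = 0.01), n, 1, dimnames = list(NULL, "I"))
  bip <- matrix(0, n, 1, dimnames = list(NULL, "B1"))
  pos <- matrix(0, 1, 3, dimnames = list("B1", NULL))
  rec <- deep_recording(1000, surf, bip, pos)
  tr <- make_train(c(700, 800, 850))  # all windows run past the end
  cap <- confirm_capture(extract_beat_segments(rec, tr))
  expect_true(is_outcome(cap, "capture_indeterminate"))
})
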