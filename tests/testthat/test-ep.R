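ep_of <- function(latency, morphology = sin(seq(0, 2 * pi, length.out = 21)),
                  channel = "B1") {
  deepmapr:::new_ep(channel, 0, latency, 0.5, morphology)
}

test_that("clean S1 evoked potentials are found at the planted latency", {
  sim <- clean_sim(c(0, 20, 40))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  period <- 1000 / sim$recording$sampling_rate
  eps <- detect_s1_eps(sim$recording, tr, "B1")
  expect_length(eps, 3)
  for (e in eps) expect_lte(abs(e$latency - 40), period)
  # a channel that decrements only on S2 has identical S1 latencies
  eps3 <- detect_s1_eps(sim$recording, tr, "B3")
  lats <- vapply(eps3, `[[`, numeric(1), "latency")
  expect_equal(lats, rep(lats[1], 3))
})

test_that("returned latencies are positive and inside the search window", {
  sim <- clean_sim(c(0, 15, 55))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  for (ch in colnames(sim$recording$bipolar)) {
    eps <- detect_s1_eps(sim$recording, tr, ch)
    for (e in eps) {
      expect_gt(e$latency, 0)
      expect_lte(e$latency, 0.9 * tr$s1_interval)
    }
  }
})

test_that("a flat-line channel yields a typed insufficient-S1 outcome", {
  sim <- clean_sim(c(0, 20))
  sim$recording$bipolar[, "B1"] <- 0
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  out <- detect_s1_eps(sim$recording, tr, "B1")
  expect_true(is_outcome(out, "insufficient_s1"))
})

test_that("stability statistics match hand-computed values", {
  # zero variance, identical shapes
  s <- assess_stability(list(ep_of(40), ep_of(40), ep_of(40)))
  expect_equal(s$latency_sd, 0)
  expect_equal(s$mean_pairwise_morphology_correlation, 1)
  expect_true(s$stable)
  # population sd of {40, 46, 52} is sqrt(24) = 4.898979...
  s2 <- assess_stability(list(ep_of(40), ep_of(46), ep_of(52)))
  expect_equal(s2$latency_sd, sqrt(24), tolerance = 1e-12)
  expect_equal(s2$latency_sd, 4.898979, tolerance = 1e-6)
  expect_true(s2$stable)    # 4.90 ms is just inside the 5-ms default
  # ... but fails a tighter timing criterion
  s3 <- assess_stability(list(ep_of(40), ep_of(46), ep_of(52)),
                         deep_config(ep.stability_sd_ms = 4))
  expect_false(s3$stable)
})

test_that("a white-noise morphology breaks stability via the correlation criterion", {
  set.seed(123)
  noise <- rnorm(21)
  s <- assess_stability(list(ep_of(40), ep_of(40),
                             ep_of(40, morphology = noise)))
  expect_equal(s$latency_sd, 0)
  expect_lt(s$mean_pairwise_morphology_correlation, 0.85)
  expect_false(s$stable)
})

test_that("stability assessment is permutation-invariant", {
  set.seed(5)
  eps <- list(ep_of(40), ep_of(43, morphology = sin(seq(0, 6, length.out = 21))),
              ep_of(47, morphology = cos(seq(0, 6, length.out = 21))))
  ref <- assess_stability(eps)
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    s <- assess_stability(eps[p])
    expect_equal(s$latency_sd, ref$latency_sd)
    expect_equal(s$mean_pairwise_morphology_correlation,
                 ref$mean_pairwise_morphology_correlation)
    expect_identical(s$stable, ref$stable)
  }
  expect_true(is_outcome(assess_stability(eps[1:2]), "insufficient_s1"))
})

test_that("the extra-stimulus response is found at base latency plus the planted decrement", {
  sim <- clean_sim(c(35, 0))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  period <- 1000 / sim$recording$sampling_rate

  eps1 <- detect_s1_eps(sim$recording, tr, "B1")
  s2e <- detect_s2_ep(sim$recording, tr, "B1", eps1[[3]])
  expect_s3_class(s2e, "evoked_potential")
  expect_lte(abs(s2e$latency - (40 + 35)), period)
  expect_gte(attr(s2e, "match_score"), 0.7)

  # no decrement: S2 latency equals the S1 latency
  eps2 <- detect_s1_eps(sim$recording, tr, "B2")
  s2e2 <- detect_s2_ep(sim$recording, tr, "B2", eps2[[3]])
  expect_lte(abs(s2e2$latency - eps2[[3]]$latency), period)
})

test_that("a blocked extra-stimulus response is reported absent, not zero", {
  sim <- simulate_recording(sim_config(n_channels = 2, noise_sd = 0,
                                       s2_block = c(TRUE, FALSE)))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  eps <- detect_s1_eps(sim$recording, tr, "B1")
  expect_null(detect_s2_ep(sim$recording, tr, "B1", eps[[3]]))
})

test_that("a train without an extra-stimulus gives a typed no-S2 outcome", {
  sim <- simulate_recording(sim_config(n_channels = 1, noise_sd = 0,
                                       include_s2 = FALSE))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  eps <- detect_s1_eps(sim$recording, tr, "B1")
  out <- detect_s2_ep(sim$recording, tr, "B1", eps[[3]])
  expect_true(is_outcome(out, "no_s2"))
})

test_that("template matching recovers every planted shift from 0 to 100 ms", {
  shifts <- seq(0, 100, by = 5)
  sim <- simulate_recording(sim_config(n_channels = length(shifts),
                                       planted_decrement = shifts,
                                       noise_sd = 0))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  period <- 1000 / sim$recording$sampling_rate
  for (j in seq_along(shifts)) {
    ch <- colnames(sim$recording$bipolar)[j]
    eps <- detect_s1_eps(sim$recording, tr, ch)
    s2e <- detect_s2_ep(sim$recording, tr, ch, eps[[3]])
    expect_lte(abs((s2e$latency - eps[[3]]$latency) - shifts[j]), period)
  }
})
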