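test_that("generators are pure functions of scenario and seed", {
  sc <- behaviorScenario()
  g1 <- generateLandmarks(sc, seed = 13)
  g2 <- generateLandmarks(sc, seed = 13)
  expect_identical(g1$session@coords, g2$session@coords)
  expect_identical(g1$events, g2$events)
  expect_false(identical(g1$session@coords,
                         generateLandmarks(sc, seed = 14)$session@coords))
  cs <- calciumScenario(noise_sd = 0.02, shift_schedule = "random")
  m1 <- generateMovie(cs, seed = 5)
  m2 <- generateMovie(cs, seed = 5)
  expect_identical(movieData(m1$movie), movieData(m2$movie))
  expect_identical(m1$shifts, m2$shifts)
  es <- ephysScenario()
  t1 <- generateTrace(es, seed = 5)
  t2 <- generateTrace(es, seed = 5)
  expect_identical(t1$trace@samples, t2$trace@samples)
  expect_identical(t1$spike_times, t2$spike_times)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generateLandmarks(behaviorScenario(), seed = 1))
  expect_identical(runif(1), before)
})

test_that("noiseless planted events are recovered exactly by detection", {
  sc <- behaviorScenario(noise_px = 0, dropout_rate = 0, partial_prob = 0)
  g <- generateLandmarks(sc, seed = 31)
  a <- computeAngles(g$session, likelihood_min = 0)
  ev <- detectPER(a, merge_gap = 0, min_duration = 0)
  gt <- g$events[order(g$events$onset), ]
  expect_equal(ev$onset, gt$onset)
  expect_equal(ev$offset, gt$offset)
  expect_equal(ev$peak_haustellum, gt$peak_haustellum, tolerance = 1e-9)
})

test_that("planted response probability is recovered within binomial error", {
  # 60 trials of a single stimulus at p = 0.8
  sc <- behaviorScenario(stimuli = "EBR", blocks = 60,
                         response_prob = c(EBR = 0.8),
                         noise_px = 0, dropout_rate = 0, partial_prob = 0)
  g <- generateLandmarks(sc, seed = 32)
  a <- computeAngles(g$session, likelihood_min = 0)
  sm <- sessionMetrics(detectPER(a), trials(g$session))
  phat <- mean(sm$responded)
  expect_lt(abs(phat - 0.8), 1.96 * sqrt(0.8 * 0.2 / 60))
})

test_that("impossible angle targets are rejected", {
  expect_error(landmarksFromAngles(0, 120, 150), "impossible geometry")
  expect_error(behaviorScenario(response_prob = 1.4), "response_prob")
  expect_error(calciumScenario(blob_center = c(100, 100)), "blob center")
})

test_that("zero-amplitude and zero-rate scenarios yield null responses", {
  g <- generateMovie(calciumScenario(stimuli = "air", amplitude = 0,
                                     trials_per_stimulus = 1,
                                     noise_sd = 0.002), seed = 6)
  res <- calciumResponses(g$movie, g$roi, stimulus = g$trials$stimulus,
                          register = FALSE)
  # noise floor: peak within 3 SD of the ROI-mean noise
  n_pix <- length(g$roi$rows) * length(g$roi$cols) * length(g$roi$planes)
  sigma_peak <- 0.002 / sqrt(n_pix * 5) / mean(movieData(g$movie)[1, , g$roi$rows, g$roi$cols])
  expect_lt(abs(res$per_trial$peak), 3 * max(sigma_peak, 0.01))
  ge <- generateTrace(ephysScenario(rate = 0, noise_sd = 0.05), seed = 7)
  expect_length(ge$spike_times, 0)
  # only the contact-artifact edge (first 100 ms, outside the counting
  # window by design) may trigger; no detections beyond it
  det <- spikeTimes(detectSpikes(bandpassFilter(ge$trace)))
  expect_length(det[det >= 0.1], 0)
  expect_equal(countWindow(detectSpikes(bandpassFilter(ge$trace)))$count, 0L)
})

test_that("ground-truth spike counts follow the planted Poisson rate", {
  counts <- vapply(1:200, function(s) {
    g <- generateTrace(ephysScenario(rate = 40, noise_sd = 0,
                                     artifact_amp = 0), seed = s)
    sum(g$spike_times >= 0.2 & g$spike_times < 0.7)
  }, numeric(1))
  # dead-time-corrected Poisson mean: lambda/(1 + lambda*tau) * 0.5 s
  expected <- 40 / (1 + 40 * 0.003) * 0.5
  expect_lt(abs(mean(counts) - expected), 0.75)
  # and without a refractory period the raw Poisson mean of 20 applies
  counts0 <- vapply(1:200, function(s) {
    g <- generateTrace(ephysScenario(rate = 40, noise_sd = 0,
                                     refractory_s = 0, artifact_amp = 0),
                       seed = 1000 + s)
    sum(g$spike_times >= 0.2 & g$spike_times < 0.7)
  }, numeric(1))
  expect_lt(abs(mean(counts0) - 20), 0.95)  # ~3 SE of the Monte-Carlo mean
})

test_that("noiseless model dataset gives exact weights and R^2 = 1", {
  d <- generateModelDataset(weights = c(5e-4, -2.3e-5), intercept = 0.2,
                            noise_sd = 0, seed = 8)
  fit <- fitPerModel(d$gr5a, d$gr66a, d$per_magnitude)
  expect_equal(fit$weight_gr5a, 5e-4, tolerance = 1e-9)
  expect_equal(fit$weight_gr66a, -2.3e-5, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(d$per_magnitude, d$per_expected)
})

test_that("factorial generator plants detectable main effects", {
  d0 <- generateFactorialDataset(seed = 10)
  expect_equal(nrow(d0), 3 * 9 * 5)
  expect_equal(nlevels(d0$A), 3)
  d1 <- generateFactorialDataset(effect_a = 1.5, n_per_cell = 20, seed = 11)
  r <- scheirerRayHare(d1$value, d1$A, d1$B)
  expect_lt(r$table$p_value[1], 0.05)
})
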