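oneTrial <- function(t0 = 10) {
  data.frame(trial_index = 1L, stimulus_id = "EBR", valve_open_time = t0,
             stimulus_duration = 2, block = 1L, stringsAsFactors = FALSE)
}

test_that("trial metrics measure window overlap and latency", {
  tr <- oneTrial(10)
  # no events
  m <- trialMetrics(handEvents(numeric(0), numeric(0)), tr)
  expect_equal(m$integrated_duration, 0)
  expect_false(m$responded)
  expect_true(is.na(m$latency))
  # PER spanning the whole trial: capped at the 4 s window
  m <- trialMetrics(handEvents(8, 12), tr)
  expect_equal(m$integrated_duration, 4)
  expect_equal(m$per_second_duration, rep(1, 4))
  # event 2.0-3.5 s after onset: 1.5 s overlap, latency 2.0 s
  m <- trialMetrics(handEvents(12, 1.5), tr)
  expect_equal(m$integrated_duration, 1.5)
  expect_equal(m$per_second_duration, c(0, 1, 0.5, 0))
  expect_true(m$responded)
  expect_equal(m$latency, 2)
  # onset after the response window: not a response, still no overlap credit
  m <- trialMetrics(handEvents(16, 1), tr)
  expect_false(m$responded)
  expect_equal(m$integrated_duration, 0)
})

test_that("integrated duration is additive and order-invariant", {
  tr <- oneTrial(10)
  e1 <- handEvents(c(11.2, 13.0), c(0.5, 0.8))
  e2 <- e1[2:1, ]
  m1 <- trialMetrics(e1, tr)
  m2 <- trialMetrics(e2, tr)
  expect_equal(m1$integrated_duration, 0.5 + 0.8)
  expect_equal(m2$integrated_duration, m1$integrated_duration)
  expect_lte(m1$integrated_duration, 4)
})

test_that("scoring window outside the recording is an error", {
  expect_error(trialMetrics(handEvents(11, 1), oneTrial(10), n_frames = 100),
               "outside recording")
})

test_that("fly metrics aggregate per stimulus and flag exclusion", {
  stim <- rep(c("EBR", "water"), each = 3)
  tt <- trialTable(stim)
  # respond to all EBR trials, never to water
  ev <- handEvents(tt$valve_open_time[1:3] + 1.5, rep(1, 3))
  sm <- sessionMetrics(ev, tt)
  fm <- flyMetrics(sm, ev, tt)
  ps <- fm$per_stimulus
  expect_equal(ps$per_probability[ps$stimulus_id == "EBR"], 100)
  expect_equal(ps$per_probability[ps$stimulus_id == "water"], 0)
  expect_equal(ps$mean_integrated_duration[ps$stimulus_id == "EBR"], 1)
  expect_equal(ps$mean_latency[ps$stimulus_id == "EBR"], 1.5)
  expect_equal(fm$spontaneous_trial_count, 0L)
  expect_false(fm$excluded)
})

test_that("the exclusion boundary sits at more than 9 spontaneous trials", {
  tt <- trialTable(rep(paste0("s", 1:9), 3))  # 27 trials
  spontAt <- function(k) {
    # a late (outside the 5 s response window) PER in the first k trials
    handEvents(tt$valve_open_time[seq_len(k)] + 10, rep(1, k))
  }
  for (k in c(9L, 10L)) {
    ev <- spontAt(k)
    fm <- flyMetrics(sessionMetrics(ev, tt), ev, tt)
    expect_equal(fm$spontaneous_trial_count, k)
    expect_identical(fm$excluded, k > 9L)
  }
})

test_that("missing trials warn and are computed on what is present", {
  tt <- trialTable(c("EBR", "EBR", "water"))
  ev <- handEvents(tt$valve_open_time[1] + 1, 1)
  sm <- sessionMetrics(ev, tt)
  warns <- capture_warnings(fm <- flyMetrics(sm, ev, tt))
  expect_length(warns, 2)  # both stimuli are short of three trials
  expect_match(warns, "only", all = TRUE)
  ps <- fm$per_stimulus
  expect_equal(ps$n_trials, c(2L, 1L))
  expect_equal(ps$per_probability[1], 50)
})

test_that("planted response probabilities are recovered from a session", {
  sc <- behaviorScenario(noise_px = 0, dropout_rate = 0, partial_prob = 0)
  g <- generateLandmarks(sc, seed = 21)
  a <- computeAngles(g$session, likelihood_min = 0)
  ev <- detectPER(a)
  sm <- sessionMetrics(ev, trials(g$session))
  # every trial with a planted PER (latency in the response window) responds
  planted <- table(factor(g$events$stimulus_id[g$events$kind == "PER"],
                          levels = sort(unique(sm$stimulus_id))))
  measured <- tapply(sm$responded, sm$stimulus_id, sum)
  expect_equal(as.integer(measured[names(planted)]), as.integer(planted))
})
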