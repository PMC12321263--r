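mkAngles <- function(H, R = NULL) {
  n <- length(H)
  if (is.null(R)) R <- rep(35, n)
  AngleSeries(rostrum = R, haustellum = H, labellum = rep(160, n), fps = 20)
}

test_that("PER detection tiles the super-threshold frame set", {
  expect_equal(nrow(detectPER(mkAngles(rep(90, 100)))), 0)
  ev <- detectPER(mkAngles(rep(120, 200)), merge_gap = 0, min_duration = 0)
  expect_equal(ev$onset, 1L)
  expect_equal(ev$offset, 201L)
  # pulse on 1-based frames 41..60 -> half-open [41, 61)
  H <- rep(60, 100); H[41:60] <- 120
  ev <- detectPER(mkAngles(H), merge_gap = 0, min_duration = 0)
  expect_equal(ev$onset, 41L)
  expect_equal(ev$offset, 61L)
  expect_equal(ev$kind, "PER")
  expect_equal(ev$peak_haustellum, 120)
  # property: with filters off, the union of events equals {H > 100}
  set.seed(1)
  for (rep_i in 1:20) {
    H <- 60 + 80 * (runif(300) > 0.7)
    ev <- detectPER(mkAngles(H), merge_gap = 0, min_duration = 0)
    covered <- logical(300)
    for (k in seq_len(nrow(ev))) covered[ev$onset[k]:(ev$offset[k] - 1)] <- TRUE
    expect_identical(covered, H > 100)
    if (nrow(ev) > 1) expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$offset > ev$onset))
  }
})

test_that("merge gap and minimum duration filters behave as configured", {
  H <- rep(60, 60)
  H[11:20] <- 120; H[23:30] <- 120  # 2-frame gap
  ev <- detectPER(mkAngles(H), merge_gap = 2, min_duration = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset, ev$offset), c(11L, 31L))
  ev2 <- detectPER(mkAngles(H), merge_gap = 1, min_duration = 2)
  expect_equal(nrow(ev2), 2)
  H2 <- rep(60, 40); H2[15] <- 130  # single-frame blip
  expect_equal(nrow(detectPER(mkAngles(H2))), 0)
  expect_equal(nrow(detectPER(mkAngles(H2), min_duration = 1)), 1)
})

test_that("hysteresis detector grows seeds to the low-threshold region", {
  expect_equal(nrow(detectExtensions(rep(12, 100))), 0)  # never above high
  # triangular bump: crosses 5 deg just after 1-based frame 10 and falls
  # back to 5 at frame 91 -> event [11, 91)
  s <- approx(c(1, 10, 51, 91, 100), c(0, 5, 20, 5, 0), xout = 1:100)$y
  ev <- detectExtensions(s, low = 5, high = 15)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset, ev$offset), c(11L, 91L))
  # two super-high bumps joined by a valley above low -> one merged event
  s2 <- rep(0, 80)
  s2[11:25] <- 18; s2[26:30] <- 8; s2[31:45] <- 18
  ev2 <- detectExtensions(s2, low = 5, high = 15)
  expect_equal(nrow(ev2), 1)
  expect_equal(c(ev2$onset, ev2$offset), c(11L, 46L))
  # a bump between low and high is not an event
  s3 <- rep(0, 50); s3[10:20] <- 10
  expect_equal(nrow(detectExtensions(s3)), 0)
})

test_that("hysteresis events contain a super-high frame and end below low", {
  set.seed(3)
  for (rep_i in 1:20) {
    s <- pmax(0, 20 * sin(seq(0, 6 * pi, length.out = 240)) + rnorm(240, 0, 4))
    ev <- detectExtensions(s, low = 5, high = 15)
    for (k in seq_len(nrow(ev))) {
      seg <- s[ev$onset[k]:(ev$offset[k] - 1)]
      expect_gt(max(seg), 15)
      expect_true(all(seg > 5))
      if (ev$onset[k] > 1) expect_lte(s[ev$onset[k] - 1], 5)
      if (ev$offset[k] <= length(s)) expect_lte(s[ev$offset[k]], 5)
    }
  }
})

test_that("hysteresis events are labelled PER or partial by the haustellum", {
  s <- rep(0, 60); s[11:20] <- 20; s[41:50] <- 20
  H <- rep(60, 60); H[11:20] <- 130; H[41:50] <- 90
  ev <- detectExtensions(s, haustellum = H)
  expect_equal(ev$kind, c("PER", "partial"))
  expect_equal(ev$peak_haustellum, c(130, 90))
  expect_true(all(ev$source == "rostrum_hysteresis"))
})

test_that("event trajectories carry the per-frame rostrum/haustellum pair", {
  g <- generateLandmarks(behaviorScenario(noise_px = 0, dropout_rate = 0),
                         seed = 4)
  a <- computeAngles(g$session, likelihood_min = 0)
  ev <- detectPER(a)
  tr <- eventTrajectories(ev, a)
  expect_length(tr, nrow(ev))
  expect_equal(nrow(tr[[1]]), ev$offset[1] - ev$onset[1])
  expect_equal(attr(tr[[1]], "fps"), 20)
  expect_equal(tr[[1]][, "haustellum"],
               a@haustellum[ev$onset[1]:(ev$offset[1] - 1)])
})
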