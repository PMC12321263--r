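test_that("shiftVolume translates content and fills vacated voxels", {
  v <- array(seq_len(2 * 4 * 4), c(2, 4, 4))
  s <- shiftVolume(v, c(0, 1, 0), fill = 0)
  expect_equal(s[1, 2:4, ], v[1, 1:3, ])
  expect_true(all(s[, 1, ] == 0))
  expect_equal(shiftVolume(v, c(0, 0, 0)), v)
})

test_that("registration returns zero shift for an unshifted movie", {
  g <- generateMovie(calciumScenario(stimuli = "a", trials_per_stimulus = 1,
                                     frames_per_trial = 6), seed = 1)
  reg <- registerStack(g$movie, search = c(3, 3, 1))
  expect_true(all(reg$shifts$dx == 0 & reg$shifts$dy == 0 &
                    reg$shifts$dz == 0))
  expect_true(all(reg$shifts$correlation > 0.999))
})

test_that("injected integer shifts are recovered exactly without noise", {
  shifts <- cbind(dx = c(3, -2, 0, 4, -4, 1),
                  dy = c(-2, 1, 3, 0, -3, 2),
                  dz = c(0, 1, -1, 0, 1, -1))
  g0 <- generateMovie(calciumScenario(stimuli = "a", trials_per_stimulus = 1,
                                      frames_per_trial = 6), seed = 2)
  ref <- array(movieData(g0$movie)[1, , , ],
               dim(movieData(g0$movie))[2:4])
  g <- generateMovie(calciumScenario(stimuli = "a", trials_per_stimulus = 1,
                                     frames_per_trial = 6,
                                     shift_schedule = shifts), seed = 2)
  reg <- registerStack(g$movie, reference = ref, search = c(4, 4, 1))
  expect_equal(reg$shifts$dx, -shifts[, "dx"])
  expect_equal(reg$shifts$dy, -shifts[, "dy"])
  expect_equal(reg$shifts$dz, -shifts[, "dz"])
})

test_that("ROI traces average the rectangle across its plane span", {
  dat <- array(7, c(3, 2, 8, 8))
  m <- MovieStack(dat)
  roi <- list(rows = 2:5, cols = 3:6, planes = 1:2)
  expect_equal(roiTrace(m, roi), rep(7, 3))
  # half-bright / half-dark ROI averages the two values
  dat[, , , 1:4] <- 2; dat[, , , 5:8] <- 10
  m2 <- MovieStack(dat)
  expect_equal(roiTrace(m2, list(rows = 1:8, cols = 1:8, planes = 1:2)),
               rep(6, 3))
  expect_error(roiTrace(m, list(rows = 7:9, cols = 1:2, planes = 1)),
               "bounds")
  expect_error(makeRoi(m, 4, 4, 80, 60, units = "um"), "pixel_size")
})

test_that("dF/F uses the five pre-onset frames and is gain invariant", {
  tr <- rep(100, 25)
  expect_equal(as.numeric(dff(tr)), rep(0, 25))
  tr[12:16] <- 200
  d <- dff(tr)
  expect_equal(as.numeric(d[12:16]), rep(1, 5))
  expect_equal(attr(d, "f0"), 100)
  expect_equal(attr(d, "baseline_frames"), 6:10)
  # gain invariance: scaling the raw trace leaves dF/F unchanged
  expect_equal(as.numeric(dff(3.7 * tr)), as.numeric(d))
  expect_error(dff(rep(0, 25)), "baseline")
  expect_error(dff(tr, stimulus_onset_frame = 3), "before the start")
})

test_that("peak response averages the quantification frames and trials", {
  z <- rep(0, 20)
  expect_equal(peakResponse(z)$per_trial$peak, 0)
  tr <- rep(0, 20); tr[12:16] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(peakResponse(tr)$per_trial$peak, 0.3)
  # three trials of one stimulus average arithmetically
  mk <- function(p) { x <- rep(0, 20); x[12:16] <- p; x }
  res <- peakResponse(list(mk(0.2), mk(0.3), mk(0.4)),
                      stimulus = rep("EBR", 3))
  expect_equal(res$per_stimulus$peak, 0.3)
  expect_equal(res$per_stimulus$n_trials, 3L)
  # linearity in dF/F
  res2 <- peakResponse(list(mk(0.4), mk(0.6), mk(0.8)),
                       stimulus = rep("EBR", 3))
  expect_equal(res2$per_stimulus$peak, 2 * res$per_stimulus$peak)
  expect_error(peakResponse(rep(0, 10)), "shorter")
})

test_that("noiseless pipeline peak equals the closed-form kernel mean", {
  sc <- calciumScenario(stimuli = "EBR", trials_per_stimulus = 3,
                        amplitude = 0.5, noise_sd = 0)
  g <- generateMovie(sc, seed = 4)
  res <- calciumResponses(g$movie, g$roi, stimulus = g$trials$stimulus,
                          register = FALSE)
  expected <- 0.5 * mean(calciumKernel((12:16 - 11) * 0.5))
  expect_equal(res$per_stimulus$peak, expected, tolerance = 1e-9)
})
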