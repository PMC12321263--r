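## Small helper: a single-frame session from six explicit points.
sessionFromPoints <- function(pts, likelihood = 1) {
  arr <- array(NA_real_, c(1, 6, 3),
               dimnames = list(NULL, landmarkNames(),
                               c("x", "y", "likelihood")))
  for (l in landmarkNames()) arr[1, l, ] <- c(pts[[l]], likelihood)
  LandmarkSession(coords = arr, fps = 20)
}

test_that("haustellum angle matches hand geometry", {
  base <- list(antenna_proximal = c(0, 0), antenna_distal = c(10, 0),
               rostrum_apex = c(0, 10))
  # collinear: apex (0,10) -- joint (0,20) -- next joint (0,30): H = 180
  p <- c(base, list(rostrum_haustellum_joint = c(0, 20),
                    haustellum_labellum_joint = c(0, 30),
                    labellum_distal = c(10, 30)))
  a <- computeAngles(sessionFromPoints(p), likelihood_min = 0)
  expect_equal(a@haustellum, 180)
  # perpendicular: (joint->apex) = (0,-10), (joint->next) = (10,0): H = 90
  p$haustellum_labellum_joint <- c(10, 20)
  a <- computeAngles(sessionFromPoints(p), likelihood_min = 0)
  expect_equal(a@haustellum, 90)
  expect_equal(a@labellum, 90)  # (-10,0) vs (0,10) at the labellum joint
})

test_that("generated landmarks invert to the programmed angles", {
  arr <- landmarksFromAngles(40, 120, 150)
  s <- LandmarkSession(coords = arr, fps = 20)
  a <- computeAngles(s, likelihood_min = 0)
  expect_equal(a@rostrum, 40, tolerance = 1e-6)
  expect_equal(a@haustellum, 120, tolerance = 1e-6)
  expect_equal(a@labellum, 150, tolerance = 1e-6)
})

test_that("angle recovery holds across the whole (1,179)^3 range", {
  set.seed(42)
  n <- 200
  R <- runif(n, 1, 179); H <- runif(n, 1, 179); L <- runif(n, 1, 179)
  a <- computeAngles(LandmarkSession(coords = landmarksFromAngles(R, H, L)),
                     likelihood_min = 0)
  expect_lt(max(abs(a@rostrum - R)), 1e-6)
  expect_lt(max(abs(a@haustellum - H)), 1e-6)
  expect_lt(max(abs(a@labellum - L)), 1e-6)
})

test_that("low-likelihood frames are interpolated before angle computation", {
  R <- rep(40, 11); H <- rep(120, 11); L <- rep(150, 11)
  arr <- landmarksFromAngles(R, H, L)
  # corrupt frame 6 badly and mark it unreliable
  arr[6, "rostrum_haustellum_joint", 1:2] <- c(0, 0)
  arr[6, "rostrum_haustellum_joint", 3] <- 0.1
  s <- LandmarkSession(coords = arr, fps = 20)
  a <- computeAngles(s, likelihood_min = 0.9)
  expect_equal(a@haustellum[6], 120, tolerance = 1e-6)
  # with filtering off the corrupted frame leaks through
  a0 <- computeAngles(s, likelihood_min = 0)
  expect_gt(abs(a0@haustellum[6] - 120), 1)
})

test_that("degenerate zero-length segments raise an error naming the frame", {
  arr <- landmarksFromAngles(rep(40, 3), rep(120, 3), rep(150, 3))
  arr[2, "haustellum_labellum_joint", 1:2] <-
    arr[2, "rostrum_haustellum_joint", 1:2]
  s <- LandmarkSession(coords = arr, fps = 20)
  expect_error(computeAngles(s, likelihood_min = 0), "frame 2")
})

test_that("rolling baseline reproduces the sort-based percentile", {
  # constant signal: baseline is the constant
  expect_equal(rollingBaseline(rep(30, 200), fps = 20), rep(30, 200))
  # short pulse occupies < 25% of any window: baseline stays at zero
  x <- rep(0, 400)
  x[200:209] <- 20  # 0.5 s pulse at 20 Hz
  expect_equal(rollingBaseline(x, fps = 20), rep(0, 400))
  # random trace equals the brute-force percentile at every index
  set.seed(7)
  x <- rnorm(600, 50, 10)
  b <- rollingBaseline(x, fps = 20, window_s = 5, percentile = 25)
  for (i in c(1, 2, 50, 300, 599, 600)) {
    lo <- max(1, i - 50); hi <- min(600, i + 50)
    expect_equal(b[i], sortPercentile(x[lo:hi], 0.25))
  }
  expect_error(rollingBaseline(numeric(0)), "empty")
})

test_that("rolling baseline is monotone in the signal", {
  set.seed(8)
  x <- rnorm(300)
  y <- x + abs(rnorm(300))  # pointwise larger
  expect_true(all(rollingBaseline(y, fps = 20) >=
                    rollingBaseline(x, fps = 20) - 1e-12))
})
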