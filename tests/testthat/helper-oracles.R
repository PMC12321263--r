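# Independent oracles used to check the implementation paths.

# Sort-based percentile with linear interpolation between order statistics
# (the classical definition; written without quantile()).
sortPercentile <- function(x, p = 0.25) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

dtwLocalCost <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  lc <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d <- a - matrix(b[j, ], n, ncol(a), byrow = TRUE)
    lc[, j] <- sqrt(rowSums(d * d))
  }
  lc
}

# Exhaustive recursive enumeration of all monotone banded warping paths
# (no memoisation; feasible only for short sequences).
dtwOracleRecursive <- function(a, b, w) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b); mx <- max(n, m)
  lc <- dtwLocalCost(a, b)
  rec <- function(i, j) {
    if (abs(i * m - j * n) > w * mx) return(Inf)
    if (i == 1 && j == 1) return(lc[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    best + lc[i, j]
  }
  rec(n, m)
}

# Shortest path through the banded alignment DAG via igraph (independent
# algorithm and code path from the package's dynamic program).
dtwOracleGraph <- function(a, b, w) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b); mx <- max(n, m)
  lc <- dtwLocalCost(a, b)
  id <- function(i, j) (i - 1) * m + j
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (abs(i * m - j * n) > w * mx) next
      for (st in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
        i2 <- i + st[1]; j2 <- j + st[2]
        if (i2 <= n && j2 <= m && abs(i2 * m - j2 * n) <= w * mx) {
          from <- c(from, id(i, j)); to <- c(to, id(i2, j2))
          wt <- c(wt, lc[i2, j2])
        }
      }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n * m, directed = TRUE)
  d <- igraph::distances(g, v = id(1, 1), to = id(n, m), mode = "out",
                         weights = wt)
  as.numeric(d) + lc[1, 1]
}

# Rand index between two flat partitions.
randIndex <- function(a, b) {
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  ut <- upper.tri(sa)
  mean(sa[ut] == sb[ut])
}

# Random angle trajectory pair for DTW property tests.
randomTrajectory <- function(n, d = 2) {
  matrix(runif(n * d, 0, 50), n, d)
}

# Two well-separated groups of angle trajectories (between-group offset
# `sep` versus within-group jitter of SD 0.4) for clustering tests.
plantedTrajectories <- function(n_per = 8, sep = 60, seed = 5) {
  withr::with_seed(seed, {
    mk <- function(base) {
      n <- sample(15:22, 1)
      t <- seq(0, 1, length.out = n)
      cbind(base[1] + 5 * sin(pi * t) + rnorm(n, 0, 0.4),
            base[2] + 20 * sin(pi * t) + rnorm(n, 0, 0.4))
    }
    c(lapply(seq_len(n_per), function(i) mk(c(40, 100))),
      lapply(seq_len(n_per), function(i) mk(c(40 + sep, 100 + sep))))
  })
}

# Session fixture: trials laid out regularly, PER events placed by hand at
# given onset times (seconds); returns the pieces trialMetrics needs.
handEvents <- function(onsets_s, durations_s, fps = 20) {
  if (!length(onsets_s))
    return(data.frame(onset = integer(), offset = integer(),
                      kind = character(), peak_haustellum = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  data.frame(onset = round(onsets_s * fps) + 1L,
             offset = round((onsets_s + durations_s) * fps) + 1L,
             kind = "PER", peak_haustellum = 130,
             source = "haustellum_threshold", stringsAsFactors = FALSE)
}
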