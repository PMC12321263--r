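## Band-constrained dynamic time warping between angle trajectories.

## Band membership for cell (i, j) of an n x m alignment grid:
## slope-adjusted Sakoe-Chiba band of half-width w frames, in the
## symmetric form |i*m - j*n| <= w * max(n, m), which reduces to
## |i - j| <= w for equal lengths and is invariant to swapping the
## arguments (so the distance is symmetric by construction).
inBand <- function(i, j, n, m, w) abs(i * m - j * n) <= w * max(n, m)

#' Dynamic time warping distance between two trajectories
#'
#' Minimal cumulative cost over monotone warping paths with unit steps
#' (match / insert / delete), where the local cost is the Euclidean
#' distance between the per-frame vectors (rows). Paths are constrained to
#' a slope-adjusted Sakoe–Chiba band whose half-width is `window_s` seconds
#' (default 0.25 s, i.e. 5 frames at 20 Hz). The raw cumulative cost is
#' returned; set `normalize = TRUE` to divide by the optimal path length.
#'
#' @param a,b numeric matrices (frames x dims) or vectors; an `fps`
#'   attribute on `a` is used when `fps` is missing.
#' @param window_s warping-window half-width in seconds.
#' @param fps frames per second of both trajectories.
#' @param window_frames band half-width in frames; overrides `window_s`.
#' @param normalize divide the cost by the optimal path length.
#' @return the DTW distance (numeric scalar).
#' @export
dtwDistance <- function(a, b, window_s = 0.25, fps = NULL,
                        window_frames = NULL, normalize = FALSE) {
  a <- asTrajectoryMatrix(a)
  b <- asTrajectoryMatrix(b)
  if (ncol(a) != ncol(b)) stop("trajectories differ in dimensionality")
  if (is.null(window_frames)) {
    if (is.null(fps)) fps <- attr(a, "fps")
    if (is.null(fps)) stop("supply fps (or window_frames) to size the band")
    window_frames <- round(window_s * fps)
  }
  w <- max(1L, as.integer(window_frames))
  n <- nrow(a); m <- nrow(b)
  if (n < 1L || m < 1L) stop("trajectories must be non-empty")
  ## local cost matrix
  lc <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d <- a - matrix(b[j, ], n, ncol(a), byrow = TRUE)
    lc[, j] <- sqrt(rowSums(d * d))
  }
  D <- matrix(Inf, n, m)
  S <- matrix(NA_integer_, n, m)  # optimal path length in steps
  mx <- max(n, m)
  for (i in seq_len(n)) {
    jlo <- max(1L, ceiling((i * m - w * mx) / n))
    jhi <- min(m, floor((i * m + w * mx) / n))
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      if (i == 1L && j == 1L) { D[1, 1] <- lc[1, 1]; S[1, 1] <- 1L; next }
      best <- Inf; bs <- NA_integer_
      if (i > 1L && is.finite(D[i - 1L, j]) && D[i - 1L, j] < best) {
        best <- D[i - 1L, j]; bs <- S[i - 1L, j]
      }
      if (j > 1L && is.finite(D[i, j - 1L]) && D[i, j - 1L] < best) {
        best <- D[i, j - 1L]; bs <- S[i, j - 1L]
      }
      if (i > 1L && j > 1L && is.finite(D[i - 1L, j - 1L]) &&
          D[i - 1L, j - 1L] < best) {
        best <- D[i - 1L, j - 1L]; bs <- S[i - 1L, j - 1L]
      }
      if (is.finite(best)) { D[i, j] <- best + lc[i, j]; S[i, j] <- bs + 1L }
    }
  }
  if (!is.finite(D[n, m]))
    stop("warping band infeasible for lengths ", n, " and ", m,
         "; increase window_s")
  if (normalize) D[n, m] / S[n, m] else D[n, m]
}

asTrajectoryMatrix <- function(x) {
  f <- attr(x, "fps")
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  attr(x, "fps") <- f
  x
}

#' Pairwise DTW distance matrix
#'
#' Computes [dtwDistance()] once per unordered pair; the result is
#' symmetric by construction with a zero diagonal.
#'
#' @param trajectories list of trajectory matrices (e.g. from
#'   [eventTrajectories()]).
#' @inheritParams dtwDistance
#' @return an `n x n` symmetric distance matrix.
#' @export
pairwiseDistances <- function(trajectories, window_s = 0.25, fps = NULL,
                              window_frames = NULL, normalize = FALSE) {
  n <- length(trajectories)
  if (n < 2L) stop("need at least 2 trajectories")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- dtwDistance(trajectories[[i]], trajectories[[j]],
                       window_s = window_s, fps = fps,
                       window_frames = window_frames, normalize = normalize)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  if (!is.null(names(trajectories)))
    dimnames(D) <- list(names(trajectories), names(trajectories))
  D
}
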