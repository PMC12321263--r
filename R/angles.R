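## Proboscis angle computation and the rolling-percentile baseline.

## Unsigned angle (degrees, [0,180]) between row-wise 2-D vectors a and b.
## Frames with a zero-length vector raise a degenerate-geometry error.
vectorAngleDeg <- function(a, b, what = "segment") {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  bad <- which(na == 0 | nb == 0)
  if (length(bad))
    stop("degenerate geometry: zero-length ", what, " at frame ", bad[1L])
  cosv <- rowSums(a * b) / (na * nb)
  cosv <- pmin(1, pmax(-1, cosv))
  acos(cosv) * 180 / pi
}

## Linear interpolation of low-likelihood frames, one landmark at a time.
interpolateLowLikelihood <- function(coords, likelihood_min) {
  nf <- dim(coords)[1L]
  for (l in seq_len(dim(coords)[2L])) {
    bad <- coords[, l, 3L] < likelihood_min
    if (!any(bad)) next
    if (all(bad))
      stop("all frames below likelihood_min for landmark ",
           dimnames(coords)[[2L]][l])
    idx <- seq_len(nf)
    for (k in 1:2) {
      coords[bad, l, k] <- approx(idx[!bad], coords[!bad, l, k],
                                  xout = idx[bad], rule = 2)$y
    }
  }
  coords
}

#' Compute the three proboscis angles from tracked landmarks
#'
#' The rostrum angle (R) is the unsigned angle between the antenna line
#' (`antenna_proximal` to `antenna_distal`) and the rostrum segment
#' (`rostrum_apex` to `rostrum_haustellum_joint`). The haustellum angle (H)
#' is the interior angle at the rostrum–haustellum joint, between the
#' vectors joint-to-apex and joint-to-haustellum–labellum-joint; the
#' labellum angle (L) is the interior angle at the haustellum–labellum
#' joint, between joint-to-rostrum–haustellum-joint and
#' joint-to-labellum-tip. All angles are in degrees in \[0, 180\] and are
#' consistent with image-convention coordinates (y downward).
#'
#' Frames where any landmark's tracking likelihood falls below
#' `likelihood_min` are linearly interpolated (per landmark, per coordinate)
#' from the neighboring confident frames before the angles are computed;
#' set `likelihood_min = 0` to disable filtering.
#'
#' @param session a [LandmarkSession-class].
#' @param likelihood_min likelihood threshold in \[0, 1\] (default 0.9).
#' @return an [AngleSeries-class].
#' @export
computeAngles <- function(session, likelihood_min = 0.9) {
  stopifnot(methods::is(session, "LandmarkSession"))
  coords <- session@coords
  if (likelihood_min > 0)
    coords <- interpolateLowLikelihood(coords, likelihood_min)
  p <- function(nm) {
    m <- coords[, nm, 1:2, drop = FALSE]
    matrix(m, dim(m)[1L], 2L)
  }
  ant_p <- p("antenna_proximal"); ant_d <- p("antenna_distal")
  apex  <- p("rostrum_apex");     rh    <- p("rostrum_haustellum_joint")
  hl    <- p("haustellum_labellum_joint"); lab <- p("labellum_distal")
  R <- vectorAngleDeg(ant_d - ant_p, rh - apex, "antenna/rostrum segment")
  H <- vectorAngleDeg(apex - rh, hl - rh, "haustellum joint segment")
  L <- vectorAngleDeg(rh - hl, lab - hl, "labellum joint segment")
  AngleSeries(rostrum = R, haustellum = H, labellum = L, fps = session@fps)
}

#' Rolling-percentile baseline of an angle signal
#'
#' Per-frame baseline computed as a percentile (default the 25th) of a
#' centered rolling window (default 5 s). The window is clipped at the
#' sequence edges, so the first and last frames use asymmetric windows. A
#' centered window avoids the phase lag of a trailing window, which would
#' bias extension-onset latencies.
#'
#' @param signal numeric vector (degrees).
#' @param fps frames per second.
#' @param window_s window length in seconds (default 5).
#' @param percentile percentile in \[0, 100\] (default 25).
#' @return numeric baseline, same length as `signal`.
#' @export
rollingBaseline <- function(signal, fps = 20, window_s = 5, percentile = 25) {
  n <- length(signal)
  if (n == 0L) stop("empty signal")
  half <- floor(window_s * fps / 2)
  if (2 * half + 1 < 1) stop("window shorter than one frame")
  p <- percentile / 100
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    unname(quantile(signal[lo:hi], p, names = FALSE, type = 7))
  }, numeric(1))
}
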