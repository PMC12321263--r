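## Extension-event detection: haustellum threshold (full PER) and
## hysteresis on the baseline-subtracted rostrum angle (PER + partials).

## Events are data.frames with 1-based half-open [onset, offset) frame
## intervals: the event covers frames onset .. offset-1.
eventFrame <- function(onset = integer(), offset = integer(),
                       kind = character(), peak_haustellum = numeric(),
                       source = character()) {
  data.frame(onset = as.integer(onset), offset = as.integer(offset),
             kind = kind, peak_haustellum = peak_haustellum,
             source = source, stringsAsFactors = FALSE)
}

## Maximal runs of TRUE in a logical vector, as [onset, offset) intervals.
runsToIntervals <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(onset = starts[keep], offset = ends[keep] + 1L)
}

#' Detect full proboscis extensions (PER) from the haustellum angle
#'
#' A frame is part of a PER when the haustellum angle exceeds
#' `threshold_deg` (default 100 degrees, the angle corresponding to full
#' extension). Maximal super-threshold runs become events; runs separated
#' by at most `merge_gap` frames are merged, and events shorter than
#' `min_duration` frames are dropped. The merge/minimum-duration filters
#' suppress single-frame tracker jitter; set both to 0 for the raw
#' super-threshold tiling.
#'
#' @param angles an [AngleSeries-class].
#' @param threshold_deg PER threshold on the haustellum angle (degrees).
#' @param merge_gap maximal gap (frames) between runs that are merged
#'   (default 2, i.e. 100 ms at 20 Hz).
#' @param min_duration minimal event length in frames (default 2).
#' @return data.frame of events with columns `onset`, `offset` (1-based
#'   half-open frames), `kind` (`"PER"`), `peak_haustellum`, `source`.
#' @export
detectPER <- function(angles, threshold_deg = 100, merge_gap = 2,
                      min_duration = 2) {
  stopifnot(methods::is(angles, "AngleSeries"))
  H <- angles@haustellum
  above <- H > threshold_deg
  if (!any(above)) return(eventFrame())
  iv <- runsToIntervals(above)
  iv <- mergeIntervals(iv, merge_gap)
  keep <- (iv[, "offset"] - iv[, "onset"]) >= max(min_duration, 1L)
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0L) return(eventFrame())
  peak <- vapply(seq_len(nrow(iv)), function(i)
    max(H[iv[i, "onset"]:(iv[i, "offset"] - 1L)]), numeric(1))
  eventFrame(iv[, "onset"], iv[, "offset"], rep("PER", nrow(iv)), peak,
             rep("haustellum_threshold", nrow(iv)))
}

## Merge [onset, offset) intervals whose gap is <= merge_gap frames.
mergeIntervals <- function(iv, merge_gap) {
  if (nrow(iv) <= 1L || merge_gap <= 0) return(iv)
  out <- iv[1L, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    gap <- iv[i, "onset"] - out[nrow(out), "offset"]
    if (gap <= merge_gap) {
      out[nrow(out), "offset"] <- iv[i, "offset"]
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Detect proboscis extensions by hysteresis thresholding
#'
#' Segments PER and partial extensions from the baseline-subtracted rostrum
#' angle. An event is seeded wherever the signal exceeds the upper
#' threshold (default 15 degrees) and grows to the surrounding contiguous
#' region where the signal stays above the lower threshold (default 5
#' degrees); super-`low` regions without a super-`high` frame are not
#' events, and seeded regions that touch merge into one event.
#'
#' @param signal baseline-subtracted rostrum angle (degrees per frame); see
#'   [rollingBaseline()].
#' @param low,high hysteresis thresholds in degrees (defaults 5 and 15).
#' @param haustellum optional haustellum angle vector, used to label each
#'   event `"PER"` (haustellum exceeds `per_threshold` within the event) or
#'   `"partial"`, and to report the peak haustellum angle.
#' @param per_threshold haustellum angle distinguishing full PER from
#'   partial extension (degrees, default 100).
#' @return data.frame of events (see [detectPER()]) with
#'   `source = "rostrum_hysteresis"` and `kind` in `{"PER","partial"}`.
#' @export
detectExtensions <- function(signal, low = 5, high = 15,
                             haustellum = NULL, per_threshold = 100) {
  if (low >= high) stop("hysteresis requires low < high")
  above_low <- signal > low
  if (!any(above_low)) return(eventFrame())
  iv <- runsToIntervals(above_low)
  seeded <- vapply(seq_len(nrow(iv)), function(i)
    any(signal[iv[i, "onset"]:(iv[i, "offset"] - 1L)] > high), logical(1))
  iv <- iv[seeded, , drop = FALSE]
  if (nrow(iv) == 0L) return(eventFrame())
  n <- nrow(iv)
  kind <- rep("partial", n)
  peak <- rep(NA_real_, n)
  if (!is.null(haustellum)) {
    for (i in seq_len(n)) {
      hseg <- haustellum[iv[i, "onset"]:(iv[i, "offset"] - 1L)]
      peak[i] <- max(hseg)
      if (peak[i] > per_threshold) kind[i] <- "PER"
    }
  }
  eventFrame(iv[, "onset"], iv[, "offset"], kind, peak,
             rep("rostrum_hysteresis", n))
}

#' Extract per-event angle trajectories
#'
#' Returns, for each detected event, the temporal sequence of the rostrum
#' and haustellum angles over the event frames — the representation used
#' for dynamic-time-warping comparison and K-medoids clustering.
#'
#' @param events event data.frame ([detectPER()] / [detectExtensions()]).
#' @param angles an [AngleSeries-class].
#' @return list of `n x 2` matrices (columns `rostrum`, `haustellum`) with
#'   attribute `fps`; names carry the event row index.
#' @export
eventTrajectories <- function(events, angles) {
  stopifnot(methods::is(angles, "AngleSeries"))
  out <- lapply(seq_len(nrow(events)), function(i) {
    idx <- events$onset[i]:(events$offset[i] - 1L)
    m <- cbind(rostrum = angles@rostrum[idx],
               haustellum = angles@haustellum[idx])
    attr(m, "fps") <- angles@fps
    m
  })
  names(out) <- rownames(events)
  out
}
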