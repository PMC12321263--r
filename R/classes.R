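## S4 containers for the four acquisition modalities.

#' LandmarkSession: tracked head landmarks for one recording session
#'
#' Holds per-frame (x, y, likelihood) for the six canonical head landmarks
#' (`antenna_proximal`, `antenna_distal`, `rostrum_apex`,
#' `rostrum_haustellum_joint`, `haustellum_labellum_joint`,
#' `labellum_distal`), the video frame rate, and the trial table.
#'
#' @slot coords numeric array `frames x 6 x 3` with dimnames
#'   `(NULL, landmark, c("x","y","likelihood"))`; pixels, image convention
#'   (origin top-left, y downward); likelihood in \[0, 1\].
#' @slot fps frames per second (video default 20).
#' @slot trials data.frame with columns `trial_index`, `stimulus_id`,
#'   `valve_open_time` (s), `stimulus_duration` (s), `block`; may have zero
#'   rows.
#' @exportClass LandmarkSession
setClass("LandmarkSession",
  representation(coords = "array", fps = "numeric", trials = "data.frame")
)

setValidity("LandmarkSession", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 6L || d[3] != 3L)
    return("coords must be a frames x 6 x 3 array")
  if (!identical(dimnames(object@coords)[[2]], LANDMARK_NAMES))
    return(paste0("landmarks must be exactly, in order: ",
                  paste(LANDMARK_NAMES, collapse = ", ")))
  lik <- object@coords[, , 3L]
  if (anyNA(object@coords[, , 1:2]))
    return("coordinates contain NA")
  if (any(lik < 0 | lik > 1, na.rm = TRUE))
    return("likelihood values must lie in [0, 1]")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a single positive number")
  if (nrow(object@trials) > 0) {
    need <- c("trial_index", "stimulus_id", "valve_open_time")
    if (!all(need %in% names(object@trials)))
      return(paste("trial table must contain:", paste(need, collapse = ", ")))
    if (any(object@trials$valve_open_time < 0))
      return("valve_open_time must be >= 0")
  }
  TRUE
})

#' Construct a LandmarkSession
#'
#' @param coords `frames x 6 x 3` array (see [LandmarkSession-class]) or a
#'   named list of per-landmark matrices with columns x, y, likelihood.
#' @param fps frames per second.
#' @param trials trial table data.frame (see [trialTable()]); optional.
#' @return a validated `LandmarkSession`.
#' @export
LandmarkSession <- function(coords, fps = 20,
                            trials = emptyTrialTable()) {
  if (is.list(coords) && !is.array(coords)) {
    nm <- names(coords)
    if (!setequal(nm, LANDMARK_NAMES)) {
      stop("landmark set mismatch; expected exactly: ",
           paste(LANDMARK_NAMES, collapse = ", "))
    }
    nf <- nrow(coords[[1L]])
    arr <- array(NA_real_, c(nf, 6L, 3L),
                 dimnames = list(NULL, LANDMARK_NAMES,
                                 c("x", "y", "likelihood")))
    for (l in LANDMARK_NAMES) {
      m <- as.matrix(coords[[l]])
      if (nrow(m) != nf) stop("per-frame series differ in length")
      if (ncol(m) == 2L) m <- cbind(m, 1.0)
      arr[, l, ] <- m[, 1:3]
    }
    coords <- arr
  }
  methods::new("LandmarkSession", coords = coords, fps = fps,
               trials = as.data.frame(trials))
}

#' @describeIn LandmarkSession Number of frames in the session.
#' @param x,object a `LandmarkSession`.
#' @export
nFrames <- function(x) dim(x@coords)[1L]

#' Frame rate accessor
#' @param x an object with an `fps` slot.
#' @return frames (or volumes) per second.
#' @export
fps <- function(x) x@fps

#' Trial table accessor
#' @param x a `LandmarkSession`.
#' @export
trials <- function(x) x@trials

#' Landmark coordinate accessor
#' @param x a `LandmarkSession`.
#' @param landmark landmark name; if `NULL`, the full array.
#' @return a `frames x 3` matrix (x, y, likelihood) or the full array.
#' @export
landmarkCoords <- function(x, landmark = NULL) {
  if (is.null(landmark)) return(x@coords)
  if (!landmark %in% LANDMARK_NAMES) stop("unknown landmark: ", landmark)
  x@coords[, landmark, , drop = TRUE]
}

setMethod("show", "LandmarkSession", function(object) {
  cat("LandmarkSession:", nFrames(object), "frames at", object@fps, "Hz (",
      sprintf("%.1f", nFrames(object) / object@fps), "s );",
      nrow(object@trials), "trials\n")
})

#' AngleSeries: proboscis joint angles over time
#'
#' The three unsigned proboscis angles per video frame, in degrees:
#' rostrum (R, between the antenna line and the rostrum segment),
#' haustellum (H, at the rostrum–haustellum joint) and labellum (L, at the
#' haustellum–labellum joint).
#'
#' @slot rostrum,haustellum,labellum numeric vectors, degrees in \[0, 180\].
#' @slot fps frames per second.
#' @exportClass AngleSeries
setClass("AngleSeries",
  representation(rostrum = "numeric", haustellum = "numeric",
                 labellum = "numeric", fps = "numeric")
)

setValidity("AngleSeries", function(object) {
  n <- length(object@rostrum)
  if (length(object@haustellum) != n || length(object@labellum) != n)
    return("angle series must have equal lengths")
  all_a <- c(object@rostrum, object@haustellum, object@labellum)
  if (any(all_a < 0 | all_a > 180, na.rm = TRUE))
    return("angles must lie in [0, 180] degrees")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' Construct an AngleSeries
#' @param rostrum,haustellum,labellum angle vectors in degrees.
#' @param fps frames per second.
#' @export
AngleSeries <- function(rostrum, haustellum, labellum, fps = 20) {
  methods::new("AngleSeries", rostrum = rostrum, haustellum = haustellum,
               labellum = labellum, fps = fps)
}

#' @describeIn AngleSeries angles as a data.frame with a time column.
#' @param x an `AngleSeries`.
#' @export
anglesAsFrame <- function(x) {
  data.frame(
    frame = seq_along(x@rostrum),
    time = (seq_along(x@rostrum) - 1) / x@fps,
    rostrum = x@rostrum, haustellum = x@haustellum, labellum = x@labellum
  )
}

setMethod("show", "AngleSeries", function(object) {
  cat("AngleSeries:", length(object@rostrum), "frames at", object@fps,
      "Hz; haustellum range",
      sprintf("[%.1f, %.1f]", min(object@haustellum), max(object@haustellum)),
      "deg\n")
})

#' MovieStack: multi-plane fluorescence movie
#'
#' A 4-D intensity array indexed `(time, plane, row, col)` from volumetric
#' two-photon imaging (default 5 optical planes scanned every 500 ms).
#'
#' @slot data numeric 4-D array `(time, plane, row, col)`, non-negative
#'   (NA allowed for registration edge fill).
#' @slot volume_period seconds per volume (default 0.5).
#' @slot pixel_size micrometers per pixel (NA when unknown).
#' @slot trial_frames volumes per trial (0 when the stack is not organized
#'   in trials).
#' @exportClass MovieStack
setClass("MovieStack",
  representation(data = "array", volume_period = "numeric",
                 pixel_size = "numeric", trial_frames = "integer")
)

setValidity("MovieStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a (time, plane, row, col) array")
  if (any(object@data < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  if (object@volume_period <= 0) return("volume_period must be positive")
  if (object@trial_frames < 0) return("trial_frames must be >= 0")
  TRUE
})

#' Construct a MovieStack
#' @param data 4-D array `(time, plane, row, col)`.
#' @param volume_period seconds per volume.
#' @param pixel_size micrometers per pixel (`NA` if unknown).
#' @param trial_frames volumes per trial (0 if not trial-organized).
#' @export
MovieStack <- function(data, volume_period = 0.5, pixel_size = NA_real_,
                       trial_frames = 0L) {
  methods::new("MovieStack", data = data, volume_period = volume_period,
               pixel_size = pixel_size, trial_frames = as.integer(trial_frames))
}

#' @describeIn MovieStack number of time points (volumes).
#' @param x a `MovieStack`.
#' @export
nVolumes <- function(x) dim(x@data)[1L]

#' @describeIn MovieStack number of optical planes.
#' @export
nPlanes <- function(x) dim(x@data)[2L]

#' Movie intensity data accessor
#' @param x a `MovieStack`.
#' @return the 4-D array `(time, plane, row, col)`.
#' @export
movieData <- function(x) x@data

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat("MovieStack:", d[1], "volumes x", d[2], "planes x", d[3], "x", d[4],
      "px;", object@volume_period, "s/volume\n")
})

#' VoltageTrace: extracellular tip-recording trace
#'
#' @slot samples voltage samples (arbitrary units).
#' @slot sampling_rate Hz (default 10000).
#' @slot t0 time of the first sample in seconds relative to stimulus
#'   contact (contact at t = 0 by convention).
#' @exportClass VoltageTrace
setClass("VoltageTrace",
  representation(samples = "numeric", sampling_rate = "numeric",
                 t0 = "numeric")
)

setValidity("VoltageTrace", function(object) {
  if (length(object@samples) < 2L) return("trace must contain >= 2 samples")
  if (object@sampling_rate <= 0) return("sampling_rate must be positive")
  TRUE
})

#' Construct a VoltageTrace
#' @param samples numeric vector of voltage samples.
#' @param sampling_rate Hz.
#' @param t0 time of first sample relative to stimulus contact (s).
#' @export
VoltageTrace <- function(samples, sampling_rate = 10000, t0 = 0) {
  methods::new("VoltageTrace", samples = samples,
               sampling_rate = sampling_rate, t0 = t0)
}

#' Sample times of a VoltageTrace
#' @param x a `VoltageTrace`.
#' @return times in seconds relative to stimulus contact.
#' @export
traceTimes <- function(x) x@t0 + (seq_along(x@samples) - 1) / x@sampling_rate

setMethod("show", "VoltageTrace", function(object) {
  cat("VoltageTrace:", length(object@samples), "samples at",
      object@sampling_rate, "Hz (",
      sprintf("%.3f", length(object@samples) / object@sampling_rate), "s )\n")
})

#' SpikeTrain: detected spike times
#'
#' Spike times in seconds relative to stimulus contact, strictly increasing,
#' with inter-spike intervals at least the refractory period used by the
#' detector. Spikes are counted, never sorted by shape or amplitude.
#'
#' @slot times numeric, strictly increasing, seconds.
#' @slot threshold detection threshold in trace units.
#' @slot refractory refractory period (s) enforced by the detector.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", threshold = "numeric",
                 refractory = "numeric")
)

setValidity("SpikeTrain", function(object) {
  if (is.unsorted(object@times, strictly = TRUE))
    return("spike times must be strictly increasing")
  if (length(object@times) > 1L &&
      any(diff(object@times) < object@refractory - 1e-12))
    return("inter-spike intervals violate the refractory period")
  TRUE
})

#' Construct a SpikeTrain
#' @param times spike times (s, relative to contact), strictly increasing.
#' @param threshold detection threshold used (trace units).
#' @param refractory refractory period (s).
#' @export
SpikeTrain <- function(times, threshold = NA_real_, refractory = 0) {
  methods::new("SpikeTrain", times = as.numeric(times),
               threshold = threshold, refractory = refractory)
}

#' Spike time accessor
#' @param x a `SpikeTrain`.
#' @export
spikeTimes <- function(x) x@times

setMethod("show", "SpikeTrain", function(object) {
  cat("SpikeTrain:", length(object@times), "spikes")
  if (length(object@times))
    cat(" in [", sprintf("%.3f", min(object@times)), ",",
        sprintf("%.3f", max(object@times)), "] s")
  cat("; threshold", sprintf("%.3g", object@threshold), "\n")
})

#' Build a trial table
#'
#' One row per trial: stimulus identity, valve-open time, stimulus duration
#' and block. The default protocol presents 9 stimuli (six odors plus
#' mineral-oil, water and air controls) for 2 s each with a 15 s
#' inter-trial interval, in each of 3 blocks.
#'
#' @param stimulus_id character vector of stimulus labels, one per trial in
#'   presentation order.
#' @param valve_open_time valve-open times in seconds from recording start;
#'   if `NULL`, trials are laid out regularly with the given interval.
#' @param stimulus_duration stimulus duration per trial (s).
#' @param iti_s inter-trial interval (s) used for the regular layout.
#' @param block block index per trial; if `NULL` and the number of trials is
#'   a multiple of the number of unique stimuli, blocks are inferred.
#' @param start_s time of the first valve opening (s).
#' @return data.frame with columns `trial_index`, `stimulus_id`,
#'   `valve_open_time`, `stimulus_duration`, `block`.
#' @export
trialTable <- function(stimulus_id, valve_open_time = NULL,
                       stimulus_duration = 2, iti_s = 15, block = NULL,
                       start_s = 5) {
  n <- length(stimulus_id)
  if (is.null(valve_open_time))
    valve_open_time <- start_s + (seq_len(n) - 1) * (stimulus_duration + iti_s)
  if (length(valve_open_time) != n)
    stop("stimulus_id and valve_open_time differ in length")
  if (is.unsorted(valve_open_time, strictly = TRUE))
    stop("valve_open_time must be strictly increasing")
  gaps <- diff(valve_open_time)
  if (any(gaps < stimulus_duration))
    stop("trials overlap: valve openings closer than the stimulus duration")
  if (is.null(block)) {
    ns <- length(unique(stimulus_id))
    block <- if (n %% ns == 0) rep(seq_len(n / ns), each = ns) else rep(1L, n)
  }
  data.frame(
    trial_index = seq_len(n), stimulus_id = as.character(stimulus_id),
    valve_open_time = valve_open_time,
    stimulus_duration = rep(stimulus_duration, length.out = n),
    block = block, stringsAsFactors = FALSE
  )
}

emptyTrialTable <- function() {
  data.frame(trial_index = integer(), stimulus_id = character(),
             valve_open_time = numeric(), stimulus_duration = numeric(),
             block = integer(), stringsAsFactors = FALSE)
}

#' Canonical landmark names
#'
#' @return the six tracked head points in canonical order.
#' @export
landmarkNames <- function() LANDMARK_NAMES
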