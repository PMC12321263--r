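## Forward-kinematic behavior generator: plants extension events with
## known angle trajectories and renders the six head landmarks.

#' Describe a synthetic behavior session
#'
#' Parameterizes the tethered-fly odor assay: 9 stimuli (six odors plus
#' mineral-oil, water and air controls) presented for 2 s with a 15 s
#' inter-trial interval, in 3 blocks, filmed at 20 Hz. Response
#' probabilities, latency and duration distributions, the peak haustellum
#' angle and the tracking-noise model are all explicit so every detector
#' can be scored against ground truth.
#'
#' @param stimuli stimulus labels (default six odors + three controls).
#' @param blocks number of blocks (default 3); each stimulus appears once
#'   per block.
#' @param fps video frame rate (default 20).
#' @param stimulus_s stimulus duration (default 2 s).
#' @param iti_s inter-trial interval (default 15 s).
#' @param response_prob named (or recycled) per-stimulus probability that a
#'   trial elicits PER; defaults: 0.8 for odors, 0.05 for controls.
#' @param latency_mean,latency_sd lognormal-ish latency of the PER onset
#'   after odor onset (s); drawn as `1 + gamma`, truncated to \[1, 4\] so
#'   planted events fall in the scoring window.
#' @param duration_mean,duration_sd PER event duration (s), truncated to
#'   \[0.5, 3\].
#' @param peak_haustellum_mean,peak_haustellum_sd peak haustellum angle of
#'   full PER (deg), truncated to (105, 175).
#' @param partial_prob per-trial probability of an additional partial
#'   extension (haustellum stays below 100 deg).
#' @param spontaneous_rate expected number of spontaneous PER events per
#'   trial period, planted outside the response window.
#' @param noise_px Gaussian tracking noise SD in pixels (default 1).
#' @param dropout_rate per-frame probability that one landmark's
#'   likelihood drops below threshold (its coordinates are corrupted).
#' @param rest_angles baseline (rostrum, haustellum, labellum) in degrees.
#' @return list of class `behavior_scenario`.
#' @export
behaviorScenario <- function(stimuli = c("2PT", "OCT", "MCH", "BNZ", "EBR",
                                         "IPA", "mineral_oil", "water",
                                         "air"),
                             blocks = 3, fps = 20, stimulus_s = 2,
                             iti_s = 15,
                             response_prob = NULL,
                             latency_mean = 1.6, latency_sd = 0.6,
                             duration_mean = 1.5, duration_sd = 0.5,
                             peak_haustellum_mean = 130,
                             peak_haustellum_sd = 8,
                             partial_prob = 0.15,
                             spontaneous_rate = 0,
                             noise_px = 1, dropout_rate = 0.01,
                             rest_angles = c(rostrum = 35, haustellum = 60,
                                             labellum = 160)) {
  if (is.null(response_prob)) {
    response_prob <- ifelse(stimuli %in% c("mineral_oil", "water", "air"),
                            0.05, 0.8)
    names(response_prob) <- stimuli
  } else if (is.null(names(response_prob))) {
    response_prob <- setNames(rep(response_prob, length.out =
                                    length(stimuli)), stimuli)
  }
  stopifnot(all(response_prob >= 0 & response_prob <= 1))
  structure(list(stimuli = stimuli, blocks = blocks, fps = fps,
                 stimulus_s = stimulus_s, iti_s = iti_s,
                 response_prob = response_prob,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 peak_haustellum_mean = peak_haustellum_mean,
                 peak_haustellum_sd = peak_haustellum_sd,
                 partial_prob = partial_prob,
                 spontaneous_rate = spontaneous_rate,
                 noise_px = noise_px, dropout_rate = dropout_rate,
                 rest_angles = rest_angles),
            class = "behavior_scenario")
}

## Rotation of a unit 2-vector by deg (image convention; the sign of the
## rotation is irrelevant for the unsigned angles we invert).
rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

## Head-model segment lengths (px) and fixed anchors: ~50 px segments so
## 1 px tracking noise translates to ~2 deg of angle noise.
HEAD_GEOM <- list(
  antenna_proximal = c(120, 80), antenna_dir = c(0.5, 0.8),
  antenna_len = 40, apex_offset = c(8, 22),
  rostrum_len = 50, haustellum_len = 45, labellum_len = 28
)

#' Render landmark coordinates that realize given angle trajectories
#'
#' Forward kinematics of the head model: the antenna line is fixed; the
#' rostrum direction makes the rostrum angle R with it; the haustellum and
#' labellum directions make the interior angles H and L at their joints.
#' [computeAngles()] inverts this exactly (to numerical precision) in the
#' noiseless case.
#'
#' @param R,H,L angle vectors in degrees, all in (0, 180).
#' @return `frames x 6 x 3` coordinate array (likelihood 1).
#' @export
landmarksFromAngles <- function(R, H, L) {
  n <- length(R)
  if (any(c(R, H, L) <= 0 | c(R, H, L) >= 180))
    stop("impossible geometry: angles must lie strictly inside (0, 180)")
  g <- HEAD_GEOM
  a_dir <- g$antenna_dir / sqrt(sum(g$antenna_dir^2))
  arr <- array(NA_real_, c(n, 6L, 3L),
               dimnames = list(NULL, LANDMARK_NAMES,
                               c("x", "y", "likelihood")))
  ant_p <- g$antenna_proximal
  ant_d <- ant_p + g$antenna_len * a_dir
  apex <- ant_p + g$apex_offset
  for (i in seq_len(n)) {
    d_r <- rot2(a_dir, R[i])
    j1 <- apex + g$rostrum_len * d_r
    d_h <- rot2(-d_r, H[i])
    j2 <- j1 + g$haustellum_len * d_h
    d_l <- rot2(-d_h, L[i])
    j3 <- j2 + g$labellum_len * d_l
    arr[i, "antenna_proximal", 1:2] <- ant_p
    arr[i, "antenna_distal", 1:2] <- ant_d
    arr[i, "rostrum_apex", 1:2] <- apex
    arr[i, "rostrum_haustellum_joint", 1:2] <- j1
    arr[i, "haustellum_labellum_joint", 1:2] <- j2
    arr[i, "labellum_distal", 1:2] <- j3
  }
  arr[, , 3L] <- 1
  arr
}

## Truncated normal draw by rejection (cheap at these scales).
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate a synthetic behavior session with known ground truth
#'
#' Plants PER and partial-extension events on the angle timeline
#' (rectangular haustellum excursions above / below 100 degrees with short
#' sub-threshold shoulders, plus matching rostrum excursions), renders the
#' six landmarks by forward kinematics, then adds Gaussian pixel noise and
#' likelihood dropouts. Deterministic given `seed`.
#'
#' @param scenario a [behaviorScenario()].
#' @param seed integer seed.
#' @return list: `session` ([LandmarkSession-class]), `events`
#'   (ground-truth data.frame: `trial_index`, `stimulus_id`, `kind`,
#'   `onset`, `offset` 1-based half-open frames, `latency_s`,
#'   `peak_haustellum`), `angles` (the noiseless [AngleSeries-class]).
#' @export
generateLandmarks <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "behavior_scenario"))
  sc <- scenario
  withSeed(seed, {
    stim_seq <- as.vector(vapply(seq_len(sc$blocks), function(b)
      sample(sc$stimuli), character(length(sc$stimuli))))
    tt <- trialTable(stim_seq, stimulus_duration = sc$stimulus_s,
                     iti_s = sc$iti_s)
    n_trials <- nrow(tt)
    total_s <- max(tt$valve_open_time) + sc$stimulus_s + sc$iti_s
    nf <- ceiling(total_s * sc$fps)
    R <- rep(sc$rest_angles[["rostrum"]], nf)
    H <- rep(sc$rest_angles[["haustellum"]], nf)
    L <- rep(sc$rest_angles[["labellum"]], nf)
    ev <- list()
    plant <- function(onset_f, dur_f, kind, peakH, trial_i, stim, lat) {
      offset_f <- min(onset_f + dur_f, nf - 2L)
      if (offset_f <= onset_f) return(NULL)
      idx <- onset_f:(offset_f - 1L)
      dR <- if (kind == "PER") 27 else 19
      H[idx] <<- peakH
      R[idx] <<- sc$rest_angles[["rostrum"]] + dR
      L[idx] <<- sc$rest_angles[["labellum"]] - 15
      ## sub-threshold shoulders just outside the event
      for (s in 1:2) {
        w <- 1 - s / 3
        pre <- onset_f - s; post <- offset_f - 1L + s
        if (pre >= 1L && H[pre] == sc$rest_angles[["haustellum"]]) {
          H[pre] <<- sc$rest_angles[["haustellum"]] +
            w * (min(95, peakH) - sc$rest_angles[["haustellum"]])
          R[pre] <<- sc$rest_angles[["rostrum"]] + w * 4
        }
        if (post <= nf && H[post] == sc$rest_angles[["haustellum"]]) {
          H[post] <<- sc$rest_angles[["haustellum"]] +
            w * (min(95, peakH) - sc$rest_angles[["haustellum"]])
          R[post] <<- sc$rest_angles[["rostrum"]] + w * 4
        }
      }
      data.frame(trial_index = trial_i, stimulus_id = stim, kind = kind,
                 onset = onset_f, offset = offset_f, latency_s = lat,
                 peak_haustellum = peakH, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_trials)) {
      p <- sc$response_prob[[tt$stimulus_id[i]]]
      t0 <- tt$valve_open_time[i]
      if (runif(1) < p) {
        lat <- rtnorm(1, sc$latency_mean, sc$latency_sd, 1.05, 3.9)
        dur <- rtnorm(1, sc$duration_mean, sc$duration_sd, 0.5, 3)
        peak <- rtnorm(1, sc$peak_haustellum_mean, sc$peak_haustellum_sd,
                       106, 174)
        onset_f <- round((t0 + lat) * sc$fps) + 1L
        ev[[length(ev) + 1L]] <- plant(onset_f, round(dur * sc$fps), "PER",
                                       peak, i, tt$stimulus_id[i], lat)
      }
      if (runif(1) < sc$partial_prob) {
        lat <- runif(1, 7.2, 9.5)  # clear of the response window and PER
        dur <- rtnorm(1, 0.8, 0.3, 0.4, 1.5)
        onset_f <- round((t0 + lat) * sc$fps) + 1L
        ev[[length(ev) + 1L]] <- plant(onset_f, round(dur * sc$fps),
                                       "partial", rtnorm(1, 88, 4, 75, 97),
                                       i, tt$stimulus_id[i], lat)
      }
      if (sc$spontaneous_rate > 0 && runif(1) < min(1, sc$spontaneous_rate)) {
        lat <- runif(1, 11.8, sc$iti_s - 1)  # outside the response window
        dur <- rtnorm(1, 1, 0.3, 0.5, 2)
        onset_f <- round((t0 + lat) * sc$fps) + 1L
        ev[[length(ev) + 1L]] <- plant(onset_f, round(dur * sc$fps), "PER",
                                       rtnorm(1, 125, 6, 106, 174), i,
                                       tt$stimulus_id[i], lat)
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(trial_index = integer(), stimulus_id = character(),
                 kind = character(), onset = integer(), offset = integer(),
                 latency_s = numeric(), peak_haustellum = numeric(),
                 stringsAsFactors = FALSE)
    angles_true <- AngleSeries(R, H, L, fps = sc$fps)
    coords <- landmarksFromAngles(R, H, L)
    if (sc$noise_px > 0)
      coords[, , 1:2] <- coords[, , 1:2] +
        rnorm(length(coords[, , 1:2]), 0, sc$noise_px)
    if (sc$dropout_rate > 0) {
      drop_frame <- runif(nf) < sc$dropout_rate
      if (any(drop_frame)) {
        which_lm <- sample.int(6L, sum(drop_frame), replace = TRUE)
        for (k in seq_along(which_lm)) {
          f <- which(drop_frame)[k]
          coords[f, which_lm[k], 1:2] <-
            coords[f, which_lm[k], 1:2] + rnorm(2, 0, 25)
          coords[f, which_lm[k], 3L] <- runif(1, 0, 0.5)
        }
      }
    }
    session <- methods::new("LandmarkSession", coords = coords,
                            fps = sc$fps, trials = tt)
    list(session = session, events = events, angles = angles_true)
  })
}
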