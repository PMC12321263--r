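## Per-trial and per-fly behavioral metrics.

## Overlap (s) between [a0, a1) and [b0, b1).
overlapLen <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

## Event frame interval -> time interval [onset_t, offset_t) in seconds.
eventTimes <- function(events, fps) {
  cbind(on = (events$onset - 1) / fps, off = (events$offset - 1) / fps)
}

#' Per-trial PER metrics
#'
#' Scores one trial against the detected PER events. The integrated
#' duration is the total overlap (seconds) of PER events with the scoring
#' window — by default 4 s starting 1 s after odor onset, the period in
#' which most odor-evoked extensions occur (the 1 s offset absorbs the
#' delay between valve opening and odor arrival). The per-second duration
#' is the same overlap split into 1-s bins. A trial counts as a response
#' when a PER onset falls within `response_window_s` of the odor onset;
#' latency is the first such onset relative to odor onset.
#'
#' @param events PER event data.frame from [detectPER()] (rows with
#'   `kind != "PER"` are ignored).
#' @param trial one row of a trial table ([trialTable()]).
#' @param fps video frames per second.
#' @param n_frames total frames in the recording (for window validation);
#'   `NULL` skips the check.
#' @param odor_delay_s extra delay between valve opening and stimulus
#'   arrival (s). Default 0 because the 1-s offset of the default scoring
#'   window already accounts for odor travel time; a measured travel delay
#'   of 1.1 s is available as `odorArrivalDelay()` for analyses that score
#'   relative to arrival instead.
#' @param window scoring window in seconds relative to odor onset
#'   (default `c(1, 5)`).
#' @param response_window_s window (s) after odor onset in which a PER
#'   onset counts as a response (default 5; use 2 for brief-touch assays).
#' @return list with `trial_index`, `stimulus_id`, `integrated_duration`,
#'   `per_second_duration` (one value per 1-s bin, each in \[0, 1\]),
#'   `responded`, `latency` (NA when no response).
#' @export
trialMetrics <- function(events, trial, fps = 20, n_frames = NULL,
                         odor_delay_s = 0, window = c(1, 5),
                         response_window_s = 5) {
  t0 <- trial$valve_open_time + odor_delay_s
  w0 <- t0 + window[1]
  w1 <- t0 + window[2]
  if (!is.null(n_frames)) {
    t_end <- (n_frames - 1) / fps
    if (w0 < 0 || w1 > t_end)
      stop("scoring window [", w0, ", ", w1, ") outside recording [0, ",
           t_end, ")")
  }
  ev <- events[events$kind == "PER", , drop = FALSE]
  nbins <- floor(window[2] - window[1])
  persec <- numeric(nbins)
  integ <- 0
  responded <- FALSE
  latency <- NA_real_
  if (nrow(ev)) {
    et <- eventTimes(ev, fps)
    integ <- sum(overlapLen(et[, "on"], et[, "off"], w0, w1))
    for (b in seq_len(nbins)) {
      persec[b] <- sum(overlapLen(et[, "on"], et[, "off"],
                                  w0 + b - 1, w0 + b))
    }
    in_resp <- et[, "on"] >= t0 & et[, "on"] <= t0 + response_window_s
    responded <- any(in_resp)
    if (responded) latency <- min(et[in_resp, "on"]) - t0
  }
  list(trial_index = trial$trial_index,
       stimulus_id = trial$stimulus_id,
       integrated_duration = integ,
       per_second_duration = persec,
       responded = responded,
       latency = latency)
}

#' Odor arrival delay preset
#'
#' Measured travel time from valve opening to odor arrival at the fly in
#' the frontal-delivery configuration.
#'
#' @return 1.1 (seconds).
#' @export
odorArrivalDelay <- function() 1.1

#' Score every trial of a session
#'
#' Applies [trialMetrics()] to each row of the trial table and returns a
#' tidy per-trial data.frame (per-second bins as columns `per_sec_1` ...).
#'
#' @inheritParams trialMetrics
#' @param trials trial table ([trialTable()]).
#' @return data.frame, one row per trial.
#' @export
sessionMetrics <- function(events, trials, fps = 20, n_frames = NULL,
                           odor_delay_s = 0, window = c(1, 5),
                           response_window_s = 5) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    m <- trialMetrics(events, trials[i, ], fps, n_frames, odor_delay_s,
                      window, response_window_s)
    ps <- setNames(as.list(m$per_second_duration),
                   paste0("per_sec_", seq_along(m$per_second_duration)))
    c(list(trial_index = m$trial_index, stimulus_id = m$stimulus_id,
           block = trials$block[i], responded = m$responded,
           latency = m$latency,
           integrated_duration = m$integrated_duration), ps)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Per-fly, per-stimulus summary metrics and the exclusion flag
#'
#' Averages the trial metrics per stimulus (by default across the three
#' presentations of each stimulus): PER probability is the percentage of a
#' stimulus' trials in which PER was observed; integrated duration and
#' latency are means across trials (latency across responding trials).
#' A trial is flagged *spontaneous* when a PER onset occurs within the
#' trial period but outside the response window; flies with spontaneous
#' PER in more than `spontaneous_max` trials (default 9) are flagged
#' `excluded` — flagged only, never silently dropped.
#'
#' @param session_metrics per-trial data.frame from [sessionMetrics()].
#' @param events PER event data.frame for the same session.
#' @param trials trial table.
#' @param fps frames per second.
#' @param trials_per_stimulus expected presentations per stimulus
#'   (default 3); fewer available trials triggers a warning and the
#'   summary is computed on what is present.
#' @param response_window_s response window used for the spontaneous rule
#'   (must match the one used in scoring).
#' @param odor_delay_s as in [trialMetrics()].
#' @param spontaneous_max largest tolerated number of spontaneous trials
#'   (default 9; more than this excludes the fly).
#' @param iti_s inter-trial interval (s), used to bound the last trial's
#'   period.
#' @return list with `per_stimulus` (data.frame: `stimulus_id`, `n_trials`,
#'   `per_probability` in %, `mean_integrated_duration`, `mean_latency`),
#'   `spontaneous_trial_count`, `excluded`.
#' @export
flyMetrics <- function(session_metrics, events, trials, fps = 20,
                       trials_per_stimulus = 3, response_window_s = 5,
                       odor_delay_s = 0, spontaneous_max = 9, iti_s = 15) {
  sm <- session_metrics
  stim <- unique(trials$stimulus_id)
  per_stim <- do.call(rbind, lapply(stim, function(s) {
    rows <- sm[sm$stimulus_id == s, , drop = FALSE]
    if (nrow(rows) < trials_per_stimulus)
      warning("stimulus ", s, ": only ", nrow(rows), " of ",
              trials_per_stimulus, " trials available")
    lat <- rows$latency[rows$responded]
    data.frame(
      stimulus_id = s, n_trials = nrow(rows),
      per_probability = 100 * mean(rows$responded),
      mean_integrated_duration = mean(rows$integrated_duration),
      mean_latency = if (length(lat)) mean(lat) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  ev <- events[events$kind == "PER", , drop = FALSE]
  spont <- 0L
  if (nrow(ev) && nrow(trials)) {
    on_t <- (ev$onset - 1) / fps
    starts <- trials$valve_open_time
    ends <- c(starts[-1], starts[length(starts)] +
                trials$stimulus_duration[nrow(trials)] + iti_s)
    t0 <- starts + odor_delay_s
    spont <- sum(vapply(seq_len(nrow(trials)), function(i) {
      inside <- on_t >= starts[i] & on_t < ends[i]
      in_resp <- on_t >= t0[i] & on_t <= t0[i] + response_window_s
      any(inside & !in_resp)
    }, logical(1)))
  }
  list(per_stimulus = per_stim,
       spontaneous_trial_count = as.integer(spont),
       excluded = spont > spontaneous_max)
}
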