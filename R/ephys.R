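## Tip-recording analysis: bandpass filtering, MAD-threshold spike
## detection (no sorting), and windowed spike counts.

#' Zero-phase bandpass filter for voltage traces
#'
#' Butterworth bandpass (default 100–1000 Hz) applied forward and backward
#' (`signal::filtfilt`), giving a zero-phase 4th-order response so spike
#' times are not shifted by the filter. The trace mean (DC) is removed
#' before filtering.
#'
#' @param trace a [VoltageTrace-class].
#' @param low,high band edges in Hz.
#' @return a filtered [VoltageTrace-class].
#' @export
bandpassFilter <- function(trace, low = 100, high = 1000) {
  stopifnot(methods::is(trace, "VoltageTrace"))
  fs <- trace@sampling_rate
  if (high >= fs / 2)
    stop("upper band edge (", high, " Hz) must be below the Nyquist ",
         "frequency (", fs / 2, " Hz)")
  if (low <= 0 || low >= high) stop("band edges must satisfy 0 < low < high")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  x <- trace@samples - mean(trace@samples)
  y <- signal::filtfilt(bf, x)
  methods::new("VoltageTrace", samples = as.numeric(y),
               sampling_rate = fs, t0 = trace@t0)
}

#' Detect spikes with a MAD-scaled threshold
#'
#' Spikes are counted, not sorted: any excursion of the filtered trace
#' beyond `k_mad` robust standard deviations (`1.4826 x` median absolute
#' deviation) in either polarity is a candidate spike, timed at the local
#' extremum of the excursion. Candidates closer than the refractory period
#' collapse to the one with the larger absolute extremum. Because the
#' threshold scales with the MAD, detection is invariant to trace gain.
#'
#' @param trace a filtered [VoltageTrace-class] ([bandpassFilter()]).
#' @param k_mad threshold in robust SD units (default 4).
#' @param refractory_ms minimal separation between spikes (default 1 ms).
#' @param polarity `"both"` (default), `"positive"` or `"negative"`.
#' @return a [SpikeTrain-class] (times relative to stimulus contact).
#' @export
detectSpikes <- function(trace, k_mad = 4, refractory_ms = 1,
                         polarity = c("both", "positive", "negative")) {
  stopifnot(methods::is(trace, "VoltageTrace"))
  polarity <- match.arg(polarity)
  x <- trace@samples
  sigma <- mad(x)  # includes the 1.4826 normal-consistency constant
  if (sigma == 0) stop("flat trace: MAD is zero, cannot set a threshold")
  thr <- k_mad * sigma
  excess <- switch(polarity,
    both = abs(x) > thr,
    positive = x > thr,
    negative = -x > thr)
  if (!any(excess)) {
    return(methods::new("SpikeTrain", times = numeric(0), threshold = thr,
                        refractory = refractory_ms / 1000))
  }
  iv <- runsToIntervals(excess)
  amp_sig <- switch(polarity, both = abs(x), positive = x, negative = -x)
  peaks <- vapply(seq_len(nrow(iv)), function(i) {
    idx <- iv[i, "onset"]:(iv[i, "offset"] - 1L)
    idx[which.max(amp_sig[idx])]
  }, integer(1))
  ## refractory collapse: keep the larger extremum of any pair closer
  ## than the refractory period
  refr <- refractory_ms / 1000 * trace@sampling_rate
  keep <- collapseRefractory(peaks, amp_sig[peaks], refr)
  times <- trace@t0 + (keep - 1L) / trace@sampling_rate
  methods::new("SpikeTrain", times = times, threshold = thr,
               refractory = refractory_ms / 1000)
}

collapseRefractory <- function(peaks, amps, refr_samples) {
  repeat {
    if (length(peaks) <= 1L) break
    gaps <- diff(peaks)
    close_i <- which(gaps < refr_samples)
    if (!length(close_i)) break
    i <- close_i[1L]
    drop <- if (amps[i] >= amps[i + 1L]) i + 1L else i
    peaks <- peaks[-drop]
    amps <- amps[-drop]
  }
  peaks
}

#' Count spikes in the response window
#'
#' Counts spikes with time in the half-open window `[0.2, 0.7)` s after
#' stimulus contact (the conventional window that avoids the contact
#' artifact at the start of the recording); the rate is the count divided
#' by the window length.
#'
#' @param spikes a [SpikeTrain-class].
#' @param window half-open window `c(start, end)` in seconds
#'   (default `c(0.2, 0.7)`).
#' @param stimulus optional stimulus label carried into the result.
#' @return data.frame with `count`, `rate` (spikes/s), `window_start`,
#'   `window_end`, `stimulus`.
#' @export
countWindow <- function(spikes, window = c(0.2, 0.7), stimulus = NA_character_) {
  stopifnot(methods::is(spikes, "SpikeTrain"))
  t <- spikes@times
  n <- sum(t >= window[1] & t < window[2])
  data.frame(count = as.integer(n), rate = n / (window[2] - window[1]),
             window_start = window[1], window_end = window[2],
             stimulus = stimulus, stringsAsFactors = FALSE)
}

#' Quantify a tip recording end to end
#'
#' Bandpass filter, spike detection and windowed counting in one call.
#'
#' @param trace a raw [VoltageTrace-class].
#' @inheritParams bandpassFilter
#' @inheritParams detectSpikes
#' @inheritParams countWindow
#' @return list: `filtered` trace, `spikes`, `count` (as [countWindow()]).
#' @export
quantifySensillum <- function(trace, low = 100, high = 1000, k_mad = 4,
                              refractory_ms = 1, window = c(0.2, 0.7),
                              stimulus = NA_character_) {
  filt <- bandpassFilter(trace, low, high)
  sp <- detectSpikes(filt, k_mad = k_mad, refractory_ms = refractory_ms)
  list(filtered = filt, spikes = sp,
       count = countWindow(sp, window, stimulus))
}
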