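## Synthetic tip-recording traces: inhomogeneous-Poisson spikes from
## biphasic templates, contact artifact, and noise.

#' Describe a synthetic tip-recording scenario
#'
#' Emulates a sensillum tip recording sampled at 10 kHz: spike times from
#' an (in)homogeneous Poisson process with an absolute refractory period,
#' convolved with millisecond-scale biphasic templates of two amplitudes
#' (mimicking multiple GRNs firing in the same sensillum — counted, never
#' sorted), a slow contact artifact in the first 100 ms, and additive
#' Gaussian noise.
#'
#' @param duration_s trace duration after contact (default 2 s).
#' @param sampling_rate Hz (default 10000).
#' @param rate firing rate profile: a single number (Hz), or a function of
#'   time `lambda(t)` in Hz.
#' @param template_amps peak amplitudes of the spike templates (trace
#'   units); one is drawn per spike.
#' @param refractory_s absolute refractory period between ground-truth
#'   spikes (default 3 ms).
#' @param noise_sd additive Gaussian noise SD. The SNR is
#'   `min(template_amps) / noise_sd`.
#' @param artifact_amp amplitude of the damped 30 Hz contact artifact in
#'   the first 100 ms (0 disables it).
#' @return list of class `ephys_scenario`.
#' @export
ephysScenario <- function(duration_s = 2, sampling_rate = 10000,
                          rate = 40, template_amps = c(1, 0.7),
                          refractory_s = 0.003, noise_sd = 0.1,
                          artifact_amp = 2) {
  stopifnot(duration_s > 0, sampling_rate > 0)
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 rate = rate, template_amps = template_amps,
                 refractory_s = refractory_s, noise_sd = noise_sd,
                 artifact_amp = artifact_amp),
            class = "ephys_scenario")
}

#' Biphasic spike template
#'
#' A ~1.7 ms biphasic waveform — one cycle of a 600 Hz oscillation under a
#' decaying envelope (dominant positive lobe, smaller negative rebound) —
#' with unit peak amplitude. Its energy lies inside the 100–1000 Hz
#' recording band, so bandpass filtering preserves the waveform and its
#' extremum time.
#'
#' @param sampling_rate Hz.
#' @return numeric template vector.
#' @export
spikeTemplate <- function(sampling_rate = 10000) {
  f0 <- 600
  t <- seq(0, 1 / f0, by = 1 / sampling_rate)
  w <- sin(2 * pi * f0 * t) * sin(pi * f0 * t)^2 * exp(-t / 6e-4)
  w / max(abs(w))
}

#' Generate a synthetic voltage trace with ground-truth spike times
#'
#' Spike times are drawn by Poisson thinning of the rate profile on
#' `[0, duration_s)` with an absolute refractory period, each spike adds a
#' randomly chosen template, the contact artifact is added over the first
#' 100 ms, and Gaussian noise on top. Deterministic given `seed`.
#'
#' @param scenario an [ephysScenario()].
#' @param seed integer seed.
#' @return list: `trace` ([VoltageTrace-class], `t0 = 0` at contact),
#'   `spike_times` (ground truth, s), `spike_amps`.
#' @export
generateTrace <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "ephys_scenario"))
  sc <- scenario
  withSeed(seed, {
    fs <- sc$sampling_rate
    n <- round(sc$duration_s * fs)
    lambda <- if (is.function(sc$rate)) sc$rate else function(t)
      rep(sc$rate, length(t))
    lam_max <- max(lambda(seq(0, sc$duration_s, length.out = 1000)))
    times <- numeric(0)
    if (lam_max > 0) {
      t <- 0
      last <- -Inf
      while (TRUE) {
        t <- t + stats::rexp(1, lam_max)
        if (t >= sc$duration_s) break
        if (runif(1) <= lambda(t) / lam_max && t - last >= sc$refractory_s) {
          times <- c(times, t)
          last <- t
        }
      }
    }
    tmpl <- spikeTemplate(fs)
    x <- numeric(n)
    amps <- if (length(times))
      sample(sc$template_amps, length(times), replace = TRUE) else numeric(0)
    ## place templates so the waveform extremum falls at the ground-truth
    ## spike time (detectors report the extremum)
    peak_off <- which.max(abs(tmpl)) - 1L
    for (k in seq_along(times)) {
      i0 <- round(times[k] * fs) + 1L - peak_off
      idx <- max(1L, i0):min(n, i0 + length(tmpl) - 1L)
      x[idx] <- x[idx] + amps[k] * tmpl[idx - i0 + 1L]
    }
    if (sc$artifact_amp > 0) {
      na <- min(n, round(0.1 * fs))
      ta <- (seq_len(na) - 1) / fs
      x[seq_len(na)] <- x[seq_len(na)] +
        sc$artifact_amp * sin(2 * pi * 30 * ta) * exp(-ta / 0.03)
    }
    if (sc$noise_sd > 0) x <- x + rnorm(n, 0, sc$noise_sd)
    list(trace = VoltageTrace(x, sampling_rate = fs, t0 = 0),
         spike_times = times, spike_amps = amps)
  })
}
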