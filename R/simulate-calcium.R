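## Synthetic multi-plane calcium movies with programmed transients,
## rigid shifts and noise.

#' Describe a synthetic calcium-imaging scenario
#'
#' Emulates volumetric two-photon acquisition: 5 optical planes scanned
#' every 500 ms, trials of `frames_per_trial` volumes with stimulus onset
#' at frame 11 of each trial, a Gaussian fluorescent blob whose intensity
#' follows `F0 * (1 + amplitude * kernel(t))`, a rigid-shift schedule and
#' additive Gaussian noise.
#'
#' @param stimuli stimulus labels.
#' @param trials_per_stimulus trials per stimulus (default 3).
#' @param frames_per_trial volumes per trial (default 25).
#' @param planes,rows,cols volume shape (default 5 x 48 x 48).
#' @param volume_period seconds per volume (default 0.5).
#' @param pixel_size micrometers per pixel (default 1).
#' @param amplitude named per-stimulus transient amplitude (peak dF/F);
#'   recycled over stimuli when unnamed.
#' @param kernel_rise,kernel_decay calcium-indicator kernel time constants
#'   in seconds (defaults 0.2 and 1.5, a slow-indicator regime).
#' @param f0 baseline blob brightness (image units in \[0, 1\]).
#' @param blob_center,blob_sigma_px blob position (row, col) and width.
#' @param plane_weights per-plane blob weight (default Gaussian across
#'   planes, so depth shifts are detectable).
#' @param shift_schedule `"none"`, `"random"` (per-volume integer shifts
#'   within `shift_max`), or an explicit `n x 3` matrix `(dx, dy, dz)`.
#' @param shift_max bounds `c(dx, dy, dz)` for random shifts (default
#'   `c(3, 3, 1)`, inside the default registration search range).
#' @param noise_sd additive Gaussian noise SD (image units). The blob SNR
#'   is `f0 / noise_sd`.
#' @return list of class `calcium_scenario`.
#' @export
calciumScenario <- function(stimuli = c("EBR", "BNZ", "sucrose"),
                            trials_per_stimulus = 3,
                            frames_per_trial = 25,
                            planes = 5, rows = 48, cols = 48,
                            volume_period = 0.5, pixel_size = 1,
                            amplitude = 0.5,
                            kernel_rise = 0.2, kernel_decay = 1.5,
                            f0 = 0.4, blob_center = NULL,
                            blob_sigma_px = 6, plane_weights = NULL,
                            shift_schedule = "none",
                            shift_max = c(3, 3, 1),
                            noise_sd = 0) {
  if (is.null(names(amplitude)))
    amplitude <- setNames(rep(amplitude, length.out = length(stimuli)),
                          stimuli)
  stopifnot(all(amplitude >= 0))
  if (is.null(blob_center)) blob_center <- c(rows / 2, cols / 2)
  if (blob_center[1] < 1 || blob_center[1] > rows ||
      blob_center[2] < 1 || blob_center[2] > cols)
    stop("blob center outside the field of view")
  if (is.null(plane_weights)) {
    z <- seq_len(planes)
    plane_weights <- exp(-((z - (planes + 1) / 2)^2) / (2 * 1.2^2))
  }
  structure(list(stimuli = stimuli,
                 trials_per_stimulus = trials_per_stimulus,
                 frames_per_trial = frames_per_trial, planes = planes,
                 rows = rows, cols = cols, volume_period = volume_period,
                 pixel_size = pixel_size, amplitude = amplitude,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 f0 = f0, blob_center = blob_center,
                 blob_sigma_px = blob_sigma_px,
                 plane_weights = plane_weights,
                 shift_schedule = shift_schedule, shift_max = shift_max,
                 noise_sd = noise_sd),
            class = "calcium_scenario")
}

#' Calcium-indicator response kernel
#'
#' `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)` for `t >= 0`, scaled so its
#' continuous-time maximum is 1; 0 for `t < 0`. With the scaling, a
#' transient of amplitude `a` peaks at dF/F = `a`.
#'
#' @param t time since stimulus onset (s); vectorized.
#' @param rise,decay time constants (s).
#' @return kernel values.
#' @export
calciumKernel <- function(t, rise = 0.2, decay = 1.5) {
  tmax <- rise * log(1 + decay / rise)
  kmax <- (1 - exp(-tmax / rise)) * exp(-tmax / decay)
  ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay) / kmax)
}

#' Generate a synthetic calcium movie with ground truth
#'
#' Builds a trial-organized [MovieStack-class]: a Gaussian blob on zero
#' background scales multiplicatively with `1 + a * k(t)` from stimulus
#' onset (frame 11 of each trial), rigid shifts are applied per schedule,
#' then Gaussian noise is added (clamped to non-negative). Deterministic
#' given `seed`.
#'
#' Because every blob pixel scales by the same factor and the background
#' is zero, the ROI-mean dF/F equals `a * k(t)` exactly in the noiseless,
#' shift-free case — the closed form used by the pipeline tests.
#'
#' @param scenario a [calciumScenario()].
#' @param seed integer seed.
#' @return list: `movie` ([MovieStack-class]), `trials` (data.frame
#'   `trial`, `stimulus`, `amplitude`, `onset_frame` global 1-based),
#'   `shifts` (planted per-volume `dx`, `dy`, `dz`), `roi` (ground-truth
#'   blob bounding box usable with [roiTrace()]), `kernel` (the sampled
#'   within-trial kernel values).
#' @export
generateMovie <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "calcium_scenario"))
  sc <- scenario
  withSeed(seed, {
    stim <- rep(sc$stimuli, each = sc$trials_per_stimulus)
    ntr <- length(stim)
    fpt <- sc$frames_per_trial
    nt <- ntr * fpt
    ## within-trial kernel sampled at volume times; onset at frame 11
    tt <- ((seq_len(fpt)) - STIM_ONSET_FRAME) * sc$volume_period
    kern <- calciumKernel(tt, sc$kernel_rise, sc$kernel_decay)
    ## blob image (planes x rows x cols), zero background
    rr <- matrix(seq_len(sc$rows), sc$rows, sc$cols)
    cc <- matrix(seq_len(sc$cols), sc$rows, sc$cols, byrow = TRUE)
    g2 <- exp(-((rr - sc$blob_center[1])^2 + (cc - sc$blob_center[2])^2) /
                (2 * sc$blob_sigma_px^2))
    g2[g2 < 0.05] <- 0  # compact support so shifts keep the blob intact
    blob <- array(0, c(sc$planes, sc$rows, sc$cols))
    for (p in seq_len(sc$planes)) blob[p, , ] <- sc$plane_weights[p] * g2
    blob <- blob * sc$f0
    ## shift schedule
    if (is.matrix(sc$shift_schedule)) {
      shifts <- sc$shift_schedule
      stopifnot(nrow(shifts) == nt, ncol(shifts) == 3L)
    } else if (identical(sc$shift_schedule, "random")) {
      shifts <- cbind(dx = sample(-sc$shift_max[1]:sc$shift_max[1], nt, TRUE),
                      dy = sample(-sc$shift_max[2]:sc$shift_max[2], nt, TRUE),
                      dz = sample(-sc$shift_max[3]:sc$shift_max[3], nt, TRUE))
    } else {
      shifts <- matrix(0L, nt, 3L, dimnames = list(NULL, c("dx", "dy", "dz")))
    }
    colnames(shifts) <- c("dx", "dy", "dz")
    dat <- array(0, c(nt, sc$planes, sc$rows, sc$cols))
    amp <- sc$amplitude[stim]
    for (t in seq_len(nt)) {
      tr_i <- (t - 1L) %/% fpt + 1L
      f_in <- t - (tr_i - 1L) * fpt
      vol <- blob * (1 + amp[tr_i] * kern[f_in])
      s <- shifts[t, ]
      if (any(s != 0))
        vol <- shiftVolume(vol, c(s[["dz"]], s[["dy"]], s[["dx"]]), fill = 0)
      dat[t, , , ] <- vol
    }
    if (sc$noise_sd > 0)
      dat[] <- pmax(0, dat + rnorm(length(dat), 0, sc$noise_sd))
    movie <- MovieStack(dat, volume_period = sc$volume_period,
                        pixel_size = sc$pixel_size, trial_frames = fpt)
    ## ground-truth ROI: blob support bounding box, all planes
    nz <- which(g2 > 0, arr.ind = TRUE)
    roi <- list(rows = min(nz[, 1]):max(nz[, 1]),
                cols = min(nz[, 2]):max(nz[, 2]),
                planes = seq_len(sc$planes))
    trials_df <- data.frame(trial = seq_len(ntr), stimulus = stim,
                            amplitude = unname(amp),
                            onset_frame = (seq_len(ntr) - 1L) * fpt +
                              STIM_ONSET_FRAME,
                            stringsAsFactors = FALSE)
    list(movie = movie, trials = trials_df,
         shifts = as.data.frame(shifts), roi = roi, kernel = kern)
  })
}
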