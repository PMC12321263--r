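## Rigid 3-D registration, ROI extraction, dF/F and peak quantification
## for multi-plane calcium movies.

#' Translate a volume by an integer 3-D shift
#'
#' Returns the volume `v'` with `v'(x) = v(x - s)` for
#' `s = (dz, dy, dx)` (planes, rows, cols); vacated voxels take `fill`.
#'
#' @param vol 3-D array `(plane, row, col)`.
#' @param shift integer vector `c(dz, dy, dx)`.
#' @param fill fill value for vacated voxels (default `NA`).
#' @return shifted array, same shape.
#' @export
shiftVolume <- function(vol, shift, fill = NA_real_) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- shift[k]
    dst_lo <- max(1L, 1L + s); dst_hi <- min(d[k], d[k] + s)
    if (dst_lo > dst_hi) return(out)
    dst[[k]] <- dst_lo:dst_hi
    src[[k]] <- (dst_lo - s):(dst_hi - s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

## Pearson correlation between vol (shifted by s) and ref over the overlap;
## NA when the overlap is below min_overlap of the volume or degenerate.
shiftCorrelation <- function(vol, ref, s, min_overlap) {
  d <- dim(vol)
  idx_v <- idx_r <- vector("list", 3L)
  nvox <- 1
  for (k in 1:3) {
    lo <- max(1L, 1L + s[k]); hi <- min(d[k], d[k] + s[k])
    if (lo > hi) return(NA_real_)
    idx_r[[k]] <- lo:hi
    idx_v[[k]] <- (lo - s[k]):(hi - s[k])
    nvox <- nvox * (hi - lo + 1L)
  }
  if (nvox < min_overlap * prod(d)) return(NA_real_)
  a <- as.vector(vol[idx_v[[1]], idx_v[[2]], idx_v[[3]]])
  b <- as.vector(ref[idx_r[[1]], idx_r[[2]], idx_r[[3]]])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Register a multi-plane movie by correlation maximization
#'
#' For every time point, finds the integer 3-D shift (x, y and depth)
#' maximizing the Pearson correlation between the shifted volume and the
#' reference over their overlap, then applies the correction (vacated
#' voxels become `NA`). Ties break toward the smallest shift magnitude,
#' then lexicographically in `(dz, dy, dx)`. Candidate shifts whose
#' overlap with the reference falls below `min_overlap` are skipped; a
#' frame where all candidates are skipped is an error.
#'
#' @param movie a [MovieStack-class].
#' @param reference reference volume `(plane, row, col)`; default is the
#'   mean volume of the first trial (or of the whole stack when the movie
#'   carries no trial organization).
#' @param search integer search half-widths `c(dx, dy, dz)` in pixels /
#'   planes (default `c(10, 10, 2)`).
#' @param min_overlap minimal overlap fraction (default 0.5).
#' @return list: `movie` (registered [MovieStack-class]) and `shifts`
#'   (data.frame `dx`, `dy`, `dz`, `correlation`, one row per volume).
#' @export
registerStack <- function(movie, reference = NULL,
                          search = c(10, 10, 2), min_overlap = 0.5) {
  stopifnot(methods::is(movie, "MovieStack"))
  dat <- movie@data
  nt <- dim(dat)[1L]
  if (is.null(reference)) {
    ref_frames <- if (movie@trial_frames > 0)
      seq_len(min(movie@trial_frames, nt)) else seq_len(nt)
    reference <- apply(dat[ref_frames, , , , drop = FALSE], 2:4, mean)
  }
  ## candidate shifts ordered by magnitude then lexicographically, so the
  ## first maximum encountered is the tie-break winner
  grid <- expand.grid(dz = -search[3]:search[3], dy = -search[2]:search[2],
                      dx = -search[1]:search[1])
  ord <- order(grid$dx^2 + grid$dy^2 + grid$dz^2, grid$dx, grid$dy, grid$dz)
  grid <- grid[ord, ]
  out <- array(NA_real_, dim(dat))
  shifts <- data.frame(dx = integer(nt), dy = integer(nt), dz = integer(nt),
                       correlation = numeric(nt))
  for (t in seq_len(nt)) {
    vol <- array(dat[t, , , ], dim(dat)[2:4])
    best_c <- -Inf; best_s <- NULL
    for (g in seq_len(nrow(grid))) {
      s <- c(grid$dz[g], grid$dy[g], grid$dx[g])
      cc <- shiftCorrelation(vol, reference, s, min_overlap)
      if (!is.na(cc) && cc > best_c + 1e-12) { best_c <- cc; best_s <- s }
    }
    if (is.null(best_s))
      stop("registration failed at volume ", t,
           ": no candidate shift with sufficient overlap")
    out[t, , , ] <- shiftVolume(vol, best_s)
    shifts$dz[t] <- best_s[1]; shifts$dy[t] <- best_s[2]
    shifts$dx[t] <- best_s[3]; shifts$correlation[t] <- best_c
  }
  reg <- movie
  reg@data <- out
  list(movie = reg, shifts = shifts)
}

#' Define a rectangular ROI
#'
#' Rectangle in pixels or micrometers (converted with the movie's
#' `pixel_size`), spanning one or more optical planes. Typical rectangles
#' are 80x60 um for Gr5a GRN axons and 60x40 um for Gr66a.
#'
#' @param movie a [MovieStack-class] (for bounds and pixel size).
#' @param center_row,center_col ROI center (pixels).
#' @param height,width rectangle size, in `units`.
#' @param planes plane indices spanned (default all).
#' @param units `"px"` or `"um"`; micrometers require `pixel_size` in the
#'   movie metadata.
#' @return list with `rows`, `cols`, `planes` index vectors.
#' @export
makeRoi <- function(movie, center_row, center_col, height, width,
                    planes = NULL, units = c("px", "um")) {
  units <- match.arg(units)
  d <- dim(movie@data)
  if (units == "um") {
    if (is.na(movie@pixel_size))
      stop("ROI given in micrometers but movie has no pixel_size")
    height <- height / movie@pixel_size
    width <- width / movie@pixel_size
  }
  hh <- max(1L, round(height / 2)); hw <- max(1L, round(width / 2))
  rows <- (center_row - hh):(center_row + hh)
  cols <- (center_col - hw):(center_col + hw)
  if (is.null(planes)) planes <- seq_len(d[2])
  if (min(rows) < 1L || max(rows) > d[3] || min(cols) < 1L ||
      max(cols) > d[4] || min(planes) < 1L || max(planes) > d[2])
    stop("ROI extends outside the image bounds")
  list(rows = rows, cols = cols, planes = planes)
}

#' Mean ROI intensity per time frame
#'
#' Averages pixel intensity over the ROI rectangle and its plane span for
#' each volume (planes are averaged, not max-projected). `NA` voxels from
#' registration edge fill are excluded from the mean.
#'
#' @param movie a [MovieStack-class].
#' @param roi ROI from [makeRoi()] (or a list with `rows`, `cols`,
#'   `planes`).
#' @return numeric vector, one mean per volume.
#' @export
roiTrace <- function(movie, roi) {
  stopifnot(methods::is(movie, "MovieStack"))
  d <- dim(movie@data)
  if (min(roi$rows) < 1L || max(roi$rows) > d[3] || min(roi$cols) < 1L ||
      max(roi$cols) > d[4] || min(roi$planes) < 1L || max(roi$planes) > d[2])
    stop("ROI extends outside the image bounds")
  sub <- movie@data[, roi$planes, roi$rows, roi$cols, drop = FALSE]
  apply(sub, 1L, mean, na.rm = TRUE)
}

#' Fractional fluorescence change (dF/F)
#'
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean of the `baseline_len`
#' frames immediately preceding the stimulus onset frame (frames
#' `onset - baseline_len` to `onset - 1`). Frame numbering is 1-based and
#' matches acquisition frames: stimulation begins at frame 11, so the
#' default baseline is frames 6–10.
#'
#' @param trace ROI intensity per frame ([roiTrace()]).
#' @param stimulus_onset_frame 1-based onset frame (default 11).
#' @param baseline_len number of baseline frames (default 5).
#' @return numeric dF/F vector with attributes `f0`, `stimulus_onset_frame`
#'   and `baseline_frames`.
#' @export
dff <- function(trace, stimulus_onset_frame = STIM_ONSET_FRAME,
                baseline_len = BASELINE_LEN) {
  if (stimulus_onset_frame - baseline_len < 1L)
    stop("baseline frames fall before the start of the trace")
  bl <- (stimulus_onset_frame - baseline_len):(stimulus_onset_frame - 1L)
  f0 <- mean(trace[bl])
  if (!is.finite(f0) || f0 <= 0)
    stop("degenerate baseline: F0 = ", f0)
  structure((trace - f0) / f0, f0 = f0,
            stimulus_onset_frame = stimulus_onset_frame,
            baseline_frames = bl)
}

#' Peak stimulus response from dF/F traces
#'
#' The per-trial peak is the mean dF/F over the quantification frames
#' (default frames 12–16, the five frames following the frame-11 onset);
#' per-stimulus values are arithmetic means over that stimulus' trials.
#' An alternative mode centers the 5-frame window on the per-trial dF/F
#' argmax (`mode = "argmax"`) for sensitivity checks; the fixed window is
#' the default.
#'
#' @param dff_traces list of dF/F vectors (one per trial) or a single
#'   vector.
#' @param stimulus character vector of stimulus labels, one per trial.
#' @param quant_frames 1-based frame indices to average (default 12:16).
#' @param mode `"fixed"` (default) or `"argmax"`.
#' @return list: `per_trial` (data.frame `trial`, `stimulus`, `peak`) and
#'   `per_stimulus` (data.frame `stimulus`, `n_trials`, `peak`).
#' @export
peakResponse <- function(dff_traces, stimulus = NULL,
                         quant_frames = QUANT_FRAMES,
                         mode = c("fixed", "argmax")) {
  mode <- match.arg(mode)
  if (!is.list(dff_traces)) dff_traces <- list(dff_traces)
  nt <- length(dff_traces)
  if (is.null(stimulus)) stimulus <- rep("stimulus", nt)
  win <- length(quant_frames)
  peaks <- vapply(dff_traces, function(tr) {
    if (max(quant_frames) > length(tr))
      stop("trace shorter than the quantification window")
    if (mode == "fixed") {
      mean(tr[quant_frames])
    } else {
      onset <- attr(tr, "stimulus_onset_frame")
      from <- if (is.null(onset)) 1L else onset
      pk <- from - 1L + which.max(tr[from:length(tr)])
      lo <- max(1L, pk - (win %/% 2))
      hi <- min(length(tr), lo + win - 1L)
      mean(tr[lo:hi])
    }
  }, numeric(1))
  per_trial <- data.frame(trial = seq_len(nt), stimulus = stimulus,
                          peak = peaks, stringsAsFactors = FALSE)
  agg <- lapply(split(per_trial, per_trial$stimulus), function(g)
    data.frame(stimulus = g$stimulus[1], n_trials = nrow(g),
               peak = mean(g$peak), stringsAsFactors = FALSE))
  per_stimulus <- do.call(rbind, agg)
  rownames(per_stimulus) <- NULL
  list(per_trial = per_trial, per_stimulus = per_stimulus)
}

#' Quantify a trial-organized movie end to end
#'
#' Registration (optional), ROI trace extraction, per-trial dF/F and peak
#' responses for a stack laid out as consecutive equal-length trials.
#'
#' @param movie a [MovieStack-class] with `trial_frames > 0`.
#' @param roi ROI from [makeRoi()].
#' @param stimulus stimulus label per trial.
#' @param register run [registerStack()] first (default TRUE).
#' @param ... passed to [registerStack()].
#' @inheritParams peakResponse
#' @inheritParams dff
#' @return as [peakResponse()], plus `dff_traces` and `shifts`.
#' @export
calciumResponses <- function(movie, roi, stimulus, register = TRUE,
                             stimulus_onset_frame = STIM_ONSET_FRAME,
                             baseline_len = BASELINE_LEN,
                             quant_frames = QUANT_FRAMES, ...) {
  stopifnot(methods::is(movie, "MovieStack"), movie@trial_frames > 0)
  shifts <- NULL
  if (register) {
    reg <- registerStack(movie, ...)
    movie <- reg$movie
    shifts <- reg$shifts
  }
  tr <- roiTrace(movie, roi)
  fpt <- movie@trial_frames
  ntr <- length(tr) %/% fpt
  dffs <- lapply(seq_len(ntr), function(i)
    dff(tr[((i - 1L) * fpt + 1L):(i * fpt)], stimulus_onset_frame,
        baseline_len))
  res <- peakResponse(dffs, stimulus = stimulus, quant_frames = quant_frames)
  res$dff_traces <- dffs
  res$shifts <- shifts
  res
}
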