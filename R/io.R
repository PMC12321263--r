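## Readers and writers for external formats. No science in this file.

#' Read a landmark table
#'
#' Reads per-frame landmark coordinates in either of two CSV dialects:
#' the pose-tracking three-row-header dialect (rows `scorer`, `bodyparts`,
#' `coords`, with an index column and `x`/`y`/`likelihood` triplets per
#' body part) or a flat table with columns `<bodypart>_x`, `<bodypart>_y`
#' and optional `<bodypart>_likelihood` (missing likelihood defaults to
#' 1.0). The body-part set must be exactly the six canonical landmarks;
#' anything else is a validation error. Landmark order is normalized to
#' canonical order, never silently trusted from the file.
#'
#' @param path CSV file path.
#' @param fps video frame rate (default 20).
#' @param trials optional trial table ([trialTable()]) or path to a
#'   YAML/JSON trial config ([readTrialConfig()]).
#' @param format `"auto"` (default), `"dlc"` (three-row header) or
#'   `"flat"`.
#' @return a [LandmarkSession-class].
#' @export
readLandmarkTable <- function(path, fps = 20, trials = NULL,
                              format = c("auto", "dlc", "flat")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (startsWith(first, "scorer")) "dlc" else "flat"
  }
  if (format == "dlc") {
    hdr <- readLines(path, n = 3L)
    keys <- vapply(strsplit(hdr, ","), `[[`, character(1), 1L)
    expect <- c("scorer", "bodyparts", "coords")
    bad <- which(keys != expect)
    if (length(bad))
      stop("malformed header: row ", bad[1L], " should start with '",
           expect[bad[1L]], "' but starts with '", keys[bad[1L]], "'")
    parts <- strsplit(hdr[2L], ",")[[1L]][-1L]
    coords_k <- strsplit(hdr[3L], ",")[[1L]][-1L]
    dat <- read.csv(path, skip = 3L, header = FALSE)
    if (ncol(dat) != length(parts) + 1L)
      stop("malformed header: data has ", ncol(dat) - 1L,
           " value columns but the bodyparts row names ", length(parts))
    dat <- dat[, -1L, drop = FALSE]  # frame-index column
    cols <- data.frame(part = parts, coord = coords_k,
                       stringsAsFactors = FALSE)
  } else {
    dat <- read.csv(path)
    nm <- names(dat)
    m <- regmatches(nm, regexec("^(.*)_(x|y|likelihood)$", nm))
    ok <- lengths(m) == 3L
    if (!any(ok))
      stop("malformed header: no '<bodypart>_x/_y/_likelihood' columns")
    dat <- dat[, ok, drop = FALSE]
    cols <- data.frame(part = vapply(m[ok], `[[`, character(1), 2L),
                       coord = vapply(m[ok], `[[`, character(1), 3L),
                       stringsAsFactors = FALSE)
  }
  found <- unique(cols$part)
  if (!setequal(found, LANDMARK_NAMES))
    stop("body-part set mismatch; expected exactly {",
         paste(LANDMARK_NAMES, collapse = ", "), "} but found {",
         paste(found, collapse = ", "), "}")
  nf <- nrow(dat)
  arr <- array(NA_real_, c(nf, 6L, 3L),
               dimnames = list(NULL, LANDMARK_NAMES,
                               c("x", "y", "likelihood")))
  for (l in LANDMARK_NAMES) {
    for (k in c("x", "y", "likelihood")) {
      j <- which(cols$part == l & cols$coord == k)
      if (length(j) == 1L) {
        arr[, l, k] <- as.numeric(dat[[j]])
      } else if (k == "likelihood") {
        arr[, l, k] <- 1.0
      } else {
        stop("missing ", k, " column for body part ", l)
      }
    }
  }
  if (!is.null(trials) && is.character(trials))
    trials <- readTrialConfig(trials)
  if (is.null(trials)) trials <- emptyTrialTable()
  methods::new("LandmarkSession", coords = arr, fps = fps, trials = trials)
}

#' Write a landmark table
#'
#' Inverse of [readLandmarkTable()]; round trips are lossless to full
#' double precision in the flat dialect and to the printed precision
#' (15 significant digits) in both.
#'
#' @param session a [LandmarkSession-class].
#' @param path output CSV path.
#' @param format `"dlc"` (three-row header, default) or `"flat"`.
#' @param scorer scorer name for the dialect's first header row.
#' @return `path`, invisibly.
#' @export
writeLandmarkTable <- function(session, path, format = c("dlc", "flat"),
                               scorer = "perflex") {
  format <- match.arg(format)
  arr <- session@coords
  nf <- dim(arr)[1L]
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  if (format == "dlc") {
    ncols <- 6L * 3L
    lines <- c(
      paste(c("scorer", rep(scorer, ncols)), collapse = ","),
      paste(c("bodyparts", rep(LANDMARK_NAMES, each = 3L)), collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), 6L)), collapse = ",")
    )
    block <- do.call(cbind, lapply(LANDMARK_NAMES, function(l)
      cbind(arr[, l, 1L], arr[, l, 2L], arr[, l, 3L])))
    rows <- apply(block, 1L, function(r) paste(fmt(r), collapse = ","))
    lines <- c(lines, paste(seq_len(nf) - 1L, rows, sep = ","))
    writeLines(lines, path)
  } else {
    out <- list()
    for (l in LANDMARK_NAMES) {
      out[[paste0(l, "_x")]] <- arr[, l, 1L]
      out[[paste0(l, "_y")]] <- arr[, l, 2L]
      out[[paste0(l, "_likelihood")]] <- arr[, l, 3L]
    }
    write.csv(as.data.frame(out), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a trial config (YAML or JSON)
#'
#' Trial metadata is supplied as a structured config rather than parsed
#' from filenames. Accepted shapes: a list with `stimulus_id` (vector) and
#' optional `valve_open_time`, `stimulus_duration`, `iti_s`, `start_s`,
#' `block`; or a list of per-trial records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a trial table ([trialTable()]).
#' @export
readTrialConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$stimulus_id)) {
    trialTable(
      stimulus_id = unlist(cfg$stimulus_id),
      valve_open_time = if (!is.null(cfg$valve_open_time))
        unlist(cfg$valve_open_time) else NULL,
      stimulus_duration = cfg$stimulus_duration %||% 2,
      iti_s = cfg$iti_s %||% 15,
      block = if (!is.null(cfg$block)) unlist(cfg$block) else NULL,
      start_s = cfg$start_s %||% 5
    )
  } else if (is.data.frame(cfg) || (is.list(cfg) && length(cfg) &&
                                    is.list(cfg[[1L]]))) {
    recs <- if (is.data.frame(cfg)) cfg else
      do.call(rbind, lapply(cfg, as.data.frame))
    trialTable(stimulus_id = recs$stimulus_id,
               valve_open_time = recs$valve_open_time,
               stimulus_duration = recs$stimulus_duration %||% 2,
               block = recs$block)
  } else {
    stop("unrecognized trial config structure in ", path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial config as YAML
#' @param trials a trial table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrialConfig <- function(trials, path) {
  yaml::write_yaml(list(stimulus_id = trials$stimulus_id,
                        valve_open_time = trials$valve_open_time,
                        stimulus_duration = trials$stimulus_duration[1],
                        block = trials$block), path)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Pages must be ordered time-major, plane-minor; the page count must be
#' divisible by the plane count.
#'
#' @param path TIFF path.
#' @param planes optical planes per volume (default 5).
#' @param volume_period seconds per volume (default 0.5).
#' @param pixel_size micrometers per pixel (`NA` if unknown).
#' @param trial_frames volumes per trial (0 if not trial-organized).
#' @return a [MovieStack-class].
#' @export
readMovie <- function(path, planes = 5, volume_period = 0.5,
                      pixel_size = NA_real_, trial_frames = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% planes != 0L)
    stop("shape error: ", np, " pages not divisible by ", planes, " planes")
  nt <- np %/% planes
  d <- dim(pages[[1L]])
  dat <- array(0, c(nt, planes, d[1L], d[2L]))
  for (t in seq_len(nt)) {
    for (p in seq_len(planes)) {
      dat[t, p, , ] <- pages[[(t - 1L) * planes + p]]
    }
  }
  MovieStack(dat, volume_period = volume_period, pixel_size = pixel_size,
             trial_frames = trial_frames)
}

#' Write a movie as a multi-page TIFF
#'
#' Pages are written time-major, plane-minor as 32-bit float samples;
#' intensities must lie in \[0, 1\] (the TIFF writer's range).
#'
#' @param movie a [MovieStack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path) {
  dat <- movie@data
  if (anyNA(dat)) stop("cannot write a movie containing NA (edge fill)")
  if (max(dat) > 1 || min(dat) < 0)
    stop("intensities must lie in [0, 1] for TIFF output")
  d <- dim(dat)
  pages <- vector("list", d[1L] * d[2L])
  for (t in seq_len(d[1L])) {
    for (p in seq_len(d[2L])) {
      pages[[(t - 1L) * d[2L] + p]] <- matrix(dat[t, p, , ], d[3L], d[4L])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a voltage trace from CSV
#'
#' Single-column CSV (column `voltage`); an optional leading comment line
#' `# sampling_rate_hz: <value>` carries the rate, otherwise the
#' `sampling_rate` argument applies.
#'
#' @param path CSV path.
#' @param sampling_rate Hz, used when the file carries no rate comment.
#' @param t0 time of the first sample relative to stimulus contact (s).
#' @return a [VoltageTrace-class].
#' @export
readTrace <- function(path, sampling_rate = 10000, t0 = 0) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("sampling_rate_hz:\\s*([0-9.eE+-]+)",
                                   first))[[1L]]
    if (length(m) == 2L) sampling_rate <- as.numeric(m[2L])
    skip <- 1L
  }
  dat <- read.csv(path, skip = skip)
  VoltageTrace(as.numeric(dat[[1L]]), sampling_rate = sampling_rate, t0 = t0)
}

#' Write a voltage trace to CSV
#' @param trace a [VoltageTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sampling_rate_hz: ", trace@sampling_rate), con)
  writeLines("voltage", con)
  writeLines(formatC(trace@samples, format = "g", digits = 15), con)
  invisible(path)
}

#' Write per-fly metrics as a tidy long table
#'
#' One row per fly x stimulus x measure (measures: `per_probability`,
#' `mean_integrated_duration`, `mean_latency`), in CSV.
#'
#' @param metrics the [flyMetrics()] result, or a named list of results
#'   (names = fly identifiers).
#' @param path output CSV path.
#' @param fly fly identifier used when a single result is given.
#' @return the long-format data.frame, invisibly.
#' @export
writeMetricsTable <- function(metrics, path, fly = "fly1") {
  if (!is.null(metrics$per_stimulus)) metrics <- setNames(list(metrics), fly)
  measures <- c("per_probability", "mean_integrated_duration",
                "mean_latency")
  rows <- list()
  for (f in names(metrics)) {
    ps <- metrics[[f]]$per_stimulus
    for (i in seq_len(NROW(ps))) {
      for (m in measures) {
        rows[[length(rows) + 1L]] <- data.frame(
          fly = f, stimulus_id = ps$stimulus_id[i], measure = m,
          value = ps[[m]][i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fly = character(), stimulus_id = character(),
               measure = character(), value = numeric(),
               stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a tidy metrics table written by [writeMetricsTable()]
#' @param path CSV path.
#' @return data.frame with `fly`, `stimulus_id`, `measure`, `value`.
#' @export
readMetricsTable <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a JSON run manifest
#'
#' Records the seed, package version and free-form parameters of a run for
#' reproducibility.
#'
#' @param path output JSON path.
#' @param seed integer seed used.
#' @param parameters named list of parameters.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, seed, parameters = list()) {
  jsonlite::write_json(
    list(package = "perflex",
         version = as.character(utils::packageVersion("perflex")),
         seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
         parameters = parameters),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
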