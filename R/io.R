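# File formats: traces as two-column CSV (`time_s,<channel>`), stacks as
# single-channel TIFF with a JSON sidecar (pixel size, frame rate,
# intensity scale), ground truth and session reports as JSON.

#' Read a trace from CSV
#'
#' Expects a header `time_s,<channel>`, monotone time stamps and a uniform
#' step (within 1% relative tolerance); the sampling rate is inferred from
#' the median step.
#'
#' @param path CSV file path.
#' @return a [trace_series()] with the channel taken from the header.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "time_s") {
    stop(sprintf("%s: expected header 'time_s,<channel>'", path), call. = FALSE)
  }
  tm <- df[[1]]
  bad <- which(!is.finite(tm) | !is.finite(df[[2]]))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value at data line %d", path, bad[1]), call. = FALSE)
  }
  dt <- diff(tm)
  if (any(dt <= 0)) stop(sprintf("%s: time stamps not monotone", path), call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    stop(sprintf("%s: non-uniform sampling beyond 1%% tolerance", path), call. = FALSE)
  }
  trace_series(df[[2]], rate = 1 / step, channel = names(df)[2], start = tm[1])
}

#' Write a trace to CSV
#'
#' @param trace a [trace_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_series"))
  df <- data.frame(time_s = trace_time(trace), value = trace$values)
  names(df)[2] <- trace$channel
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an image stack as TIFF plus JSON sidecar
#'
#' Frames are written as a multi-page single-channel TIFF. Intensities are
#' scaled into `[0, 1]` by the recorded offset/scale, which is stored with
#' the pixel size and frame rate in `<path>.json` so [read_stack()] can
#' restore the original values.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(n_frames(stack)), function(k) {
    (stack$data[k, , ] - lo) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  meta <- list(pixel_size_um = stack$pixel_size, frame_rate_hz = stack$frame_rate,
               channel = stack$channel, intensity_offset = lo,
               intensity_scale = scale, n_frames = n_frames(stack))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must sit alongside).
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  dat <- array(0, dim = c(length(frames), d[1], d[2]))
  for (k in seq_along(frames)) {
    dat[k, , ] <- frames[[k]] * meta$intensity_scale + meta$intensity_offset
  }
  image_stack(dat, pixel_size = meta$pixel_size_um,
              frame_rate = meta$frame_rate_hz, channel = meta$channel)
}

#' Write a ground-truth record as JSON
#'
#' @param ground_truth the `ground_truth` element returned by a generator.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Run a full session analysis
#'
#' Executes the stage chain appropriate to the supplied inputs: an image
#' stack runs the vessel pipeline and event detection on the diameter
#' series; a fluorescence trace (or pair) runs percent normalization,
#' spectra, PR and (for a pair) cross-correlation phase; an eye trace runs
#' the HOKR chain. Absent inputs are flagged `"not run"`.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized entries: `stack` (TIFF path) with `rois` (left/right/vessel
#'   row+col ranges and `line_rows`); `trace` and `trace2` (CSV paths);
#'   `eye` (CSV path); `stimulus` (`temporal_frequency`, `cycle`); `f0`,
#'   `band`, `pr_threshold`; `seed`; `out_dir`.
#' @return list of class `session_report`; written to `out_dir` as JSON
#'   when `out_dir` is set.
#' @export
run_session <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  f0 <- config$f0 %||% 0.25
  band <- config$band %||% c(0.1, 1)
  cycle <- config$stimulus$cycle %||% (1 / f0)
  report <- list(config = config,
                 config_hash = config_hash(config),
                 seed = config$seed %||% NA)

  if (!is.null(config$stack)) {
    stack <- read_stack(config$stack)
    r <- config$rois
    series <- diameter_and_peak_series(
      stack,
      left_roi = pixel_roi(r$left$rows, r$left$cols),
      right_roi = pixel_roi(r$right$rows, r$right$cols),
      vessel_roi = pixel_roi(r$vessel$rows, r$vessel$cols),
      line_rows = r$line_rows
    )
    ev <- detect_events(shift_to_baseline(series$diameter))
    report$vessel <- list(
      basal_diameter_um = series$basal_diameter_um,
      diameter = as.data.frame(series$diameter),
      peak = as.data.frame(series$peak),
      events = as.data.frame(ev),
      event_summary_mean = summarize_events(ev)
    )
  } else {
    report$vessel <- "not run"
  }

  if (!is.null(config$trace)) {
    tr <- normalize_percent(read_trace(config$trace))
    spec <- amplitude_spectrum(tr)
    report$spectral <- list(
      pr = unclass(peak_ratio(spec, f0 = f0, band = band)),
      argmax_hz = spec$frequencies[which.max(spec$amplitudes)]
    )
    if (!is.null(config$trace2)) {
      tr2 <- normalize_percent(read_trace(config$trace2))
      lag <- crosscorr_lag(tr, tr2, max_lag = cycle)
      report$phase <- list(
        delta_t = lag$delta_t, excluded = lag$excluded,
        phase_deg = if (lag$excluded) NA_real_ else phase_from_lag(lag$delta_t, cycle)
      )
    } else {
      report$phase <- "not run"
    }
  } else {
    report$spectral <- "not run"
    report$phase <- "not run"
  }

  if (!is.null(config$eye)) {
    eye <- bandpass_eye(remove_saccades(read_trace(config$eye)))
    seg <- segment_average(eye, cycle = cycle)
    fit <- sine_fit_phase(seg)
    report$hokr <- list(
      amplitude_deg = eye_amplitude(eye, cycle = cycle),
      n_segments = seg$count,
      phase_lag_deg = fit$phase_deg
    )
  } else {
    report$hokr <- "not run"
  }

  class(report) <- "session_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Centre a %-of-basal series (basal = 100) to a 0-baseline % trace.
shift_to_baseline <- function(trace) {
  trace_series(trace$values - 100, trace$rate, channel = trace$channel,
               start = trace$start, units = "%")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  # small stable polynomial hash; enough to fingerprint a config in a report
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a session report to a directory
#'
#' @param report a `session_report` from [run_session()].
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "session_report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
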