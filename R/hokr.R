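# Horizontal optokinetic response (HOKR) eye-movement processing: saccade
# rejection, drift-removing band-pass, cycle-wise amplitude, relative gain
# across a spaced-training schedule, and the gain-vs-PR correlation.

#' Remove saccades from an eye trace
#'
#' Inter-frame steps larger than `step_threshold` (1 degree at 30 fps by
#' default) flag a saccade; the two samples forming the step plus a guard
#' of `guard` frames on each side are removed and the gap is filled by
#' linear interpolation so the trace stays uniformly sampled for
#' filtering. The operation is idempotent: interpolated ramps spread any
#' removed step over several frames, below the detection threshold.
#'
#' @param trace an eye-angle [trace_series()] in degrees.
#' @param step_threshold saccade detection threshold, degrees per frame.
#' @param guard extra frames removed on each side of a flagged step.
#' @return the saccade-free [trace_series()]; indices of removed samples
#'   in `attr(, "removed")`.
#' @export
remove_saccades <- function(trace, step_threshold = 1, guard = 1) {
  stopifnot(inherits(trace, "trace_series"))
  v <- trace$values
  n <- length(v)
  removed <- integer(0)
  # repeat until no supra-threshold step remains: a large step bridged by
  # interpolation over a steep tracking slope can itself exceed the
  # threshold, so one pass is not always enough
  for (pass in 1:20) {
    steps <- which(abs(diff(v)) > step_threshold)
    if (length(steps) == 0) break
    bad <- unique(unlist(lapply(steps, function(i) {
      max(1L, i - guard):min(n, i + 1L + guard)
    })))
    removed <- union(removed, bad)
    keep <- setdiff(seq_len(n), removed)
    if (length(keep) < 2) {
      stop("saccade removal left fewer than 2 samples", call. = FALSE)
    }
    v <- stats::approx(keep, trace$values[keep], xout = seq_len(n), rule = 2)$y
  }
  out <- trace_series(v, trace$rate, channel = trace$channel,
                      start = trace$start, units = trace$units)
  attr(out, "removed") <- sort(removed)
  out
}

#' Band-pass an eye trace to the tracking band
#'
#' Zero-phase band-pass with unity gain across `band` (100-500 mHz by
#' default): the 0.25 Hz tracking component passes untouched while DC
#' offset and slow drift below the lower stop edge are removed entirely.
#'
#' @param trace an eye-angle [trace_series()].
#' @param band two-element passband in Hz.
#' @param stop_lo,stop_hi stopband edges for the raised-cosine transitions.
#' @return the filtered [trace_series()].
#' @export
bandpass_eye <- function(trace, band = c(0.1, 0.5), stop_lo = band[1] / 2,
                         stop_hi = band[2] * 1.2) {
  stopifnot(inherits(trace, "trace_series"))
  if (band[2] >= trace$rate / 2) stop("band outside the Nyquist range", call. = FALSE)
  if (trace_duration(trace) < 3 / band[1]) {
    stop("trace too short for the lower band edge", call. = FALSE)
  }
  v <- cosine_bandpass(trace$values, trace$rate, band[1], band[2],
                       stop_lo = stop_lo, stop_hi = stop_hi)
  trace_series(v, trace$rate, channel = trace$channel, start = trace$start,
               units = trace$units)
}

#' Cycle-wise peak-to-peak eye amplitude
#'
#' Splits the analysis window into stimulus cycles and averages one peak
#' and one trough value per cycle: the peak/trough sample positions are
#' located once on the cycle-averaged template and each cycle is then read
#' out at those fixed positions, so zero-mean noise enters the average
#' unbiased instead of inflating per-cycle extrema. The amplitude is
#' `mean(peaks) - mean(troughs)` in degrees.
#'
#' @param trace a saccade-free, band-passed eye [trace_series()].
#' @param cycle stimulus period, s.
#' @param window analysis window length from the trace start, s (default:
#'   full trace); must cover at least one full cycle.
#' @return amplitude in degrees.
#' @export
eye_amplitude <- function(trace, cycle = 4, window = NULL) {
  stopifnot(inherits(trace, "trace_series"))
  if (is.null(window)) window <- trace_duration(trace)
  if (window < cycle) stop("window shorter than one stimulus cycle", call. = FALSE)
  spc <- round(cycle * trace$rate)
  n_cyc <- floor(round(window * trace$rate) / spc)
  v <- trace$values[seq_len(n_cyc * spc)]
  m <- matrix(v, nrow = spc, ncol = n_cyc)
  template <- rowMeans(m)
  ip <- which.max(template)
  it <- which.min(template)
  mean(m[ip, ]) - mean(m[it, ])
}

#' Spaced-training session schedule
#'
#' The standard spaced HOKR protocol: four 15 min training sessions at 1 h
#' intervals on day 1, then 2 min tests on day 2 and day 5. Eye-movement
#' test windows are the first and last 3 min of each training session
#' (the full 2 min for the day-2/5 tests); fluorescence windows are the
#' first and last 5 min.
#'
#' @return data.frame of class `session_schedule` with one row per test:
#'   `day`, `session`, `phase` ("early"/"late"/"test"), `window_start` and
#'   `window_len` (s, relative to session start), `eye_window_len`,
#'   `fluor_window_len`.
#' @export
session_schedule <- function() {
  train <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(day = 1, session = s, phase = c("early", "late"),
               window_start = c(0, 15 * 60 - 3 * 60),
               window_len = c(3 * 60, 3 * 60),
               fluor_window_start = c(0, 15 * 60 - 5 * 60),
               fluor_window_len = c(5 * 60, 5 * 60))
  }))
  tests <- data.frame(day = c(2, 5), session = c(5, 6), phase = "test",
                      window_start = 0, window_len = 2 * 60,
                      fluor_window_start = 0, fluor_window_len = 2 * 60)
  out <- rbind(train, tests)
  rownames(out) <- NULL
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' HOKR relative gain series
#'
#' Divides each test's eye amplitude by the amplitude of the first test
#' (the start of the first training session), so the first relative gain
#' is 1 by construction. The standard spaced schedule yields 10 tests.
#'
#' @param amplitudes per-test eye amplitudes in degrees, in schedule order.
#' @param schedule optional [session_schedule()] used to label the tests.
#' @return data.frame of class `gain_series` with `amplitude` and
#'   `relative_gain` (plus schedule columns when supplied).
#' @export
relative_gain <- function(amplitudes, schedule = NULL) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1)
  if (!is.finite(amplitudes[1]) || amplitudes[1] <= 0) {
    stop("first test amplitude must be positive", call. = FALSE)
  }
  out <- data.frame(amplitude = amplitudes,
                    relative_gain = amplitudes / amplitudes[1])
  if (!is.null(schedule)) {
    stopifnot(nrow(schedule) == length(amplitudes))
    out <- cbind(schedule[, c("day", "session", "phase")], out)
  }
  class(out) <- c("gain_series", "data.frame")
  out
}

#' Correlate HOKR gain with the entrainment peak ratio
#'
#' Two pairings are supported. `"group-mean"`: gains and PRs are averaged
#' across animals per test, and the per-test means are correlated
#' (Pearson). `"per-animal-day5"`: for each animal, the day-5 gain
#' normalized to the late window of training session 4 is paired with the
#' PR at the end of session 4, and the per-animal pairs are correlated.
#'
#' @param gains animals x tests matrix of relative gains (group-mean mode)
#'   or a per-animal vector of day-5 normalized gains (day-5 mode).
#' @param prs matrix/vector of PR values with the same shape as `gains`.
#' @param mode `"group-mean"` or `"per-animal-day5"`.
#' @return list with `r`, `p`, `n` from `stats::cor.test`.
#' @export
gain_pr_correlation <- function(gains, prs,
                                mode = c("group-mean", "per-animal-day5")) {
  mode <- match.arg(mode)
  if (mode == "group-mean") {
    gains <- as.matrix(gains); prs <- as.matrix(prs)
    stopifnot(all(dim(gains) == dim(prs)))
    gv <- colMeans(gains); pv <- colMeans(prs)
  } else {
    gv <- as.numeric(gains); pv <- as.numeric(prs)
    stopifnot(length(gv) == length(pv))
  }
  if (length(gv) < 3) stop("need at least 3 paired values", call. = FALSE)
  ct <- stats::cor.test(gv, pv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(gv))
}
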