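# Phase estimation: cross-correlation lag between channel pairs with the
# lag-to-degrees conversion, cycle-segment averaging with fixed-frequency
# sine fitting, and the PR > 3 entrained-segment selection rule.

#' Cross-correlation lag of the negative peak near zero
#'
#' Normalized cross-correlation of two equal-rate traces over lags in
#' `[-max_lag, +max_lag]`; the lag of the most negative local minimum is
#' returned as `delta_t`. Ties (within numerical tolerance) are broken
#' toward the smallest `|delta_t|`. When no negative local minimum exists
#' in range the pair is marked excluded.
#'
#' @param a,b [trace_series()] of equal length and rate (percent-normalized
#'   or otherwise mean-free; means are removed internally).
#' @param max_lag lag search half-range in seconds (default one stimulus
#'   cycle, 4 s).
#' @param refine logical: parabolic sub-sample interpolation around the
#'   minimum (off by default; lags are otherwise quantized to the sampling
#'   interval).
#' @return list of class `lag_result` with `delta_t` (s; `NA` when
#'   excluded), `excluded`, `lags`, `correlation`.
#' @export
crosscorr_lag <- function(a, b, max_lag = 4, refine = FALSE) {
  stopifnot(inherits(a, "trace_series"), inherits(b, "trace_series"))
  if (length(a$values) != length(b$values)) {
    stop("traces must have equal length", call. = FALSE)
  }
  if (abs(a$rate - b$rate) > 1e-9) stop("traces must share a rate", call. = FALSE)
  rate <- a$rate
  va <- a$values - mean(a$values)
  vb <- b$values - mean(b$values)
  L <- round(max_lag * rate)
  n <- length(va)
  if (L >= n) stop("`max_lag` too large for the trace length", call. = FALSE)
  lags <- (-L):L
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      stats::cor(va[1:(n - k)], vb[(1 + k):n])
    } else {
      stats::cor(va[(1 - k):n], vb[1:(n + k)])
    }
  }, numeric(1))
  m <- length(r)
  is_min <- c(FALSE, r[2:(m - 1)] <= r[1:(m - 2)] & r[2:(m - 1)] <= r[3:m], FALSE)
  cand <- which(is_min & r < 0)
  if (length(cand) == 0) {
    return(structure(list(delta_t = NA_real_, excluded = TRUE,
                          lags = lags / rate, correlation = r),
                     class = "lag_result"))
  }
  rmin <- min(r[cand])
  tol <- 1e-9 * max(1, abs(rmin))
  best <- cand[r[cand] <= rmin + tol]
  pick <- best[which.min(abs(lags[best]))]
  delta_t <- lags[pick] / rate
  if (refine && pick > 1 && pick < m) {
    y1 <- r[pick - 1]; y2 <- r[pick]; y3 <- r[pick + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps) {
      delta_t <- delta_t + 0.5 * (y1 - y3) / denom / rate
    }
  }
  structure(list(delta_t = delta_t, excluded = FALSE,
                 lags = lags / rate, correlation = r),
            class = "lag_result")
}

#' Convert a cross-correlation lag to a phase in degrees
#'
#' `phase = (delta_t / cycle) * 360 + 180`, wrapped to `[0, 360)`. The
#' +180 accounts for the negative (anti-phase) correlation peak the lag
#' was measured on.
#'
#' @param delta_t lag in seconds (|delta_t| <= cycle).
#' @param cycle stimulus period in seconds (> 0).
#' @return phase in degrees in `[0, 360)`.
#' @export
phase_from_lag <- function(delta_t, cycle) {
  if (cycle <= 0) stop("`cycle` must be > 0", call. = FALSE)
  if (any(abs(delta_t) > cycle, na.rm = TRUE)) {
    stop("|delta_t| must not exceed the cycle", call. = FALSE)
  }
  ((delta_t / cycle) * 360 + 180) %% 360
}

#' Cut a trace into stimulus-cycle segments and average them
#'
#' Segments of one stimulus cycle are cut back-to-back from the start of
#' the analysis window (a 5 min window at the 4 s cycle gives 75
#' segments), and averaged element-wise.
#'
#' @param trace a [trace_series()].
#' @param cycle segment length in seconds; `cycle * rate` must be integral.
#' @param analysis_window length of trace to use from the start, seconds
#'   (defaults to the full trace).
#' @return list of class `segment_set` with `segments`
#'   (samples-per-cycle x count matrix), `count`, `mean_segment`, `cycle`,
#'   `rate`.
#' @export
segment_average <- function(trace, cycle = 4, analysis_window = NULL) {
  stopifnot(inherits(trace, "trace_series"))
  if (is.null(analysis_window)) analysis_window <- trace_duration(trace)
  if (analysis_window > trace_duration(trace) + 1e-9) {
    stop("`analysis_window` exceeds the trace duration", call. = FALSE)
  }
  spc <- cycle * trace$rate
  if (abs(spc - round(spc)) > 1e-8) {
    stop("`cycle` and sampling rate are not commensurate (non-integral samples per cycle)",
         call. = FALSE)
  }
  spc <- as.integer(round(spc))
  n_use <- min(length(trace$values), round(analysis_window * trace$rate))
  count <- as.integer(n_use %/% spc)
  if (count < 1) stop("analysis window shorter than one cycle", call. = FALSE)
  seg <- matrix(trace$values[seq_len(count * spc)], nrow = spc, ncol = count)
  structure(list(segments = seg, count = count, mean_segment = rowMeans(seg),
                 cycle = cycle, rate = trace$rate),
            class = "segment_set")
}

#' Fixed-frequency sine fit of an averaged segment
#'
#' Least-squares fit of `A * sin(2*pi*t/cycle + phi) + c` with the
#' frequency fixed at `1/cycle`; linear in the sin/cos basis, solved in
#' closed form. The phase is reported as the lag behind the reference
#' stimulus sinusoid `sin(2*pi*t/cycle)` in degrees: the stimulus itself
#' fits to 0, a response delayed by 0.1 s at the 4 s cycle fits to +9.
#'
#' @param x a `segment_set` from [segment_average()], or a numeric vector
#'   (one cycle of samples) with `rate` supplied.
#' @param cycle cycle length in seconds (taken from the segment set when
#'   omitted).
#' @param rate sampling rate, Hz (taken from the segment set when omitted).
#' @return list with `amplitude`, `phase_deg` (lag behind the stimulus,
#'   in `(-180, 180]`; `NA` and `flagged = TRUE` on a zero-variance
#'   segment), `offset`.
#' @export
sine_fit_phase <- function(x, cycle = NULL, rate = NULL) {
  if (inherits(x, "segment_set")) {
    y <- x$mean_segment
    if (is.null(cycle)) cycle <- x$cycle
    if (is.null(rate)) rate <- x$rate
  } else {
    y <- as.numeric(x)
    if (is.null(cycle) || is.null(rate)) {
      stop("`cycle` and `rate` required for a plain vector", call. = FALSE)
    }
  }
  if (stats::var(y) < .Machine$double.eps) {
    return(list(amplitude = 0, phase_deg = NA_real_, offset = mean(y),
                flagged = TRUE))
  }
  t <- (seq_along(y) - 1L) / rate
  w <- 2 * pi / cycle
  X <- cbind(sin(w * t), cos(w * t), 1)
  cf <- stats::lm.fit(X, y)$coefficients
  a <- cf[1]; b <- cf[2]
  amplitude <- sqrt(a^2 + b^2)
  phi <- atan2(b, a)                 # y ~ A sin(wt + phi)
  lag_deg <- -phi * 180 / pi         # y ~ A sin(wt - lag)
  lag_deg <- ((lag_deg + 180) %% 360) - 180
  list(amplitude = unname(amplitude), phase_deg = unname(lag_deg),
       offset = unname(cf[3]), flagged = FALSE)
}

#' Select entrained analysis windows by peak ratio
#'
#' Tiles a percent-normalized trace into fixed-length windows, computes
#' the peak ratio of each, and keeps those with PR above the threshold;
#' only the kept windows feed cross-correlation/phase estimation.
#'
#' @param trace a percent-normalized [trace_series()].
#' @param pr_threshold keep windows with PR strictly above this (3 by
#'   default).
#' @param segment_len window length in seconds (40 s by default: ten
#'   stimulus cycles).
#' @param f0,band peak-ratio parameters.
#' @return list of class `entrained_windows` with `windows` (list of
#'   [trace_series()]), `kept` (logical), `prs` (numeric), `start_times`.
#' @export
select_entrained_segments <- function(trace, pr_threshold = 3,
                                      segment_len = 40, f0 = 0.25,
                                      band = c(0.1, 1)) {
  stopifnot(inherits(trace, "trace_series"))
  wn <- round(segment_len * trace$rate)
  n_win <- floor(length(trace$values) / wn)
  if (n_win < 1) stop("trace shorter than one analysis window", call. = FALSE)
  prs <- numeric(n_win)
  wins <- vector("list", n_win)
  starts <- numeric(n_win)
  for (i in seq_len(n_win)) {
    i0 <- (i - 1L) * wn + 1L
    starts[i] <- trace$start + (i0 - 1L) / trace$rate
    wins[[i]] <- trace_series(trace$values[i0:(i0 + wn - 1L)], trace$rate,
                              channel = trace$channel, start = starts[i],
                              units = trace$units)
    prs[i] <- peak_ratio(amplitude_spectrum(wins[[i]]), f0 = f0, band = band)$pr
  }
  kept <- prs > pr_threshold
  structure(list(windows = wins, kept = kept, prs = prs,
                 start_times = starts, segment_len = segment_len,
                 pr_threshold = pr_threshold),
            class = "entrained_windows")
}
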