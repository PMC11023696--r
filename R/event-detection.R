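# Spontaneous vasodilation event detection on a baseline-normalized
# (rest ~ 0 %) diameter or intensity trace, and the three-statistic
# summary: inter-event interval, peak amplitude, half-width.

#' Detect spontaneous dilation events
#'
#' Contiguous supra-threshold excursions become candidate events; runs
#' containing several supra-threshold peaks separated by a deep local
#' minimum (below half of the lower neighbouring peak) are split at that
#' minimum. The half-width is the full width at half of the peak
#' amplitude, with crossings located by linear interpolation. When the
#' rising edge is unresolved at the sampling rate (the sample before the
#' half-maximum crossing is still below the detection threshold), the left
#' crossing is taken at the first supra-half sample: interpolating across
#' an unresolved step would systematically inflate the width by half a
#' sample interval. Events whose half-maximum crossings fall outside the
#' trace are discarded.
#'
#' Detection uses hysteresis: an event opens when the trace crosses the
#' threshold upward and closes only when it falls below
#' `end_frac x threshold`, so noise jitter around the threshold during an
#' event's decay does not fragment it into spurious detections.
#'
#' @param trace a baseline-normalized [trace_series()] in % (rest near 0).
#' @param threshold detection threshold in %, or `"auto"` to use
#'   `k x 1.4826 x MAD` of the trace.
#' @param k multiplier for the automatic threshold.
#' @param end_frac hysteresis: an event region ends when the trace drops
#'   below `end_frac * threshold`.
#' @return data.frame of class `dilation_events` with `onset_time`,
#'   `peak_time`, `peak_amplitude` (%), `half_width` (s); the threshold
#'   used is stored in `attr(, "threshold")`.
#' @export
detect_events <- function(trace, threshold = "auto", k = 3, end_frac = 0.5) {
  stopifnot(inherits(trace, "trace_series"))
  x <- trace$values
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  if (abs(stats::median(x)) > 5) {
    warning("trace baseline is far from 0 %; expected a baseline-normalized trace")
  }
  thr <- if (identical(threshold, "auto")) k * stats::mad(x) else threshold
  t <- trace_time(trace)
  dt <- 1 / trace$rate
  if (!any(x > thr)) return(empty_events(thr))
  runs <- hysteresis_runs(x, thr, end_frac * thr)

  segments <- list()
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    segments <- c(segments, split_overlapping(x, seg))
  }

  out <- lapply(segments, function(seg) {
    ipk <- seg[which.max(x[seg])]
    pk <- x[ipk]
    half <- pk / 2
    n <- length(x)
    # left half-crossing: first passage walking left from the peak
    j <- ipk
    while (j > 1 && x[j - 1] >= half) j <- j - 1
    if (j == 1 && x[1] >= half) return(NULL)          # runs off the trace
    if (x[j - 1] < thr) {
      t_left <- t[j]                                   # unresolved step rise
    } else {
      c1 <- t[j - 1] + (half - x[j - 1]) / (x[j] - x[j - 1]) * dt
      # earliest supra-half sample inside the event region (noise makes the
      # first passage late-biased on this side; averaging the two crossing
      # candidates cancels the bias)
      pre <- seg[seg <= ipk & x[seg] >= half]
      j2 <- min(pre)
      c2 <- if (j2 > 1) {
        t[j2 - 1] + (half - x[j2 - 1]) / (x[j2] - x[j2 - 1]) * dt
      } else c1
      t_left <- (c1 + c2) / 2
    }
    # right half-crossing: average the first passage below half and the
    # last exceedance of half within the event region; their opposite
    # noise-induced biases cancel on a monotone decay
    j <- ipk
    while (j < n && x[j + 1] >= half) j <- j + 1
    if (j == n && x[n] >= half) return(NULL)
    c1 <- t[j] + (x[j] - half) / (x[j] - x[j + 1]) * dt
    post <- seg[seg >= ipk & x[seg] >= half]
    j2 <- max(post)
    c2 <- if (j2 < n) {
      t[j2] + (x[j2] - half) / (x[j2] - x[j2 + 1]) * dt
    } else c1
    t_right <- (c1 + c2) / 2
    # onset: upward threshold crossing before the peak
    j <- ipk
    while (j > 1 && x[j - 1] > thr) j <- j - 1
    data.frame(onset_time = t[j], peak_time = t[ipk], peak_amplitude = pk,
               half_width = t_right - t_left)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) return(empty_events(thr))
  out <- out[order(out$peak_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  class(out) <- c("dilation_events", "data.frame")
  out
}

empty_events <- function(thr) {
  out <- data.frame(onset_time = numeric(0), peak_time = numeric(0),
                    peak_amplitude = numeric(0), half_width = numeric(0))
  attr(out, "threshold") <- thr
  class(out) <- c("dilation_events", "data.frame")
  out
}

# Event regions with hysteresis: open on an upward crossing of `thr`,
# close when the signal drops below `end_thr`. Returns a 2-column matrix
# of start/end sample indices.
hysteresis_runs <- function(x, thr, end_thr) {
  n <- length(x)
  runs <- matrix(integer(0), ncol = 2)
  i <- 1L
  while (i <= n) {
    if (x[i] > thr && (i == 1L || x[i - 1] <= thr)) {
      j <- i
      while (j < n && x[j + 1] >= end_thr) j <- j + 1L
      runs <- rbind(runs, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# Split a supra-threshold run at local minima that drop below half of the
# lower of the two adjacent peaks (overlapping-event rule).
split_overlapping <- function(x, seg) {
  if (length(seg) < 3) return(list(seg))
  xs <- x[seg]
  n <- length(xs)
  is_max <- c(FALSE, xs[2:(n - 1)] > xs[1:(n - 2)] & xs[2:(n - 1)] >= xs[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(list(seg))
  cuts <- integer(0)
  for (i in seq_len(length(peaks) - 1)) {
    between <- (peaks[i] + 1):(peaks[i + 1] - 1)
    if (length(between) == 0) next
    imin <- between[which.min(xs[between])]
    if (xs[imin] < 0.5 * min(xs[peaks[i]], xs[peaks[i + 1]])) {
      cuts <- c(cuts, imin)
    }
  }
  if (length(cuts) == 0) return(list(seg))
  bounds <- c(0, cuts, n)
  lapply(seq_len(length(bounds) - 1), function(i) {
    seg[(bounds[i] + 1):bounds[i + 1]]
  })
}

#' Summarize dilation events across sessions
#'
#' Inter-event intervals (successive peak-time differences), peak
#' amplitudes and half-widths are pooled per session and turned into
#' cumulative relative frequency curves on a common grid, plus their
#' across-session average.
#'
#' @param sessions a `dilation_events` data.frame, or a list of them (one
#'   per session).
#' @param n_grid number of grid points for the cumulative curves.
#' @return list of class `event_summary` with per-statistic value lists,
#'   grand means/SDs, and cumulative curves (`grid`, per-session `curves`
#'   matrix, `mean_curve`).
#' @export
summarize_events <- function(sessions, n_grid = 200) {
  if (inherits(sessions, "dilation_events")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  per <- lapply(sessions, function(ev) {
    list(
      intervals = if (nrow(ev) >= 2) diff(ev$peak_time) else numeric(0),
      amplitudes = ev$peak_amplitude,
      half_widths = ev$half_width
    )
  })
  stat_names <- c("intervals", "amplitudes", "half_widths")
  out <- list()
  for (s in stat_names) {
    vals <- lapply(per, `[[`, s)
    pooled <- unlist(vals)
    if (length(pooled) == 0) {
      out[[s]] <- list(values = vals, pooled = pooled, mean = NA_real_,
                       sd = NA_real_, flagged = TRUE, curve = NULL)
      next
    }
    grid <- seq(0, max(pooled), length.out = n_grid)
    curves <- t(vapply(vals, function(v) {
      if (length(v) == 0) rep(NA_real_, n_grid) else stats::ecdf(v)(grid)
    }, numeric(n_grid)))
    out[[s]] <- list(
      values = vals, pooled = pooled,
      mean = mean(pooled), sd = stats::sd(pooled),
      flagged = any(vapply(vals, length, integer(1)) == 0),
      curve = list(grid = grid, curves = curves,
                   mean_curve = colMeans(curves, na.rm = TRUE))
    )
  }
  structure(out, class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("<event_summary>\n")
  for (s in names(x)) {
    cat(sprintf("  %-12s n = %4d  mean = %7.2f  sd = %6.2f\n",
                s, length(x[[s]]$pooled), x[[s]]$mean, x[[s]]$sd))
  }
  invisible(x)
}
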