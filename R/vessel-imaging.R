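# Vessel image-stack processing: (1) original stack -> (2) background
# subtracted stack -> (3) baseline normalized stack, then per-frame
# cross-section profiles and the full-width-at-10%-maximum (FW10M)
# diameter readout.

#' Subtract the per-frame flank background
#'
#' For every frame, the mean intensity of the two off-vessel regions (left
#' and right of the vessel band) is computed and that scalar is subtracted
#' from every pixel of the frame.
#'
#' @param stack an [image_stack()].
#' @param left_roi,right_roi [pixel_roi()] rectangles flanking the vessel.
#' @return the background-subtracted [image_stack()].
#' @export
subtract_background <- function(stack, left_roi, right_roi) {
  stopifnot(inherits(stack, "image_stack"))
  dyx <- dim(stack$data)[2:3]
  check_roi(left_roi, dyx, "left_roi")
  check_roi(right_roi, dyx, "right_roi")
  out <- stack$data
  for (k in seq_len(n_frames(stack))) {
    frame <- stack$data[k, , ]
    bg <- mean(c(frame[left_roi$rows, left_roi$cols],
                 frame[right_roi$rows, right_roi$cols]))
    out[k, , ] <- frame - bg
  }
  image_stack(out, stack$pixel_size, stack$frame_rate, stack$channel)
}

#' Slow fade baseline of a fluorescence trace
#'
#' Strong zero-phase Gaussian low-pass (half-power at `cutoff`, 5 mHz by
#' default) of an in-vessel mean-intensity trace. Vasomotion-band
#' fluctuations (~0.1-1 Hz, 20-200x the cutoff) are suppressed to below
#' 1e-3 of their amplitude, leaving only the slow photobleach/dilution
#' decline. Edges are handled by reflection padding; the output has the
#' same length as the input.
#'
#' @param trace a [trace_series()] of raw fluorescence.
#' @param cutoff half-power frequency in Hz.
#' @return a [trace_series()] holding the baseline.
#' @export
fade_baseline <- function(trace, cutoff = 0.005) {
  stopifnot(inherits(trace, "trace_series"))
  # impulse-response sigma of the half-power-at-cutoff Gaussian
  sigma_t <- sqrt(2 * log(2)) / (2 * pi * cutoff)
  if (trace_duration(trace) < 3 * sigma_t) {
    stop("trace shorter than 3 filter time constants", call. = FALSE)
  }
  v <- gaussian_lowpass(trace$values, trace$rate, cutoff)
  trace_series(v, trace$rate, channel = paste0(trace$channel, "_baseline"),
               start = trace$start, units = trace$units)
}

#' Normalize a stack to a baseline trace
#'
#' Divides every pixel of frame `t` by `baseline(t)`, producing the
#' baseline-normalized stack in which in-vessel values sit near 1
#' regardless of dye concentration or photobleaching.
#'
#' @param stack an [image_stack()] (background subtracted).
#' @param baseline a strictly positive [trace_series()] with one value per
#'   frame, e.g. from [fade_baseline()].
#' @return the normalized [image_stack()].
#' @export
normalize_to_baseline <- function(stack, baseline) {
  stopifnot(inherits(stack, "image_stack"), inherits(baseline, "trace_series"))
  if (length(baseline$values) != n_frames(stack)) {
    stop("baseline length must equal the frame count", call. = FALSE)
  }
  if (any(baseline$values <= 0)) {
    stop("baseline must be strictly positive", call. = FALSE)
  }
  out <- stack$data
  for (k in seq_len(n_frames(stack))) {
    out[k, , ] <- stack$data[k, , ] / baseline$values[k]
  }
  image_stack(out, stack$pixel_size, stack$frame_rate, stack$channel)
}

#' Extract per-frame vessel cross-section profiles
#'
#' Averages the selected rows of each frame into one intensity profile
#' along the horizontal (position) axis, Gaussian-smooths it along
#' position, and flattens the residual horizontal slope: a straight line
#' through the two off-vessel flank means is subtracted, so the flanks end
#' up at zero even when the left and right background levels differ.
#'
#' @param stack an [image_stack()] with the vessel axis vertical.
#' @param line_rows integer row indices to average (>= 1 row).
#' @param smooth_sigma Gaussian smoothing sigma along position, in pixels.
#'   Default 1; set to 0 to disable.
#' @param flank_frac fraction of samples at each end of the profile used as
#'   the off-vessel flank for slope flattening.
#' @return list of class `profile_set` with `position` (micrometres),
#'   `profiles` (frames x position matrix), `frame_time` (s).
#' @export
extract_profile <- function(stack, line_rows, smooth_sigma = 1,
                            flank_frac = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  line_rows <- as.integer(line_rows)
  if (length(line_rows) < 1) stop("need at least 1 row", call. = FALSE)
  if (max(line_rows) > dim(stack$data)[2]) {
    stop("`line_rows` outside the frame", call. = FALSE)
  }
  nx <- dim(stack$data)[3]
  pos <- (seq_len(nx) - 1L) * stack$pixel_size
  nf <- n_frames(stack)
  n_flank <- max(2L, round(flank_frac * nx))
  il <- seq_len(n_flank)
  ir <- (nx - n_flank + 1L):nx
  profs <- matrix(0, nrow = nf, ncol = nx)
  for (k in seq_len(nf)) {
    p <- if (length(line_rows) == 1) as.numeric(stack$data[k, line_rows, ]) else
      colMeans(stack$data[k, line_rows, ])
    if (smooth_sigma > 0) p <- gaussian_smooth_1d(p, smooth_sigma)
    # flat-sloping baseline: line through the two flank (position, mean) points
    xl <- mean(pos[il]); yl <- mean(p[il])
    xr <- mean(pos[ir]); yr <- mean(p[ir])
    slope <- (yr - yl) / (xr - xl)
    p <- p - (yl + slope * (pos - xl))
    profs[k, ] <- p
  }
  structure(list(position = pos, profiles = profs,
                 frame_time = frame_times(stack),
                 pixel_size = stack$pixel_size),
            class = "profile_set")
}

#' Full width at 10% maximum of a cross-section profile
#'
#' The diameter index: threshold at 10% of the profile maximum (of a
#' reference basal profile when supplied, otherwise of the profile itself),
#' outermost threshold crossings on each flank located by linear
#' interpolation, diameter = right - left crossing. The profile maximum is
#' returned as the peak intensity.
#'
#' @param intensity numeric profile values.
#' @param position positions in micrometres (uniform spacing).
#' @param reference_max maximum of the basal reference profile; defaults to
#'   `max(intensity)`. The 10% threshold is taken from this value, so a
#'   threshold fixed at the basal phase can be reused across frames.
#' @param threshold_frac threshold as a fraction of the reference maximum.
#' @return list with `diameter_fw10m` (micrometres, `NA` when the threshold
#'   is never crossed on a flank), `peak_intensity`, and `measurable`.
#' @export
fw10m_diameter <- function(intensity, position, reference_max = NULL,
                           threshold_frac = 0.10) {
  stopifnot(length(intensity) == length(position))
  pk <- max(intensity)
  if (pk <= 0) {
    return(list(diameter_fw10m = NA_real_, peak_intensity = pk, measurable = FALSE))
  }
  ref <- if (is.null(reference_max)) pk else reference_max
  thr <- threshold_frac * ref
  above <- which(intensity > thr)
  if (length(above) == 0) {
    return(list(diameter_fw10m = NA_real_, peak_intensity = pk, measurable = FALSE))
  }
  li <- min(above); ri <- max(above)
  # outermost crossings; a flank never dipping below threshold is unmeasurable
  if (li == 1 || ri == length(intensity)) {
    return(list(diameter_fw10m = NA_real_, peak_intensity = pk, measurable = FALSE))
  }
  xl <- position[li - 1] +
    (thr - intensity[li - 1]) / (intensity[li] - intensity[li - 1]) *
    (position[li] - position[li - 1])
  xr <- position[ri] +
    (intensity[ri] - thr) / (intensity[ri] - intensity[ri + 1]) *
    (position[ri + 1] - position[ri])
  list(diameter_fw10m = xr - xl, peak_intensity = pk, measurable = TRUE)
}

#' Per-frame diameter and peak-intensity series
#'
#' Composes the full vessel pipeline: background subtraction, in-vessel
#' fade baseline, baseline normalization, profile extraction, and the
#' FW10M readout with a threshold fixed at the basal phase. The basal
#' (undilated) phase is operationalized as the lowest-quartile frames of
#' the smoothed first-pass diameter series; the reference profile maximum
#' and the basal diameter are means over those frames. Both outputs are
#' normalized to the basal phase and expressed in % (basal = 100).
#'
#' @param stack the raw [image_stack()].
#' @param left_roi,right_roi background [pixel_roi()]s.
#' @param vessel_roi in-vessel [pixel_roi()] for the fade baseline.
#' @param line_rows rows to average for the profile.
#' @param smooth_sigma profile smoothing sigma, pixels.
#' @param fade_cutoff fade-baseline half-power frequency, Hz.
#' @return list with `diameter` and `peak` ([trace_series()], % of basal),
#'   `diameter_um` (raw FW10M per frame, micrometres), `basal_diameter_um`,
#'   and `measurable` (logical per frame).
#' @export
diameter_and_peak_series <- function(stack, left_roi, right_roi, vessel_roi,
                                     line_rows, smooth_sigma = 1,
                                     fade_cutoff = 0.005) {
  sub <- subtract_background(stack, left_roi, right_roi)
  vessel_trace <- roi_mean_trace(sub, vessel_roi)
  baseline <- fade_baseline(vessel_trace, cutoff = fade_cutoff)
  norm <- normalize_to_baseline(sub, baseline)
  profs <- extract_profile(norm, line_rows, smooth_sigma = smooth_sigma)
  nf <- nrow(profs$profiles)
  # first pass: per-frame FW10M with per-frame threshold, to find the basal phase
  d1 <- vapply(seq_len(nf), function(k) {
    m <- fw10m_diameter(profs$profiles[k, ], profs$position)
    if (m$measurable) m$diameter_fw10m else NA_real_
  }, numeric(1))
  d1_s <- d1
  ok <- !is.na(d1)
  d1_s[ok] <- gaussian_smooth_1d(d1[ok], sigma = max(1, stack$frame_rate))
  q25 <- stats::quantile(d1_s, 0.25, na.rm = TRUE)
  basal <- which(ok & d1_s <= q25)
  if (length(basal) < 1) basal <- which(ok)
  ref_profile <- colMeans(profs$profiles[basal, , drop = FALSE])
  ref_max <- max(ref_profile)
  # second pass: fixed basal threshold
  meas <- lapply(seq_len(nf), function(k) {
    fw10m_diameter(profs$profiles[k, ], profs$position, reference_max = ref_max)
  })
  d_um <- vapply(meas, function(m) m$diameter_fw10m, numeric(1))
  pk <- vapply(meas, function(m) m$peak_intensity, numeric(1))
  measurable <- vapply(meas, function(m) m$measurable, logical(1))
  basal_d <- mean(d_um[basal], na.rm = TRUE)
  basal_pk <- mean(pk[basal], na.rm = TRUE)
  list(
    diameter = trace_series(d_um / basal_d * 100, stack$frame_rate,
                            channel = "diameter", units = "%"),
    peak = trace_series(pk / basal_pk * 100, stack$frame_rate,
                        channel = "peak_intensity", units = "%"),
    diameter_um = d_um, basal_diameter_um = basal_d, measurable = measurable
  )
}
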