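# Percent normalization, single-sided amplitude spectra, spectrograms,
# and the stimulus-locked peak-ratio statistic (PR0.25), per trace and
# per pixel.

#' Percent-normalize a raw fluorescence trace
#'
#' Divides the trace by its own slow low-pass baseline, subtracts 1 and
#' multiplies by 100, yielding the % deviation from the slow baseline.
#' The baseline filter is a zero-phase low-pass with a raised-cosine
#' transition between `passband_edge` and `stopband_edge` (10 -> 50 mHz by
#' default), so vasomotion-band content at 0.1-1 Hz passes into the
#' percent trace untouched while the photobleach fade and dye-dilution
#' drift are absorbed into the baseline.
#'
#' @param trace a strictly positive raw-fluorescence [trace_series()] of at
#'   least 60 s.
#' @param passband_edge baseline filter passband edge, Hz.
#' @param stopband_edge baseline filter stopband edge, Hz.
#' @return a [trace_series()] in % deviation.
#' @export
normalize_percent <- function(trace, passband_edge = 0.01, stopband_edge = 0.05) {
  stopifnot(inherits(trace, "trace_series"))
  if (any(!is.finite(trace$values)) || any(trace$values <= 0)) {
    stop("raw fluorescence expected: all samples must be positive and finite",
         call. = FALSE)
  }
  if (trace_duration(trace) < 60) {
    stop("trace must be at least 60 s for baseline estimation", call. = FALSE)
  }
  base <- cosine_lowpass(trace$values, trace$rate, passband_edge, stopband_edge)
  v <- (trace$values / base - 1) * 100
  trace_series(v, trace$rate, channel = trace$channel, start = trace$start,
               units = "%")
}

#' Single-sided amplitude spectrum
#'
#' Rectangular-window FFT amplitude spectrum scaled so that a pure
#' sinusoid of amplitude A completing an integer number of cycles yields a
#' peak of exactly A at its frequency. The frequency grid spacing is
#' `1/duration`.
#'
#' @param trace a [trace_series()] (typically percent-normalized).
#' @return list of class `spectral_result` with `frequencies` (Hz) and
#'   `amplitudes` (input units).
#' @export
amplitude_spectrum <- function(trace) {
  stopifnot(inherits(trace, "trace_series"))
  x <- trace$values
  if (any(!is.finite(x))) stop("NaN/Inf in input", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  n_half <- floor(n / 2)
  amp <- Mod(X[seq_len(n_half + 1L)]) / n
  # double everything except DC and (for even n) the Nyquist bin
  dbl <- rep(2, n_half + 1L)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half + 1L] <- 1
  amp <- amp * dbl
  freq <- (0:n_half) * trace$rate / n
  structure(list(frequencies = freq, amplitudes = amp, rate = trace$rate,
                 n = n, duration = n / trace$rate),
            class = "spectral_result")
}

#' Short-term Fourier transform spectrogram
#'
#' Rectangular windows of `window` seconds stepped by `step` seconds, each
#' scaled exactly like [amplitude_spectrum()]; time stamps are at window
#' centers.
#'
#' @param trace a [trace_series()].
#' @param window window length in seconds (<= trace duration); 120, 60 or
#'   40 s are the standard choices.
#' @param step step between window starts in seconds.
#' @return list of class `spectrogram_result` with `times` (s),
#'   `frequencies` (Hz) and `amplitudes` (time x frequency matrix).
#' @export
spectrogram <- function(trace, window = 60, step = 4) {
  stopifnot(inherits(trace, "trace_series"))
  if (window > trace_duration(trace)) {
    stop("`window` exceeds the trace duration", call. = FALSE)
  }
  wn <- round(window * trace$rate)
  st <- max(1L, round(step * trace$rate))
  n <- length(trace$values)
  starts <- seq(1L, n - wn + 1L, by = st)
  specs <- lapply(starts, function(i0) {
    seg <- trace_series(trace$values[i0:(i0 + wn - 1L)], trace$rate)
    amplitude_spectrum(seg)
  })
  freq <- specs[[1]]$frequencies
  amps <- t(vapply(specs, function(s) s$amplitudes, numeric(length(freq))))
  times <- trace$start + (starts - 1L + (wn - 1) / 2) / trace$rate
  structure(list(times = times, frequencies = freq, amplitudes = amps,
                 window = window, step = step, rate = trace$rate),
            class = "spectrogram_result")
}

#' Peak-ratio entrainment statistic
#'
#' The amplitude at the spectral bin nearest the target frequency divided
#' by the mean amplitude over all bins in the band (inclusive of the
#' target bin). A flat spectrum gives exactly 1; a trace locked to the
#' stimulus gives values well above 1 (segments with PR > 3 are treated as
#' entrained in the phase analysis).
#'
#' @param spec a `spectral_result` from [amplitude_spectrum()].
#' @param f0 target frequency, Hz (0.25 by default -> "PR0.25").
#' @param band two-element band in Hz over which the mean is taken.
#' @return list of class `peak_ratio_result` with `pr`, `peak_amplitude`,
#'   `band_mean`, `target_frequency`, and the actual bin frequency used.
#' @export
peak_ratio <- function(spec, f0 = 0.25, band = c(0.1, 1)) {
  stopifnot(inherits(spec, "spectral_result"))
  if (f0 < band[1] || f0 > band[2]) {
    stop("`f0` must lie within `band`", call. = FALSE)
  }
  f <- spec$frequencies
  i0 <- which.min(abs(f - f0))
  df <- f[2] - f[1]
  if (abs(f[i0] - f0) > 1e-9 * max(1, f0)) {
    warning(sprintf("f0 = %g Hz is not an exact bin; using nearest bin %g Hz (offset %.3g Hz)",
                    f0, f[i0], f[i0] - f0))
  }
  in_band <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  if (!any(in_band)) stop("band contains no spectral bins", call. = FALSE)
  pk <- spec$amplitudes[i0]
  bm <- mean(spec$amplitudes[in_band])
  structure(list(pr = pk / bm, peak_amplitude = pk, band_mean = bm,
                 target_frequency = f0, bin_frequency = f[i0], band = band),
            class = "peak_ratio_result")
}

#' Pixelwise peak-ratio map
#'
#' Spatially Gaussian-smooths every frame (sigma in micrometres), then for
#' each pixel percent-normalizes its time series, computes the amplitude
#' spectrum, and evaluates the peak ratio at the target frequency. The
#' result is a Y x X map of PR values.
#'
#' @param stack a raw (strictly positive) [image_stack()] of at least 5
#'   minutes.
#' @param sigma_um spatial smoothing sigma in micrometres (165 by default).
#' @param f0 target frequency, Hz.
#' @param band PR band, Hz.
#' @param passband_edge,stopband_edge baseline filter edges passed to
#'   [normalize_percent()].
#' @return list of class `pr_map_result` with `map` (Y x X matrix of PR)
#'   and the smoothing/PR parameters.
#' @export
pr_map <- function(stack, sigma_um = 165, f0 = 0.25, band = c(0.1, 1),
                   passband_edge = 0.01, stopband_edge = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$pixel_size) || !is.finite(stack$pixel_size)) {
    stop("stack pixel size required", call. = FALSE)
  }
  if (n_frames(stack) / stack$frame_rate < 300) {
    stop("stack must cover at least 5 minutes", call. = FALSE)
  }
  sigma_px <- sigma_um / stack$pixel_size
  nf <- n_frames(stack)
  ny <- dim(stack$data)[2]; nx <- dim(stack$data)[3]
  sm <- stack$data
  if (sigma_px > 0) {
    for (k in seq_len(nf)) {
      sm[k, , ] <- EBImage::gblur(stack$data[k, , ], sigma = sigma_px,
                                  boundary = "replicate")
    }
  }
  map <- matrix(NA_real_, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      px_trace <- trace_series(sm[, iy, ix], stack$frame_rate)
      norm <- normalize_percent(px_trace, passband_edge, stopband_edge)
      spec <- amplitude_spectrum(norm)
      map[iy, ix] <- peak_ratio(spec, f0 = f0, band = band)$pr
    }
  }
  structure(list(map = map, sigma_um = sigma_um, f0 = f0, band = band,
                 pixel_size = stack$pixel_size),
            class = "pr_map_result")
}

#' Average pulsed-excitation samples into an effective rate
#'
#' Pulsed acquisition delivers excitation in short pulses separated by
#' dark intervals; samples recorded within each pulse are averaged into
#' one value, giving an effective sampling rate of
#' `1 / (pulse + interval)`. Averaging 20 ms pulses with 180 ms intervals
#' therefore yields exactly 5 Hz.
#'
#' @param trace the high-rate [trace_series()] recorded during pulses and
#'   intervals.
#' @param pulse pulse duration, s.
#' @param interval inter-pulse interval, s.
#' @return a [trace_series()] at the effective rate.
#' @export
pulse_average <- function(trace, pulse = 0.020, interval = 0.180) {
  stopifnot(inherits(trace, "trace_series"), pulse > 0, interval >= 0)
  period <- pulse + interval
  eff_rate <- 1 / period
  # snap float noise so e.g. 20 ms + 180 ms gives exactly 5 Hz
  if (abs(eff_rate - round(eff_rate)) < 1e-9) eff_rate <- round(eff_rate)
  n_per <- round(period * trace$rate)
  n_pulse <- max(1L, round(pulse * trace$rate))
  n_out <- floor(length(trace$values) / n_per)
  v <- vapply(seq_len(n_out), function(i) {
    i0 <- (i - 1L) * n_per + 1L
    mean(trace$values[i0:(i0 + n_pulse - 1L)])
  }, numeric(1))
  trace_series(v, eff_rate, channel = trace$channel, start = trace$start,
               units = trace$units)
}
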