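# Synthetic-data generators. Every generator takes an explicit seed, returns
# its output together with a ground-truth record sufficient to reconstruct
# the noiseless signal, and restores the caller's RNG state on exit.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normal truncated below at `lower`, drawn by inverse-CDF so the draw count
# (and hence seed determinism) does not depend on rejection luck.
rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Visual stimulus description
#'
#' Parameters of the horizontally oscillating striped stimulus. Defaults
#' are the standard protocol: 0.25 Hz temporal frequency, 17 degrees
#' peak-to-peak oscillation in the visual angle, 6.4 degrees spatial cycle.
#'
#' @param temporal_frequency oscillation frequency in Hz (> 0).
#' @param oscillation_amplitude peak-to-peak amplitude in degrees of visual
#'   angle.
#' @param spatial_cycle spatial period of the stripe pattern in degrees.
#' @param duration presentation duration in seconds (> 0).
#' @return list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(temporal_frequency = 0.25, oscillation_amplitude = 17,
                          spatial_cycle = 6.4, duration = 300) {
  if (temporal_frequency <= 0) stop("`temporal_frequency` must be > 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  structure(list(temporal_frequency = temporal_frequency,
                 oscillation_amplitude = oscillation_amplitude,
                 spatial_cycle = spatial_cycle, duration = duration),
            class = "stimulus_spec")
}

#' Spontaneous vasodilation event model
#'
#' Distributional model for spontaneous dilation events: inter-event
#' interval, peak amplitude (% above the basal diameter/intensity) and
#' half-width (full width at half maximum of a transient, seconds). All
#' three are drawn from normal distributions truncated at zero. Defaults
#' are the spontaneous-vasomotion statistics (15.8 +/- 4.8 s,
#' 10.4 +/- 3.7 %, 1.6 +/- 0.4 s).
#'
#' @param mean_interval,interval_sd inter-event interval mean / SD, s.
#' @param mean_peak,peak_sd event peak amplitude mean / SD, %.
#' @param mean_halfwidth,halfwidth_sd event half-width mean / SD, s.
#' @return list of class `event_model`.
#' @export
event_model <- function(mean_interval = 15.8, interval_sd = 4.8,
                        mean_peak = 10.4, peak_sd = 3.7,
                        mean_halfwidth = 1.6, halfwidth_sd = 0.4) {
  if (any(c(mean_interval, mean_peak, mean_halfwidth) <= 0)) {
    stop("event model means must be > 0", call. = FALSE)
  }
  if (any(c(interval_sd, peak_sd, halfwidth_sd) < 0)) {
    stop("event model SDs must be >= 0", call. = FALSE)
  }
  structure(list(mean_interval = mean_interval, interval_sd = interval_sd,
                 mean_peak = mean_peak, peak_sd = peak_sd,
                 mean_halfwidth = mean_halfwidth, halfwidth_sd = halfwidth_sd),
            class = "event_model")
}

#' Stimulus-locked entrainment model
#'
#' Describes how strongly, and how intermittently, a fluorescence channel is
#' locked to the stimulus frequency: modulation amplitude (% of baseline
#' fluorescence), the fraction of the session spent in frequency lock,
#' a phase offset, the photobleach fade time constant, and additive noise.
#'
#' @param locked_amplitude modulation amplitude while locked, % of baseline.
#' @param lock_fraction fraction of the session in frequency lock, in `[0, 1]`.
#' @param phase_offset phase of the locked oscillation at t = 0, degrees.
#' @param fade_tau photobleach exponential time constant, s (> 0).
#' @param noise_sd additive Gaussian noise SD, % of baseline.
#' @param epoch_mean mean duration of one locked+unlocked epoch pair, s;
#'   locked and unlocked epoch durations are exponential with means
#'   `epoch_mean * lock_fraction` and `epoch_mean * (1 - lock_fraction)`.
#' @return list of class `entrainment_model`.
#' @export
entrainment_model <- function(locked_amplitude = 3, lock_fraction = 1,
                              phase_offset = 0, fade_tau = 600, noise_sd = 1,
                              epoch_mean = 80) {
  if (lock_fraction < 0 || lock_fraction > 1) {
    stop("`lock_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (fade_tau <= 0) stop("`fade_tau` must be > 0", call. = FALSE)
  structure(list(locked_amplitude = locked_amplitude,
                 lock_fraction = lock_fraction, phase_offset = phase_offset,
                 fade_tau = fade_tau, noise_sd = noise_sd,
                 epoch_mean = epoch_mean),
            class = "entrainment_model")
}

#' Channel lag producing a given cross-channel phase
#'
#' Inverse of the lag-to-phase mapping `phase = 180 * mirror +
#' lag / cycle * 360`: returns the delay (s) a mirrored companion channel
#' needs in order to sit at `phase_deg` relative to the reference channel.
#'
#' @param phase_deg target phase in degrees.
#' @param cycle stimulus period in seconds.
#' @param mirror whether the companion channel is inverted (default TRUE).
#' @export
channel_lag_for_phase <- function(phase_deg, cycle = 4, mirror = TRUE) {
  (phase_deg - 180 * mirror) / 360 * cycle
}

#' Default companion-channel models
#'
#' `dyfp_model()` is the parenchymal shadow channel that mirrors the
#' intravascular signal almost exactly (mean phase 184.4 deg at the 4 s
#' cycle); `autofluorescence_model()` is the metabolite autofluorescence
#' channel with a substantial extra delay (mean phase 246.9 deg).
#'
#' @param cycle stimulus period in seconds.
#' @return list with `mirror`, `channel_lag` (s) and `phase_deg`.
#' @export
dyfp_model <- function(cycle = 4) {
  list(mirror = TRUE, channel_lag = channel_lag_for_phase(184.4, cycle),
       phase_deg = 184.4)
}

#' @rdname dyfp_model
#' @export
autofluorescence_model <- function(cycle = 4) {
  list(mirror = TRUE, channel_lag = channel_lag_for_phase(246.9, cycle),
       phase_deg = 246.9)
}

#' Generate the stimulus position trace
#'
#' Sinusoidal stimulus position in degrees of visual angle, starting at
#' phase zero at t = 0; the peak-to-peak excursion equals
#' `oscillation_amplitude`.
#'
#' @param spec a [stimulus_spec()].
#' @param rate sampling rate in Hz; must be at least twice the temporal
#'   frequency (Nyquist).
#' @return a [trace_series()] in degrees.
#' @export
gen_stimulus <- function(spec = stimulus_spec(), rate = 5) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (rate < 2 * spec$temporal_frequency) {
    stop("`rate` below the Nyquist rate for the stimulus frequency", call. = FALSE)
  }
  n <- round(spec$duration * rate)
  t <- (seq_len(n) - 1L) / rate
  v <- spec$oscillation_amplitude / 2 *
    sin(2 * pi * spec$temporal_frequency * t)
  trace_series(v, rate, channel = "stimulus", units = "deg")
}

#' Generate a spontaneous-vasomotion event trace
#'
#' Baseline-zero percent trace carrying instant-rise, exponential-decay
#' dilation transients. Each event's decay constant is `halfwidth / ln 2`
#' so the transient's full width at half maximum equals the drawn
#' half-width. Intervals, peaks and half-widths come from the truncated
#' normal distributions of `model`.
#'
#' @param model an [event_model()].
#' @param duration trace duration in seconds; must exceed the mean interval.
#' @param rate sampling rate, Hz.
#' @param noise_sd additive Gaussian noise SD in %.
#' @param seed integer RNG seed.
#' @return list with `trace` (a [trace_series()], units %) and
#'   `ground_truth` (event times / peaks / half-widths / intervals, seed).
#' @export
gen_event_trace <- function(model = event_model(), duration = 600, rate = 5,
                            noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(model, "event_model"))
  if (duration <= model$mean_interval) {
    stop("`duration` must exceed the mean inter-event interval", call. = FALSE)
  }
  with_seed(seed, {
    # draw generously many intervals, keep events inside the trace
    n_guess <- ceiling(duration / model$mean_interval * 2) + 10L
    intervals <- rtnorm(n_guess, model$mean_interval, model$interval_sd)
    times <- cumsum(intervals)
    keep <- times < duration
    times <- times[keep]
    n_ev <- length(times)
    if (n_ev == 0) warning("trace too short to host one event; returning empty trace")
    peaks <- rtnorm(n_ev, model$mean_peak, model$peak_sd)
    halfwidths <- rtnorm(n_ev, model$mean_halfwidth, model$halfwidth_sd)
    n <- round(duration * rate)
    t <- (seq_len(n) - 1L) / rate
    v <- numeric(n)
    for (i in seq_len(n_ev)) {
      tau <- halfwidths[i] / log(2)
      idx <- t >= times[i]
      v[idx] <- v[idx] + peaks[i] * exp(-(t[idx] - times[i]) / tau)
    }
    if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
    list(
      trace = trace_series(v, rate, channel = "diameter", units = "%"),
      ground_truth = list(
        event_times = times, peaks = peaks, halfwidths = halfwidths,
        intervals = if (n_ev >= 2) diff(times) else numeric(0),
        model = unclass(model), noise_sd = noise_sd, seed = seed
      )
    )
  })
}

# Locked/unlocked epoch boundaries; returns a function lock(t) in {0,1}.
make_lock_profile <- function(lock_fraction, epoch_mean, duration) {
  if (lock_fraction >= 1) return(list(fun = function(t) rep(1, length(t)), epochs = NULL))
  if (lock_fraction <= 0) return(list(fun = function(t) rep(0, length(t)), epochs = NULL))
  m_on <- epoch_mean * lock_fraction
  m_off <- epoch_mean * (1 - lock_fraction)
  state <- stats::runif(1) < lock_fraction
  t0 <- 0
  bounds <- numeric(0); states <- logical(0)
  while (t0 < duration) {
    len <- stats::rexp(1, rate = 1 / if (state) m_on else m_off)
    bounds <- c(bounds, t0); states <- c(states, state)
    t0 <- t0 + len
    state <- !state
  }
  epochs <- data.frame(start = bounds,
                       end = c(bounds[-1], duration),
                       locked = states)
  fun <- function(t) {
    i <- findInterval(t, epochs$start)
    as.numeric(epochs$locked[pmax(i, 1L)])
  }
  list(fun = fun, epochs = epochs)
}

#' Generate a stimulus-locked photometry channel pair
#'
#' Channel 1 is a raw-fluorescence-like trace whose stimulus-locked
#' oscillation switches on and off according to the entrainment model's
#' lock fraction, multiplied by an exponential photobleach fade, plus
#' noise. Channel 2 is an inverted (if `mirror`) copy delayed by
#' `channel_lag`, with its own fade and independent noise. The true phase
#' of channel 2 relative to channel 1 is
#' `180 * mirror + channel_lag / T * 360` degrees.
#'
#' @param stim a [stimulus_spec()].
#' @param ent an [entrainment_model()].
#' @param channel_lag delay of channel 2 in seconds; must be smaller than
#'   the stimulus period.
#' @param mirror logical, invert channel 2.
#' @param rate sampling rate, Hz.
#' @param seed integer RNG seed.
#' @param baseline baseline fluorescence level, arbitrary units.
#' @return list with `ch1`, `ch2` (raw [trace_series()]) and `ground_truth`
#'   (true phase in degrees, lag, lock epochs, seed).
#' @export
gen_photometry_pair <- function(stim = stimulus_spec(duration = 900),
                                ent = entrainment_model(), channel_lag = 0,
                                mirror = TRUE, rate = 5, seed = 1,
                                baseline = 100) {
  stopifnot(inherits(stim, "stimulus_spec"), inherits(ent, "entrainment_model"))
  period <- 1 / stim$temporal_frequency
  if (rate < 2 * stim$temporal_frequency) {
    stop("`rate` below the Nyquist rate for the stimulus frequency", call. = FALSE)
  }
  if (abs(channel_lag) >= period) {
    stop("`channel_lag` must be smaller than the stimulus period", call. = FALSE)
  }
  with_seed(seed, {
    n <- round(stim$duration * rate)
    t <- (seq_len(n) - 1L) / rate
    lock <- make_lock_profile(ent$lock_fraction, ent$epoch_mean, stim$duration)
    phi0 <- ent$phase_offset * pi / 180
    osc <- function(tt) {
      lock$fun(tt) * (ent$locked_amplitude / 100) *
        sin(2 * pi * stim$temporal_frequency * tt + phi0)
    }
    sgn <- if (mirror) -1 else 1
    m1 <- osc(t)
    m2 <- sgn * osc(t - channel_lag)
    ch1 <- baseline * (1 + m1) * exp(-t / ent$fade_tau) +
      stats::rnorm(n, sd = ent$noise_sd / 100 * baseline)
    ch2 <- baseline * (1 + m2) * exp(-t / ent$fade_tau) +
      stats::rnorm(n, sd = ent$noise_sd / 100 * baseline)
    true_phase <- (180 * mirror + channel_lag / period * 360) %% 360
    list(
      ch1 = trace_series(ch1, rate, channel = "TexasRed"),
      ch2 = trace_series(ch2, rate, channel = if (mirror) "shadow" else "companion"),
      ground_truth = list(
        true_phase = true_phase, channel_lag = channel_lag, mirror = mirror,
        lock_epochs = lock$epochs, lock_fraction = ent$lock_fraction,
        locked_amplitude = ent$locked_amplitude, fade_tau = ent$fade_tau,
        period = period, seed = seed
      )
    )
  })
}

#' Generate a synthetic vessel image stack
#'
#' Vertical bright band on a dark parenchyma background (intravascular-dye
#' convention). The band's cross-section follows a projected-cylinder
#' profile: the fluorophore column depth at lateral offset `x` through a
#' cylinder of diameter `d` is `d * sqrt(1 - (2x/d)^2)`, so
#' `I(x) = I0 * (d(t)/d0) * sqrt(1 - (2x/d(t))^2)` with
#' `d(t) = true_diameter * (1 + modulation)` — a dilating vessel gets both
#' wider and brighter at its centre, which is what ties the peak-intensity
#' readout to the diameter readout. The vessel signal is multiplied by an
#' exponential photobleach fade; additive background and Gaussian noise
#' complete the frame. The per-frame true diameter is stored in the ground
#' truth.
#'
#' @param true_diameter basal vessel diameter, micrometres; must be at
#'   least 4 pixels wide.
#' @param osc_amplitude sinusoidal diameter modulation, % of the diameter.
#' @param osc_freq modulation frequency, Hz.
#' @param events optional [event_model()]; when given, spontaneous dilation
#'   transients (in % of diameter) are added to the modulation.
#' @param fade_tau photobleach time constant, s.
#' @param pixel_size micrometres per pixel.
#' @param rate frame rate, Hz.
#' @param duration stack duration, s.
#' @param noise_sd additive Gaussian noise SD, % of the vessel peak
#'   intensity.
#' @param fov_width field of view width in micrometres (default 2.4 x
#'   diameter); the dilated vessel must fit inside it.
#' @param n_rows image height in pixels.
#' @param vessel_intensity,background peak vessel intensity and additive
#'   background level, arbitrary units.
#' @param center_offset vessel centre offset from the field centre in
#'   pixels; `NULL` (default) draws a sub-pixel offset uniformly from
#'   `[-0.5, 0.5)` so the vessel edge is not artificially aligned with the
#'   pixel grid.
#' @param seed integer RNG seed.
#' @return list with `stack` (an [image_stack()]) and `ground_truth`
#'   (per-frame diameter, geometry, seed).
#' @export
gen_vessel_stack <- function(true_diameter = 45.7, osc_amplitude = 0,
                             osc_freq = 0.25, events = NULL, fade_tau = 600,
                             pixel_size = 1, rate = 5, duration = 300,
                             noise_sd = 1, fov_width = NULL, n_rows = 32,
                             vessel_intensity = 100, background = 20,
                             center_offset = NULL, seed = 1) {
  if (true_diameter < 4 * pixel_size) {
    stop("`true_diameter` must be at least 4 pixels wide", call. = FALSE)
  }
  if (is.null(fov_width)) fov_width <- 2.4 * true_diameter
  n <- round(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  with_seed(seed, {
    modulation <- (osc_amplitude / 100) * sin(2 * pi * osc_freq * t)
    event_truth <- NULL
    if (!is.null(events)) {
      ev <- gen_event_trace(events, duration = duration, rate = rate,
                            noise_sd = 0, seed = seed + 1L)
      modulation <- modulation + ev$trace$values / 100
      event_truth <- ev$ground_truth
    }
    d_t <- true_diameter * (1 + modulation)
    if (max(d_t) >= fov_width) {
      stop("vessel diameter exceeds the field of view", call. = FALSE)
    }
    nx <- round(fov_width / pixel_size)
    if (is.null(center_offset)) center_offset <- stats::runif(1, -0.5, 0.5)
    x <- (seq_len(nx) - 0.5 - nx / 2 - center_offset) * pixel_size  # um from centre
    fade <- exp(-t / fade_tau)
    dat <- array(0, dim = c(n, n_rows, nx))
    for (k in seq_len(n)) {
      prof <- vessel_intensity * (d_t[k] / true_diameter) *
        sqrt(pmax(0, 1 - (2 * x / d_t[k])^2)) * fade[k] + background
      frame <- matrix(prof, nrow = n_rows, ncol = nx, byrow = TRUE)
      if (noise_sd > 0) {
        frame <- frame + stats::rnorm(n_rows * nx,
                                      sd = noise_sd / 100 * vessel_intensity)
      }
      dat[k, , ] <- frame
    }
    list(
      stack = image_stack(dat, pixel_size = pixel_size, frame_rate = rate),
      ground_truth = list(
        true_diameter = true_diameter, diameter_t = d_t, x_positions = x,
        center_offset = center_offset,
        osc_amplitude = osc_amplitude, osc_freq = osc_freq,
        fade_tau = fade_tau, background = background,
        vessel_intensity = vessel_intensity, noise_sd = noise_sd,
        events = event_truth, seed = seed
      )
    )
  })
}

#' Generate a synthetic eye-angle trace
#'
#' Eye angle tracking the sinusoidal stimulus with a gain and a phase lag,
#' plus slow drift, Gaussian noise, and Poisson-timed saccades. Saccades
#' are instantaneous steps (> 1 degree between consecutive frames) followed
#' by exponential re-centering.
#'
#' @param stim a [stimulus_spec()].
#' @param gain tracking gain in `[0, 1.2]`.
#' @param phase_lag eye lag behind the stimulus, degrees of the stimulus
#'   cycle.
#' @param saccade_rate saccades per minute.
#' @param drift_amp slow drift amplitude, degrees.
#' @param noise_sd measurement noise SD, degrees.
#' @param frame_rate video frame rate, Hz (30 by default).
#' @param seed integer RNG seed.
#' @param saccade_recenter_tau exponential re-centering time constant, s.
#' @return list with `trace` (a [trace_series()], degrees) and
#'   `ground_truth` (gain, phase lag, saccade times/amplitudes, seed).
#' @export
gen_eye_trace <- function(stim = stimulus_spec(), gain = 0.5, phase_lag = 2.3,
                          saccade_rate = 6, drift_amp = 1, noise_sd = 0.1,
                          frame_rate = 30, seed = 1,
                          saccade_recenter_tau = 2) {
  stopifnot(inherits(stim, "stimulus_spec"))
  if (gain < 0 || gain > 1.2) stop("`gain` must be in [0, 1.2]", call. = FALSE)
  with_seed(seed, {
    n <- round(stim$duration * frame_rate)
    t <- (seq_len(n) - 1L) / frame_rate
    lag_rad <- phase_lag * pi / 180
    eye <- gain * stim$oscillation_amplitude / 2 *
      sin(2 * pi * stim$temporal_frequency * t - lag_rad)
    # slow drift: two incommensurate slow sinusoids with random phases
    drift <- drift_amp * (0.7 * sin(2 * pi * 0.011 * t + stats::runif(1, 0, 2 * pi)) +
                          0.3 * sin(2 * pi * 0.007 * t + stats::runif(1, 0, 2 * pi)))
    # Poisson saccade times
    sac_times <- numeric(0)
    if (saccade_rate > 0) {
      tt <- 0
      repeat {
        tt <- tt + stats::rexp(1, rate = saccade_rate / 60)
        if (tt >= stim$duration) break
        sac_times <- c(sac_times, tt)
      }
    }
    sac_amps <- if (length(sac_times)) {
      stats::runif(length(sac_times), 2, 5) *
        sample(c(-1, 1), length(sac_times), replace = TRUE)
    } else numeric(0)
    sac <- numeric(n)
    for (i in seq_along(sac_times)) {
      idx <- t >= sac_times[i]
      sac[idx] <- sac[idx] +
        sac_amps[i] * exp(-(t[idx] - sac_times[i]) / saccade_recenter_tau)
    }
    v <- eye + drift + sac
    if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
    list(
      trace = trace_series(v, frame_rate, channel = "eye", units = "deg"),
      ground_truth = list(
        gain = gain, phase_lag = phase_lag, saccade_times = sac_times,
        saccade_amplitudes = sac_amps, drift_amp = drift_amp,
        noise_sd = noise_sd, seed = seed
      )
    )
  })
}
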