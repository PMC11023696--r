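# Generators: construction correctness, argument validation, seed
# determinism, and fidelity of the stored ground truth.

test_that("stimulus trace is a phase-zero sinusoid with peak-to-peak amplitude", {
  s <- gen_stimulus(stimulus_spec(duration = 4), rate = 5)
  expect_length(s$values, 20)
  expect_equal(max(s$values) - min(s$values), 17)
  expect_equal(s$values[1], 0)

  long <- gen_stimulus(stimulus_spec(duration = 300), rate = 5)
  expect_length(long$values, 1500)

  expect_error(gen_stimulus(stimulus_spec(), rate = 0.4), "Nyquist")
  expect_error(stimulus_spec(duration = 0), "duration")
  expect_error(stimulus_spec(temporal_frequency = -1), "temporal_frequency")
})

test_that("event traces carry transients whose FWHM equals the drawn half-width", {
  m <- event_model(interval_sd = 0, peak_sd = 0, halfwidth_sd = 0,
                   mean_peak = 10, mean_halfwidth = 1.6)
  ev <- gen_event_trace(m, duration = 40, rate = 50, noise_sd = 0, seed = 1)
  # successive transients ride on the previous tail (~0.1% at 15.8 s spacing)
  expect_equal(max(ev$trace$values), 10, tolerance = 0.02)
  # width at half maximum of the first transient, by brute force on the grid
  t <- trace_time(ev$trace)
  first <- ev$ground_truth$event_times[1]
  in_evt <- t >= first & t < first + 10
  above <- t[in_evt][ev$trace$values[in_evt] >= 5]
  expect_equal(max(above) - min(above), 1.6, tolerance = 1 / 50 * 2)
})

test_that("drawn event intervals match the model mean within sampling error", {
  iv <- unlist(lapply(1:20, function(s) {
    gen_event_trace(duration = 600, seed = 40 + s)$ground_truth$intervals
  }))
  se <- 4.8 / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 15.8), 2 * se + 1e-9)
})

test_that("generators are bit-identical under a repeated seed", {
  a <- gen_event_trace(seed = 7); b <- gen_event_trace(seed = 7)
  expect_identical(a, b)
  p1 <- gen_photometry_pair(seed = 7); p2 <- gen_photometry_pair(seed = 7)
  expect_identical(p1, p2)
  v1 <- gen_vessel_stack(duration = 10, seed = 7)
  v2 <- gen_vessel_stack(duration = 10, seed = 7)
  expect_identical(v1, v2)
  e1 <- gen_eye_trace(seed = 7); e2 <- gen_eye_trace(seed = 7)
  expect_identical(e1, e2)
})

test_that("photometry ground-truth phase follows 180*mirror + lag/T*360", {
  p <- gen_photometry_pair(channel_lag = 0, mirror = TRUE, seed = 1)
  expect_equal(p$ground_truth$true_phase, 180)
  p <- gen_photometry_pair(channel_lag = 0.7433, mirror = TRUE, seed = 1)
  expect_equal(p$ground_truth$true_phase, 246.897, tolerance = 1e-4)
  expect_equal(dyfp_model()$channel_lag / 4 * 360 + 180, 184.4)
  expect_error(gen_photometry_pair(channel_lag = 4), "period")
})

test_that("noiseless generator outputs are reconstructible from ground truth", {
  stim <- stimulus_spec(duration = 120)
  ent <- entrainment_model(noise_sd = 0)
  p <- gen_photometry_pair(stim, ent, seed = 3)
  t <- trace_time(p$ch1)
  recon <- 100 * (1 + ent$locked_amplitude / 100 *
                    sin(2 * pi * 0.25 * t)) * exp(-t / ent$fade_tau)
  expect_equal(p$ch1$values, recon, tolerance = 1e-12)

  v <- gen_vessel_stack(duration = 2, noise_sd = 0, osc_amplitude = 10, seed = 5)
  gt <- v$ground_truth
  k <- 3
  prof_k <- gt$vessel_intensity * (gt$diameter_t[k] / gt$true_diameter) *
    sqrt(pmax(0, 1 - (2 * gt$x_positions / gt$diameter_t[k])^2)) *
    exp(-((k - 1) / 5) / gt$fade_tau) + gt$background
  expect_equal(as.numeric(v$stack$data[k, 1, ]), prof_k, tolerance = 1e-12)
})

test_that("vessel stacks record a sinusoidal true diameter when oscillating", {
  v <- gen_vessel_stack(duration = 8, osc_amplitude = 10, osc_freq = 0.25,
                        noise_sd = 0, seed = 2)
  t <- (seq_along(v$ground_truth$diameter_t) - 1) / 5
  expect_equal(v$ground_truth$diameter_t,
               45.7 * (1 + 0.10 * sin(2 * pi * 0.25 * t)), tolerance = 1e-12)
  expect_error(gen_vessel_stack(true_diameter = 3, pixel_size = 1), "4 pixels")
  expect_error(gen_vessel_stack(fov_width = 40), "field of view")
})

test_that("eye traces have the requested saccade structure", {
  ey <- gen_eye_trace(stimulus_spec(duration = 300), saccade_rate = 6,
                      noise_sd = 0.05, seed = 11)
  n_sac <- length(ey$ground_truth$saccade_times)
  # Poisson(30): count should be in a plausible range
  expect_gt(n_sac, 15); expect_lt(n_sac, 50)
  # every saccade produces an inter-frame step > 1 degree (brute force)
  steps <- abs(diff(ey$trace$values))
  step_times <- trace_time(ey$trace)[-1]
  hits <- vapply(ey$ground_truth$saccade_times, function(ts) {
    any(steps[abs(step_times - ts) < 2 / 30] > 1)
  }, logical(1))
  expect_true(all(hits))

  clean <- gen_eye_trace(gain = 1, phase_lag = 0, saccade_rate = 0,
                         drift_amp = 0, noise_sd = 0, seed = 1)
  stim <- gen_stimulus(stimulus_spec(), rate = 30)
  expect_equal(clean$trace$values, stim$values, tolerance = 1e-12)
  expect_error(gen_eye_trace(gain = 1.5), "gain")
})
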