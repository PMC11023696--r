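# Stack processing chain and the FW10M diameter readout.

test_that("background subtraction zeroes the flank ROIs frame by frame", {
  fx <- make_vessel_fixture(duration = 2, noise_sd = 0, seed = 1)
  # constant frame: everything collapses to zero
  const <- image_stack(array(7, dim = c(3, 4, 10)), 1, 5)
  out <- subtract_background(const, pixel_roi(1:4, 1:3), pixel_roi(1:4, 8:10))
  expect_equal(max(abs(out$data)), 0)
  # drifting background: post-subtraction flank means are 0 every frame
  drift <- fx$stack
  for (k in seq_len(n_frames(drift))) drift$data[k, , ] <- drift$data[k, , ] + k * 0.5
  sub <- subtract_background(drift, fx$left_roi, fx$right_roi)
  for (k in seq_len(n_frames(sub))) {
    frame <- sub$data[k, , ]
    expect_equal(mean(c(frame[fx$left_roi$rows, fx$left_roi$cols],
                        frame[fx$right_roi$rows, fx$right_roi$cols])), 0,
                 tolerance = 1e-9)
  }
  expect_error(subtract_background(const, pixel_roi(1:4, 1:3), pixel_roi(1:9, 8:10)),
               "outside")
})

test_that("fade baseline keeps the slow decay and rejects vasomotion-band content", {
  rate <- 5
  t <- (0:(600 * rate - 1)) / rate
  const <- trace_series(rep(3, length(t)), rate)
  expect_equal(fade_baseline(const)$values, rep(3, length(t)), tolerance = 1e-9)

  fade <- 100 * exp(-t / 600)
  tr <- trace_series(fade + 3 * sin(2 * pi * 0.25 * t), rate)
  out <- fade_baseline(tr)
  expect_lt(max(abs(out$values - fade) / fade), 0.01)

  # steady-state rejection at 50x the cutoff; the outermost ~2 filter
  # time constants see one-sided estimates with weaker rejection
  sine <- trace_series(sin(2 * pi * 0.25 * t), rate)
  interior <- (3 * 37.5 * rate):(length(t) - 3 * 37.5 * rate)
  expect_lt(max(abs(fade_baseline(sine)$values[interior])), 1e-3)

  expect_error(fade_baseline(trace_series(1:10, 5)), "time constants")
})

test_that("baseline normalization flattens a generator-imposed fade", {
  fx <- make_vessel_fixture(duration = 150, noise_sd = 0.5, seed = 3,
                            fade_tau = 300)
  sub <- subtract_background(fx$stack, fx$left_roi, fx$right_roi)
  vessel <- roi_mean_trace(sub, fx$vessel_roi)
  norm <- normalize_to_baseline(sub, fade_baseline(vessel))
  in_vessel <- roi_mean_trace(norm, fx$vessel_roi)
  fit <- stats::lm(v ~ t, data.frame(t = trace_time(in_vessel), v = in_vessel$values))
  expect_lt(abs(stats::coef(fit)[2]), 1e-4)   # fraction per second
  expect_error(normalize_to_baseline(sub, trace_series(rep(0, n_frames(sub)), 5)),
               "positive")
})

test_that("profile flattening removes a linear ramp and averaging reduces noise", {
  fx <- make_vessel_fixture(duration = 1, noise_sd = 0, seed = 1)
  sub <- subtract_background(fx$stack, fx$left_roi, fx$right_roi)
  base <- extract_profile(sub, fx$line_rows, smooth_sigma = 0)
  # add a ramp across x to every row of frame 1
  nx <- dim(sub$data)[3]
  ramp <- sub
  for (r in seq_len(dim(sub$data)[2])) {
    ramp$data[1, r, ] <- ramp$data[1, r, ] + 0.05 * seq_len(nx)
  }
  flat <- extract_profile(ramp, fx$line_rows, smooth_sigma = 0)
  expect_equal(flat$profiles[1, ], base$profiles[1, ], tolerance = 0.15)

  # row averaging: residual noise scales ~ 1/sqrt(k)
  set.seed(99)
  sd1 <- replicate(50, {
    st <- image_stack(array(rnorm(1 * 24 * 40), dim = c(1, 24, 40)), 1, 5)
    sd(extract_profile(st, 1:24, smooth_sigma = 0, flank_frac = 0.05)$profiles[1, ])
  })
  expect_equal(mean(sd1), 1 / sqrt(24), tolerance = 0.15)
})

test_that("FW10M matches closed forms and is scale invariant", {
  # rectangular profile of width 40 um
  pos <- seq(0, 100, by = 1)
  rect <- as.numeric(pos >= 30 & pos < 70)
  m <- fw10m_diameter(rect, pos)
  expect_equal(m$diameter_fw10m, 40, tolerance = 1)

  # projected cylinder: FW10M = sqrt(0.99) * d
  d <- 20
  x <- seq(-15, 15, by = 0.01)
  prof <- sqrt(pmax(0, 1 - (2 * x / d)^2))
  m <- fw10m_diameter(prof, x)
  expect_equal(m$diameter_fw10m, sqrt(0.99) * d, tolerance = 0.02)
  expect_equal(m$diameter_fw10m, 19.90, tolerance = 0.02)

  # positive scaling leaves the width untouched
  m2 <- fw10m_diameter(137.5 * prof, x)
  expect_equal(m2$diameter_fw10m, m$diameter_fw10m, tolerance = 1e-9)
  expect_equal(m2$peak_intensity, 137.5 * m$peak_intensity, tolerance = 1e-9)

  # threshold never crossed on a flank -> not measurable
  half <- prof[x <= 5]
  expect_false(fw10m_diameter(half, x[x <= 5])$measurable)
})

test_that("diameter estimator recovers the true diameter on noiseless stacks", {
  fx <- make_vessel_fixture(duration = 2, noise_sd = 0, seed = 4)
  sub <- subtract_background(fx$stack, fx$left_roi, fx$right_roi)
  profs <- extract_profile(sub, fx$line_rows, smooth_sigma = 0)
  m <- fw10m_diameter(profs$profiles[1, ], profs$position)
  expect_equal(m$diameter_fw10m / sqrt(0.99), 45.7, tolerance = 1)
})

test_that("diameter and peak-intensity series track an oscillating vessel together", {
  fx <- make_vessel_fixture(duration = 160, noise_sd = 0.5, seed = 6,
                            osc_amplitude = 8, osc_freq = 0.25)
  res <- diameter_and_peak_series(fx$stack, fx$left_roi, fx$right_roi,
                                  fx$vessel_roi, fx$line_rows)
  expect_true(all(res$measurable))
  # recovered diameter series oscillates at the driving frequency
  spec <- amplitude_spectrum(trace_series(res$diameter$values - mean(res$diameter$values), 5))
  expect_equal(spec$frequencies[which.max(spec$amplitudes)], 0.25)
  # diameter and in-profile peak intensity are positively correlated
  expect_gt(stats::cor(res$diameter$values, res$peak$values), 0.8)
  # relative series sit around 100% of basal
  expect_equal(stats::median(res$diameter$values), 100, tolerance = 10)
})

test_that("a constant vessel yields flat 100% series", {
  fx <- make_vessel_fixture(duration = 120, noise_sd = 0.2, seed = 8)
  res <- diameter_and_peak_series(fx$stack, fx$left_roi, fx$right_roi,
                                  fx$vessel_roi, fx$line_rows)
  expect_equal(mean(res$diameter$values), 100, tolerance = 2)
  expect_equal(mean(res$peak$values), 100, tolerance = 2)
  expect_lt(stats::sd(res$diameter$values), 3)
})
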