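# Percent normalization, amplitude spectra, spectrograms, PR and PR maps.

test_that("percent normalization recovers modulations and rejects fades", {
  rate <- 5
  t <- (0:(300 * rate - 1)) / rate
  const <- trace_series(rep(42, length(t)), rate)
  expect_lt(max(abs(normalize_percent(const)$values)), 1e-9)

  mod <- 5 * sin(2 * pi * 0.25 * t)
  out <- normalize_percent(make_raw_trace(mod))
  # amplitude preserved within 2% relative error
  sp <- amplitude_spectrum(out)
  expect_equal(sp$amplitudes[which.min(abs(sp$frequencies - 0.25))], 5,
               tolerance = 0.1)

  fady <- trace_series(100 * exp(-t / 600) * (1 + mod / 100), rate)
  outf <- normalize_percent(fady)
  fit <- stats::lm(v ~ t, data.frame(t = t / 60, v = outf$values))
  expect_lt(abs(stats::coef(fit)[2]), 0.01)   # % per minute

  expect_error(normalize_percent(trace_series(c(rep(1, 600), -1), 5)), "positive")
  expect_error(normalize_percent(trace_series(rep(1, 100), 5)), "60 s")
})

test_that("amplitude spectrum is exactly calibrated and satisfies Parseval", {
  rate <- 5
  t <- (0:(300 * rate - 1)) / rate
  tr <- trace_series(3 * sin(2 * pi * 0.25 * t), rate, units = "%")
  sp <- amplitude_spectrum(tr)
  i0 <- which(sp$frequencies == 0.25)
  expect_length(i0, 1)
  expect_equal(sp$amplitudes[i0], 3, tolerance = 1e-9)
  expect_equal(sp$frequencies[which.max(sp$amplitudes)], 0.25)

  # Parseval: mean square equals DC^2 + sum(A^2)/2 (+ Nyquist term)
  set.seed(1)
  x <- rnorm(1000)
  spx <- amplitude_spectrum(trace_series(x, rate))
  a <- spx$amplitudes
  n <- length(x)
  rhs <- a[1]^2 + sum(a[2:(length(a) - 1)]^2) / 2 + a[length(a)]^2
  expect_equal(mean(x^2), rhs, tolerance = 1e-6)

  expect_error(amplitude_spectrum(trace_series(c(1, NA, 3), 5)), "NaN")
})

test_that("white noise shows no stimulus-band peak structure", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    sp <- amplitude_spectrum(trace_series(rnorm(1500), 5))
    pr <- peak_ratio(sp, f0 = 0.25)
    pr$pr > 5
  }, logical(1))
  expect_lt(mean(hits), 0.01 + 1e-9)
})

test_that("spectrogram has the documented bin count and is stable on stationary input", {
  rate <- 5
  t <- (0:(900 * rate - 1)) / rate
  tr <- trace_series(3 * sin(2 * pi * 0.25 * t), rate, units = "%")
  sg <- spectrogram(tr, window = 60, step = 4)
  expect_equal(length(sg$times), floor((900 - 60) / 4) + 1)
  expect_equal(length(sg$times), 211)
  row025 <- sg$amplitudes[, which(sg$frequencies == 0.25)]
  expect_lt(stats::sd(row025) / mean(row025), 0.05)
  expect_error(spectrogram(trace_series(1:100, 5), window = 60), "duration")
})

test_that("intermittent lock shows up as bimodal stimulus-band power over time", {
  pp <- gen_photometry_pair(stimulus_spec(duration = 900),
                            entrainment_model(lock_fraction = 0.5), seed = 31)
  norm <- normalize_percent(pp$ch1)
  sg <- spectrogram(norm, window = 40, step = 4)
  row025 <- sg$amplitudes[, which.min(abs(sg$frequencies - 0.25))]
  ep <- pp$ground_truth$lock_epochs
  centre_locked <- vapply(sg$times, function(tt) {
    i <- findInterval(tt, ep$start); ep$locked[max(i, 1)]
  }, logical(1))
  expect_gt(mean(row025[centre_locked]), 2 * mean(row025[!centre_locked]))
})

test_that("peak ratio follows bin arithmetic and is scale invariant", {
  flat <- structure(list(frequencies = seq(0, 2.5, by = 0.01),
                         amplitudes = rep(0.7, 251), rate = 5, n = 500,
                         duration = 100), class = "spectral_result")
  expect_equal(peak_ratio(flat)$pr, 1)

  # f0 bin = 10, other B-1 bins = 1 -> pr = 10 B / (B + 9)
  f <- seq(0, 2.5, by = 0.05)
  amps <- rep(1, length(f))
  B <- sum(f >= 0.1 & f <= 1)
  amps[which(f == 0.25)] <- 10
  spec <- structure(list(frequencies = f, amplitudes = amps, rate = 5,
                         n = 100, duration = 20), class = "spectral_result")
  expect_equal(peak_ratio(spec)$pr, 10 * B / (B + 9), tolerance = 1e-12)

  spec2 <- spec; spec2$amplitudes <- spec$amplitudes * 3.7
  expect_equal(peak_ratio(spec2)$pr, peak_ratio(spec)$pr, tolerance = 1e-12)

  expect_error(peak_ratio(spec, f0 = 2), "band")
})

test_that("PR grows monotonically with locked amplitude at fixed noise", {
  prs <- vapply(c(0.5, 1.5, 3, 6), function(a) {
    pp <- gen_photometry_pair(stimulus_spec(duration = 300),
                              entrainment_model(locked_amplitude = a), seed = 77)
    peak_ratio(amplitude_spectrum(normalize_percent(pp$ch1)))$pr
  }, numeric(1))
  expect_true(all(diff(prs) > 0))
})

test_that("the PR map separates an entrained half-field from noise", {
  # small stack built in code: left half carries a locked 0.25 Hz signal
  rate <- 5; nf <- 1500; ny <- 8; nx <- 16
  t <- (0:(nf - 1)) / rate
  osc <- 4 * sin(2 * pi * 0.25 * t)
  set.seed(5)
  dat <- array(rnorm(nf * ny * nx, sd = 1), dim = c(nf, ny, nx)) + 100
  for (ix in 1:(nx / 2)) dat[, , ix] <- dat[, , ix] + osc
  st <- image_stack(dat, pixel_size = 20, frame_rate = rate)
  pm <- pr_map(st, sigma_um = 20, f0 = 0.25)
  left <- mean(pm$map[, 1:(nx / 2 - 2)])
  right <- mean(pm$map[, (nx / 2 + 3):nx])
  expect_gt(left, 2 * right)
  # uniformly entrained field: spatially homogeneous map
  dat2 <- array(rnorm(nf * ny * nx, sd = 0.5), dim = c(nf, ny, nx)) + 100 +
    rep(osc, ny * nx)
  pm2 <- pr_map(image_stack(dat2, 20, rate), sigma_um = 20)
  expect_lt(stats::sd(pm2$map) / mean(pm2$map), 0.1)
})

test_that("pulse averaging yields the 5 Hz effective rate", {
  raw_rate <- 1000
  t <- (0:(10 * raw_rate - 1)) / raw_rate
  tr <- trace_series(sin(2 * pi * 0.25 * t), raw_rate)
  out <- pulse_average(tr, pulse = 0.020, interval = 0.180)
  expect_equal(out$rate, 5)
  expect_equal(length(out$values), 50)
})
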