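# Cross-correlation lags, lag-to-phase conversion, segment averaging,
# sine fitting, and PR-based segment selection.

test_that("cross-correlation finds anti-phase and delayed-mirror lags", {
  rate <- 5
  t <- (0:(300 * rate - 1)) / rate
  set.seed(3)
  a <- trace_series(sin(2 * pi * 0.25 * t) + 0.3 * rnorm(length(t)), rate)
  b <- trace_series(-a$values, rate)
  expect_equal(crosscorr_lag(a, b)$delta_t, 0)

  # b = -a delayed by 0.6 s (3 samples at 5 Hz), constructed by shifting
  v <- -c(rep(0, 3), a$values[1:(length(t) - 3)])
  b2 <- trace_series(v, rate)
  expect_equal(crosscorr_lag(a, b2)$delta_t, 0.6)

  # broadband positively correlated pair: no negative peak -> excluded
  set.seed(4)
  n <- 1500
  base <- stats::filter(rnorm(n + 50), rep(1, 25) / 25, sides = 1)[51:(n + 50)]
  p1 <- trace_series(as.numeric(base) + 0.05 * rnorm(n), rate)
  p2 <- trace_series(as.numeric(base) + 0.05 * rnorm(n), rate)
  res <- crosscorr_lag(p1, p2, max_lag = 2)
  expect_true(res$excluded)
  expect_true(is.na(res$delta_t))

  expect_error(crosscorr_lag(a, trace_series(1:10, rate)), "length")
})

test_that("lag-to-phase conversion and its antisymmetry hold", {
  expect_equal(phase_from_lag(0, 4), 180)
  expect_equal(phase_from_lag(0.8, 4), 252)
  expect_error(phase_from_lag(1, 0), "cycle")
  expect_error(phase_from_lag(5, 4), "delta_t")
  # antisymmetry about 180: phase(dt) + phase(-dt) = 360 (mod 360)
  for (dt in c(0.2, 0.4, 1.1, 2.7, -3.3)) {
    s <- (phase_from_lag(dt, 4) + phase_from_lag(-dt, 4)) %% 360
    expect_equal(s, 0, tolerance = 1e-9)
  }
})

test_that("phase recovery on noiseless generator pairs is lag-quantization exact", {
  rate <- 5; cycle <- 4
  quantum <- 360 * (1 / rate) / cycle
  for (theta in c(90, 180, 252, 270)) {
    mirror <- TRUE
    lag <- channel_lag_for_phase(theta, cycle, mirror = mirror)
    pp <- gen_photometry_pair(stimulus_spec(duration = 300),
                              entrainment_model(noise_sd = 0),
                              channel_lag = lag, mirror = mirror, seed = 1)
    n1 <- normalize_percent(pp$ch1); n2 <- normalize_percent(pp$ch2)
    est <- phase_from_lag(crosscorr_lag(n1, n2, max_lag = cycle)$delta_t, cycle)
    d <- abs(((est - theta + 180) %% 360) - 180)
    expect_lte(d, quantum + 1e-6)
  }
})

test_that("segment averaging cuts cycle-aligned segments", {
  rate <- 5
  t <- (0:(300 * rate - 1)) / rate
  tr <- trace_series(sin(2 * pi * 0.25 * t), rate)
  seg <- segment_average(tr, cycle = 4)
  expect_equal(seg$count, 75)
  # cycle-locked input: the mean segment equals any single segment
  expect_equal(seg$mean_segment, seg$segments[, 10], tolerance = 1e-9)

  # noise averages down ~ 1/sqrt(count)
  resid <- vapply(1:50, function(s) {
    set.seed(400 + s)
    trn <- trace_series(sin(2 * pi * 0.25 * t) + rnorm(length(t)), rate)
    sa <- segment_average(trn, cycle = 4)
    stats::sd(sa$mean_segment - seg$mean_segment)
  }, numeric(1))
  expect_equal(mean(resid), 1 / sqrt(75), tolerance = 0.1)

  expect_error(segment_average(tr, cycle = 4.0001), "commensurate")
  expect_error(segment_average(tr, cycle = 4, analysis_window = 400), "duration")
})

test_that("fixed-frequency sine fit is exact on noiseless input", {
  rate <- 30; cycle <- 4
  t <- (0:(cycle * rate - 1)) / rate
  stim <- sin(2 * pi * t / cycle)
  expect_equal(sine_fit_phase(stim, cycle, rate)$phase_deg, 0, tolerance = 1e-9)

  delayed <- sin(2 * pi * (t - 0.1) / cycle)
  fit <- sine_fit_phase(delayed, cycle, rate)
  expect_equal(fit$phase_deg, 9, tolerance = 1e-9)
  expect_equal(fit$amplitude, 1, tolerance = 1e-9)

  shifted <- 2.5 + 3 * sin(2 * pi * (t - 0.5) / cycle)
  fit2 <- sine_fit_phase(shifted, cycle, rate)
  expect_equal(fit2$offset, 2.5, tolerance = 1e-9)
  expect_equal(fit2$amplitude, 3, tolerance = 1e-9)
  expect_equal(fit2$phase_deg, 45, tolerance = 1e-9)

  flatfit <- sine_fit_phase(rep(1, length(t)), cycle, rate)
  expect_true(flatfit$flagged)
  expect_equal(flatfit$amplitude, 0)
})

test_that("PR-based segment selection tracks the lock fraction", {
  # fully locked: every window kept
  full <- gen_photometry_pair(stimulus_spec(duration = 600), seed = 9)
  sel <- select_entrained_segments(normalize_percent(full$ch1))
  expect_true(all(sel$kept))

  # lock fraction 0.5: kept fraction in a plausible band around 0.5
  half <- gen_photometry_pair(stimulus_spec(duration = 900),
                              entrainment_model(lock_fraction = 0.5), seed = 10)
  selh <- select_entrained_segments(normalize_percent(half$ch1))
  expect_gt(mean(selh$kept), 0.2); expect_lt(mean(selh$kept), 0.8)

  # pure noise: kept fraction matches the Monte-Carlo null exceedance rate
  kept_noise <- unlist(lapply(1:10, function(s) {
    pp <- gen_photometry_pair(stimulus_spec(duration = 600),
                              entrainment_model(lock_fraction = 0), seed = 60 + s)
    select_entrained_segments(normalize_percent(pp$ch1))$kept
  }))
  null_rate <- mean(vapply(1:200, function(s) {
    set.seed(7000 + s)
    spec <- amplitude_spectrum(trace_series(rnorm(200), 5))
    peak_ratio(spec)$pr > 3
  }, logical(1)))
  expect_lt(abs(mean(kept_noise) - null_rate), 0.1)
})
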