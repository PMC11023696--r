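# Zero-phase frequency-domain filtering. All baseline / drift filters in the
# package go through fft_filter(): the signal is extended by reflection at
# both ends (to suppress wrap-around transients), transformed, multiplied by
# a real, even magnitude response, and transformed back. A real symmetric
# response applied this way is exactly zero-phase, which matters because the
# whole phase-analysis module depends on filters not shifting signals in time.

reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad < 1L) return(x)
  c(rev(x[2:(n_pad + 1L)]), x, rev(x[(n - n_pad):(n - 1L)]))
}

fft_filter <- function(x, rate, gain_fun) {
  n <- length(x)
  n_pad <- min(n - 1L, n)
  xp <- reflect_pad(x, n_pad)
  m <- length(xp)
  f <- (seq_len(m) - 1L) / m * rate
  f <- pmin(f, rate - f)            # fold to [0, Nyquist]
  h <- gain_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / m
  y[(n_pad + 1L):(n_pad + n)]
}

# Gaussian low-pass with half-power gain at `cutoff` Hz, realized as a
# Gaussian-weighted local linear regression (the impulse-response sigma is
# sqrt(2 ln 2) / (2 pi cutoff)). Interior samples see the plain Gaussian
# smoother; at the edges the local line keeps slow trends extrapolating
# correctly and rejects oscillations an order better than reflection
# padding, which matters because this filter estimates baselines under
# large vasomotion oscillations.
gaussian_lowpass <- function(x, rate, cutoff) {
  sigma <- sqrt(2 * log(2)) / (2 * pi * cutoff) * rate   # samples
  half <- ceiling(4 * sigma)
  d <- (-half):half
  w <- exp(-d^2 / (2 * sigma^2))
  n <- length(x)
  corr <- function(v, k) {
    vp <- c(rep(0, half), v, rep(0, half))
    out <- stats::filter(vp, rev(k), sides = 2)
    as.numeric(out[(half + 1L):(half + n)])
  }
  ones <- rep(1, n)
  s0 <- corr(ones, w)
  s1 <- corr(ones, w * d)
  s2 <- corr(ones, w * d^2)
  t0 <- corr(x, w)
  t1 <- corr(x, w * d)
  (s2 * t0 - s1 * t1) / (s0 * s2 - s1^2)
}

# Unity gain up to `passband`, raised-cosine roll-off, zero beyond `stopband`.
cosine_lowpass <- function(x, rate, passband, stopband) {
  stopifnot(stopband > passband, passband >= 0)
  fft_filter(x, rate, function(f) {
    h <- numeric(length(f))
    h[f <= passband] <- 1
    tr <- f > passband & f < stopband
    h[tr] <- 0.5 * (1 + cos(pi * (f[tr] - passband) / (stopband - passband)))
    h
  })
}

# Band-pass with raised-cosine transitions (stop_lo -> pass_lo and
# pass_hi -> stop_hi); unity gain inside [pass_lo, pass_hi], zero outside
# [stop_lo, stop_hi]. DC is always removed.
cosine_bandpass <- function(x, rate, pass_lo, pass_hi, stop_lo = pass_lo / 2,
                            stop_hi = pass_hi * 1.2) {
  stopifnot(stop_lo < pass_lo, pass_lo < pass_hi, pass_hi < stop_hi)
  fft_filter(x, rate, function(f) {
    h <- numeric(length(f))
    h[f >= pass_lo & f <= pass_hi] <- 1
    lo <- f > stop_lo & f < pass_lo
    h[lo] <- 0.5 * (1 - cos(pi * (f[lo] - stop_lo) / (pass_lo - stop_lo)))
    hi <- f > pass_hi & f < stop_hi
    h[hi] <- 0.5 * (1 + cos(pi * (f[hi] - pass_hi) / (stop_hi - pass_hi)))
    h
  })
}

# 1-D Gaussian smoothing along a vector (sigma in samples), edge-replicated.
gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}
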