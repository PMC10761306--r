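# synthesize narrowband RF with a known modulating envelope
make_rf <- function(env_fn, fs = 40, fc = 8, n = 512, n_lines = 4,
                    phase = 0) {
  t <- (seq_len(n) - 1) / fs
  a <- env_fn(t)
  matrix(rep(a * cos(2 * pi * fc * t + phase), n_lines), n, n_lines)
}

interior <- function(n, frac = 0.8) {
  k <- floor(n * (1 - frac) / 2)
  (k + 1):(n - k)
}

test_that("Butterworth design matches the independent reference", {
  # scipy.signal.butter(4, 0.3), frozen
  f <- butter_lowpass(4, 0.3)
  expect_equal(f$b, c(0.018563010627, 0.074252042508, 0.111378063761,
                      0.074252042508, 0.018563010627), tolerance = 1e-9)
  expect_equal(f$a, c(1.0, -1.570398851228, 1.275613324983, -0.484403368335,
                      0.076197064610), tolerance = 1e-9)
  # scipy.signal.filtfilt on x = cumsum(sin(1:64)), interior values frozen
  x <- cumsum(sin(1:64))
  y <- filtfilt(f$b, f$a, x)
  expect_equal(y[c(32, 33)], c(0.7376289106, 1.1017078057), tolerance = 1e-5)
  # edges agree loosely (different edge-transient handling than the reference)
  expect_equal(y[c(1, 64)], c(0.8410370500, 1.0105905740), tolerance = 2e-2)
})

test_that("quadrature demodulation recovers known envelopes", {
  # constant-amplitude tone: plateau within 1 %
  rf <- rf_frame(make_rf(function(t) rep(2.5, length(t))), 40, 8)
  env <- quadrature_demodulate(rf)
  expect_equal(dim(env$values), dim(rf$samples))
  idx <- interior(512)
  expect_lt(max(abs(env$values[idx, ] - 2.5)) / 2.5, 0.01)
  # all-zero frame
  z <- quadrature_demodulate(rf_frame(matrix(0, 64, 3), 40, 8))
  expect_true(all(z$values == 0))
  # linear amplitude ramp tracked within 1 % of full scale
  ramp <- function(t) 0.5 + t / max(t)
  rfr <- rf_frame(make_rf(ramp), 40, 8)
  er <- quadrature_demodulate(rfr)
  t <- (seq_len(512) - 1) / 40
  expect_lt(max(abs(er$values[idx, 1] - ramp(t)[idx])) / max(ramp(t)), 0.01)
})

test_that("Hilbert envelope recovers known envelopes", {
  # 102 whole carrier cycles in the window (no spectral leakage)
  fc <- 40 * 102 / 512
  rf <- rf_frame(make_rf(function(t) rep(1.3, length(t)), fc = fc), 40, fc)
  env <- hilbert_envelope(rf)
  idx <- interior(512)
  expect_lt(max(abs(env$values[idx, ] - 1.3)) / 1.3, 0.01)
  # narrowband Gaussian-windowed pulse tracks the Gaussian window
  gauss <- function(t) exp(-((t - 6.4)^2) / (2 * 1.6^2))
  eg <- hilbert_envelope(rf_frame(make_rf(gauss), 40, 8))
  t <- (seq_len(512) - 1) / 40
  expect_lt(max(abs(eg$values[idx, 1] - gauss(t)[idx])), 0.01)
  expect_error(hilbert_envelope(matrix(0, 4, 2)), "8 samples")
})

test_that("the two envelope routes agree on narrowband RF", {
  set.seed(3)
  envf <- function(t) 1 + 0.5 * sin(2 * pi * 0.3 * t)
  rf <- rf_frame(make_rf(envf, phase = 0.7), 40, 8)
  e1 <- quadrature_demodulate(rf)$values
  e2 <- hilbert_envelope(rf)$values
  idx <- interior(512)
  rms <- sqrt(mean((e1[idx, ] - e2[idx, ])^2)) / sqrt(mean(e2[idx, ]^2))
  expect_lt(rms, 0.02)
})

test_that("log compression maps the documented anchor points", {
  env <- matrix(c(1, 0.1, 10^(-40 / 20), 1e-6, 0), 5, 1)
  img <- log_compress(envelope_image(env), dynamic_range = 40)
  expect_equal(img$values[1, 1], 1)                 # max -> 1
  expect_equal(img$values[2, 1], 0.5)               # max/10, DR 40 -> 0.5
  expect_equal(img$values[3, 1], 0)                 # exactly at -DR
  expect_equal(img$values[4, 1], 0)                 # below clip
  expect_equal(img$values[5, 1], 0)                 # zero pixel
  z <- log_compress(matrix(0, 4, 4), 50)
  expect_true(all(z$values == 0))
})

test_that("envelope and compression invariants hold", {
  set.seed(4)
  envf <- function(t) 1 + 0.4 * cos(2 * pi * 0.2 * t)
  x <- make_rf(envf, fc = 11, fs = 50)
  # sign-flip invariance of envelopes
  e1 <- hilbert_envelope(rf_frame(x, 50, 11))$values
  e2 <- hilbert_envelope(rf_frame(-x, 50, 11))$values
  expect_equal(e1, e2)
  expect_true(all(e1 >= 0))
  q1 <- quadrature_demodulate(rf_frame(x, 50, 11))$values
  q2 <- quadrature_demodulate(rf_frame(-x, 50, 11))$values
  expect_equal(q1, q2, tolerance = 1e-12)
  # amplitude recovery across carriers in (0, Nyquist)
  for (fc in c(2, 5, 14, 20)) {
    rf <- rf_frame(make_rf(function(t) rep(1, length(t)), fs = 50, fc = fc), 50, fc)
    ev <- hilbert_envelope(rf)$values
    expect_lt(max(abs(ev[interior(512), 1] - 1)), 0.02)
  }
  # log compression: monotone and scale invariant
  env <- matrix(runif(100, 0, 3), 10, 10)
  i1 <- log_compress(env, 50)$values
  i2 <- log_compress(2.7 * env, 50)$values
  expect_equal(i1, i2)
  o <- order(env)
  expect_true(all(diff(i1[o]) >= -1e-12))
  # Nyquist violation rejected
  expect_error(rf_frame(matrix(0, 16, 1), 10, 8), "Nyquist")
})
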