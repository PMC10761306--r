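# Signal-processing primitives: Butterworth low-pass design, zero-phase
# filtering, and the analytic-signal envelope. Implemented here because the
# environment ships no DSP package; designs follow the textbook bilinear
# transform and are cross-checked against an independent reference in the
# test suite.

# roots -> monic polynomial coefficients (descending powers)
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth low-pass filter design
#'
#' Digital Butterworth low-pass of order `n` with cutoff `Wn` expressed as a
#' fraction of the Nyquist frequency, via analog prototype poles and the
#' bilinear transform. DC gain is exactly 1.
#'
#' @param n filter order.
#' @param Wn cutoff in (0, 1), fraction of Nyquist.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(n, Wn) {
  stopifnot(n >= 1, Wn > 0, Wn < 1)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # left half-plane
  wc <- 2 * tan(pi * Wn / 2)                          # prewarped (fs = 1)
  p <- wc * proto
  zp <- (2 + p) / (2 - p)                             # bilinear poles
  a <- Re(poly_from_roots(zp))
  b0 <- poly_from_roots(rep(-1, n))                   # n zeros at z = -1
  b <- b0 * sum(a) / sum(b0)
  list(b = b, a = a)
}

# Direct-form II transposed IIR filter, zero initial conditions.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  n <- length(a)
  z <- numeric(n - 1)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in seq_len(n - 2)) z[j] <- b[j + 1] * xi - a[j + 1] * yi + z[j + 1]
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase filtering
#'
#' Applies the filter forward and backward with odd-reflection edge padding,
#' cancelling the phase response.
#' @param b,a filter coefficients from [butter_lowpass()].
#' @param x numeric vector.
#' @export
filtfilt <- function(b, a, x) {
  nx <- length(x)
  pad <- min(nx - 1L, 9L * max(length(a), length(b)))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[nx] - x[seq(nx - 1L, nx - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[pad + seq_len(nx)]
}

# Analytic-signal envelope of one real-valued line via FFT.
hilbert_env_line <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
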