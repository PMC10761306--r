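#' Beamformed RF frame
#'
#' A 2-D real-valued array of beamformed RF data, axial samples in rows and
#' lateral scan lines in columns, with its sampling and carrier frequencies.
#' The sampling rate must satisfy Nyquist for the carrier.
#'
#' @param samples numeric matrix (axial samples x lateral lines).
#' @param sampling_rate sampling rate, MHz.
#' @param carrier_frequency transducer carrier frequency, MHz.
#' @return an object of class `usn_rf`.
#' @export
rf_frame <- function(samples, sampling_rate, carrier_frequency) {
  stopifnot(is.matrix(samples), sampling_rate > 0, carrier_frequency > 0)
  if (!all(is.finite(samples))) stop("RF samples must be finite")
  if (sampling_rate <= 2 * carrier_frequency) {
    stop("Nyquist violation: sampling_rate must exceed 2 * carrier_frequency")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 carrier_frequency = carrier_frequency), class = "usn_rf")
}

#' Envelope image
#'
#' Non-negative envelope amplitudes on the image grid.
#' @param values non-negative numeric matrix.
#' @param pixel_spacing optional `(axial, lateral)` spacing in cm.
#' @export
envelope_image <- function(values, pixel_spacing = c(NA_real_, NA_real_)) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("envelope values must be non-negative")
  structure(list(values = values, pixel_spacing = pixel_spacing),
            class = "usn_envelope")
}

#' B-scan (display) image
#'
#' Log-compressed image with values in `[0, 1]`.
#' @param values numeric matrix in `[0, 1]`.
#' @param dynamic_range displayed dynamic range, dB.
#' @export
bscan_image <- function(values, dynamic_range) {
  stopifnot(is.matrix(values), dynamic_range > 0)
  if (any(values < 0 | values > 1)) stop("B-scan values must lie in [0, 1]")
  structure(list(values = values, dynamic_range = dynamic_range),
            class = "usn_bscan")
}

#' Quadrature (IQ) demodulation envelope
#'
#' Mixes every RF line with in-phase and quadrature references at the carrier
#' frequency, low-pass filters the complex baseband with a zero-phase
#' 4th-order Butterworth, and returns twice its magnitude (so a tone
#' `A*cos(2*pi*fc*t)` recovers amplitude `A`). Output shape equals the input.
#'
#' @param rf a [rf_frame()].
#' @param lpf_cutoff low-pass cutoff, MHz; default half the carrier.
#' @return an [envelope_image()].
#' @export
quadrature_demodulate <- function(rf, lpf_cutoff = rf$carrier_frequency / 2) {
  stopifnot(inherits(rf, "usn_rf"))
  fs <- rf$sampling_rate
  if (lpf_cutoff >= fs / 2) stop("lpf_cutoff must be below Nyquist (sampling_rate/2)")
  x <- rf$samples
  n <- nrow(x)
  t <- (seq_len(n) - 1) / fs
  ref <- exp(-2i * pi * rf$carrier_frequency * t)
  flt <- butter_lowpass(4, lpf_cutoff / (fs / 2))
  env <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    z <- x[, j] * ref
    zi <- filtfilt(flt$b, flt$a, Re(z))
    zq <- filtfilt(flt$b, flt$a, Im(z))
    env[, j] <- 2 * sqrt(zi^2 + zq^2)
  }
  envelope_image(env)
}

#' Hilbert-transform envelope
#'
#' Per-line magnitude of the analytic signal; the standard route for
#' photoacoustic envelope detection from beamformed data.
#'
#' @param rf a [rf_frame()] or a plain numeric matrix (lines in columns).
#' @return an [envelope_image()].
#' @export
hilbert_envelope <- function(rf) {
  x <- if (inherits(rf, "usn_rf")) rf$samples else rf
  stopifnot(is.matrix(x))
  if (nrow(x) < 8L) stop("each line must have at least 8 samples")
  env <- apply(x, 2, hilbert_env_line)
  envelope_image(env)
}

#' Logarithmic compression
#'
#' Maps an envelope to display brightness: `20*log10(env/max(env))`, clipped
#' at `-dynamic_range` dB and rescaled linearly to `[0, 1]`. The maximum
#' pixel maps to 1; pixels at or below the clip level map to 0; an all-zero
#' envelope yields an all-zero image.
#'
#' @param env an [envelope_image()] or non-negative matrix.
#' @param dynamic_range dynamic range in dB (> 0); default 50.
#' @return a [bscan_image()].
#' @export
log_compress <- function(env, dynamic_range = 50) {
  v <- if (inherits(env, "usn_envelope")) env$values else env
  stopifnot(is.matrix(v), dynamic_range > 0)
  m <- max(v)
  if (m == 0) return(bscan_image(v, dynamic_range))
  db <- matrix(-Inf, nrow(v), ncol(v))
  pos <- v > 0
  db[pos] <- 20 * log10(v[pos] / m)
  db <- pmax(db, -dynamic_range)
  bscan_image((db + dynamic_range) / dynamic_range, dynamic_range)
}
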