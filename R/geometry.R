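#' Acquisition geometry of the dual-modal US/PA system
#'
#' Holds the scanner and laser parameters of the interleaved ultrasound /
#' photoacoustic acquisition and exposes the derived quantities: frame rate,
#' surface fluence, maximum recording duration and lateral field of view.
#' Defaults describe a 128-element 8 MHz linear array driven by a 10 Hz
#' pulsed laser with 64 parallel receive channels.
#'
#' @param n_elements number of transducer elements.
#' @param element_width element width, cm.
#' @param center_frequency transducer center frequency, MHz.
#' @param fractional_bandwidth fractional bandwidth in (0, 1].
#' @param imaging_depth configured imaging depth, cm.
#' @param sound_speed assumed speed of sound, m/s.
#' @param laser_prf laser pulse repetition frequency, Hz.
#' @param n_channels number of receive channels to fill per frame.
#' @param n_parallel_rx parallel data-acquisition channels per laser pulse.
#' @param pulse_energy laser pulse energy, mJ.
#' @param coupling_efficiency fiber coupling/transmission efficiency in (0, 1].
#' @param illumination_area illuminated surface area, cm^2.
#' @param max_frames maximum number of frames storable in one recording.
#' @return an object of class `usn_geometry`.
#' @export
#' @examples
#' g <- acquisition_geometry()
#' frame_rate(g)       # 5 Hz
#' surface_fluence(g)  # ~8.33 mJ/cm^2
acquisition_geometry <- function(n_elements = 128L, element_width = 0.03,
                                 center_frequency = 8, fractional_bandwidth = 0.95,
                                 imaging_depth = 2, sound_speed = 1540,
                                 laser_prf = 10, n_channels = 128L,
                                 n_parallel_rx = 64L, pulse_energy = 100,
                                 coupling_efficiency = 0.25,
                                 illumination_area = 3, max_frames = 500L) {
  g <- list(n_elements = as.integer(n_elements), element_width = element_width,
            center_frequency = center_frequency,
            fractional_bandwidth = fractional_bandwidth,
            imaging_depth = imaging_depth, sound_speed = sound_speed,
            laser_prf = laser_prf, n_channels = as.integer(n_channels),
            n_parallel_rx = as.integer(n_parallel_rx),
            pulse_energy = pulse_energy,
            coupling_efficiency = coupling_efficiency,
            illumination_area = illumination_area,
            max_frames = as.integer(max_frames))
  counts <- c("n_elements", "n_channels", "n_parallel_rx")
  if (any(vapply(g[counts], function(x) x < 1L, logical(1)))) {
    stop("all channel/element counts must be >= 1")
  }
  if (g$max_frames < 0L) stop("max_frames must be >= 0")
  phys <- c("element_width", "center_frequency", "imaging_depth",
            "sound_speed", "laser_prf", "pulse_energy", "illumination_area")
  if (any(vapply(g[phys], function(x) !is.finite(x) || x <= 0, logical(1)))) {
    stop("all physical quantities must be finite and > 0")
  }
  for (r in c("fractional_bandwidth", "coupling_efficiency")) {
    if (g[[r]] <= 0 || g[[r]] > 1) stop(sprintf("%s must lie in (0, 1]", r))
  }
  if (g$n_parallel_rx > g$n_channels) stop("n_parallel_rx must be <= n_channels")
  structure(g, class = "usn_geometry")
}

#' @export
print.usn_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<usn_geometry> %d-element %.1f MHz array, depth %.1f cm\n",
    "  frame rate %.3g Hz | fluence %.3g mJ/cm^2 | max recording %.3g s | lateral FOV %.3g cm\n"),
    x$n_elements, x$center_frequency, x$imaging_depth,
    frame_rate(x), surface_fluence(x), max_recording_seconds(x), lateral_fov(x)))
  invisible(x)
}

#' Imaging frame rate
#'
#' One frame needs `ceiling(n_channels / n_parallel_rx)` laser pulses, so the
#' frame rate is the laser PRF divided by that pulse count (e.g. 128 channels
#' filled 64 at a time by a 10 Hz laser give 5 frames/s).
#'
#' @param geom a `usn_geometry`.
#' @return frame rate in Hz.
#' @export
frame_rate <- function(geom) {
  stopifnot(inherits(geom, "usn_geometry"))
  geom$laser_prf / ceiling(geom$n_channels / geom$n_parallel_rx)
}

#' Surface fluence
#'
#' Pulse energy times coupling efficiency spread over the illuminated area,
#' in mJ/cm^2.
#' @param geom a `usn_geometry`.
#' @export
surface_fluence <- function(geom) {
  stopifnot(inherits(geom, "usn_geometry"))
  geom$pulse_energy * geom$coupling_efficiency / geom$illumination_area
}

#' Maximum recording duration
#'
#' Frame buffer size divided by the frame rate, seconds.
#' @param geom a `usn_geometry`.
#' @export
max_recording_seconds <- function(geom) {
  stopifnot(inherits(geom, "usn_geometry"))
  geom$max_frames / frame_rate(geom)
}

#' Lateral field of view
#'
#' `(n_elements - 1) * element_width`, cm — the span between the first and
#' last element centres. This is a reporting convention (it matches the
#' system's printed 3.81 cm for 128 elements of 0.03 cm), not a physical
#' aperture model.
#' @param geom a `usn_geometry`.
#' @export
lateral_fov <- function(geom) {
  stopifnot(inherits(geom, "usn_geometry"))
  if (geom$n_elements < 2L) stop("lateral_fov needs n_elements >= 2")
  (geom$n_elements - 1L) * geom$element_width
}

#' Load acquisition geometry from a JSON config
#'
#' Reads a JSON file (or takes a plain list) whose `geometry` block — or the
#' object itself — supplies [acquisition_geometry()] arguments; unspecified
#' fields keep their defaults.
#' @param config path to a JSON file or a named list.
#' @export
geometry_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.null(config$geometry)) config <- config$geometry
  keep <- intersect(names(config), names(formals(acquisition_geometry)))
  do.call(acquisition_geometry, config[keep])
}
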