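#' Optical configuration of the tomographic microscope emulation
#'
#' Describes the illumination and detection geometry of the limited-angle
#' circular-scan tomographic phase microscope: a single zenith angle
#' (measured inside the immersion medium) and equally spaced azimuths.
#' The detector grid is specified directly in sample space.
#'
#' @param wavelength_nm vacuum wavelength, nm (the two measurement systems
#'   use 633 and 835)
#' @param na numerical aperture of the imaging objective
#' @param n_immersion immersion-medium refractive index
#' @param zenith_deg illumination zenith angle in the immersion medium,
#'   degrees
#' @param n_projections number of equally spaced azimuthal projections
#' @param azimuth_step_deg azimuthal step, degrees
#' @param detector_n detector grid size (pixels per side), or `NA` to
#'   inherit the lateral grid of the simulated volume
#' @param detector_pitch_um detector pixel pitch in sample space, um, or
#'   `NA` to inherit the volume pitch
#' @return an object of class `optical_config`
#' @export
optical_config <- function(wavelength_nm = 633, na = 1.3,
                           n_immersion = 1.5123, zenith_deg = 47,
                           n_projections = 180, azimuth_step_deg = 2,
                           detector_n = NA_integer_,
                           detector_pitch_um = NA_real_) {
  if (na <= 0 || na > n_immersion)
    stop("require 0 < na <= n_immersion")
  structure(
    list(wavelength_nm = wavelength_nm, na = na, n_immersion = n_immersion,
         zenith_deg = zenith_deg, n_projections = as.integer(n_projections),
         azimuth_step_deg = azimuth_step_deg,
         detector_n = detector_n, detector_pitch_um = detector_pitch_um),
    class = "optical_config")
}

#' @noRd
wavelength_um <- function(config) config$wavelength_nm / 1000

# medium wavenumber k_m = 2 pi n / lambda, rad/um
#' @noRd
k_medium <- function(config) 2 * pi * config$n_immersion / wavelength_um(config)

#' Illumination directions of the circular scan
#'
#' Unit direction vectors with polar (zenith) angle `zenith_deg` in the
#' immersion medium and azimuths `k * azimuth_step_deg`,
#' `k = 0 .. n_projections - 1`. The z component points along the optical
#' axis (direction of propagation).
#'
#' @param config an [optical_config()]
#' @return matrix `n_projections x 3` of unit vectors; attribute
#'   `"azimuth_deg"` carries the azimuth of each row
#' @export
make_illumination_set <- function(config) {
  th_max <- asin(min(1, config$na / config$n_immersion)) * 180 / pi
  if (config$zenith_deg > th_max + 1e-9)
    stop("illumination outside NA: zenith exceeds asin(na / n_immersion)")
  th <- config$zenith_deg * pi / 180
  az <- (seq_len(config$n_projections) - 1L) * config$azimuth_step_deg
  phi <- az * pi / 180
  dirs <- cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                rep(cos(th), length(phi)))
  colnames(dirs) <- c("x", "y", "z")
  attr(dirs, "azimuth_deg") <- az
  dirs
}

#' 2D complex optical field
#'
#' @param values complex matrix (x along rows, y along columns)
#' @param pixel_pitch pixel pitch in sample space, um
#' @param direction illumination direction: unit 3-vector or
#'   `c(theta_deg, phi_deg)` pair (interpreted as zenith/azimuth)
#' @param k_trans optional actual transverse illumination wavevector
#'   `c(kx, ky)` in rad/um (after snapping to the simulation frequency
#'   grid); recorded so inversion uses the exact simulated carrier
#' @return an object of class `complex_field`
#' @export
complex_field <- function(values, pixel_pitch, direction = c(0, 0, 1),
                          k_trans = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (any(!is.finite(Mod(values)))) stop("field values must be finite")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (length(direction) == 2L) {
    th <- direction[1] * pi / 180; ph <- direction[2] * pi / 180
    direction <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 direction = as.numeric(direction),
                 k_trans = if (is.null(k_trans)) NULL else as.numeric(k_trans)),
            class = "complex_field")
}

#' Set of angle-resolved complex-field projections
#'
#' @param fields list of [complex_field()] objects ordered by azimuth
#' @param config the [optical_config()] used to produce them
#' @param noise_sigma phase-noise standard deviation applied to the set,
#'   radians (0 if clean)
#' @return an object of class `projection_set`
#' @export
projection_set <- function(fields, config, noise_sigma = 0) {
  d <- dim(fields[[1]]$values)
  ok <- vapply(fields, function(f) identical(dim(f$values), d), logical(1))
  if (!all(ok)) stop("all fields must share the same grid")
  structure(list(fields = fields, config = config,
                 noise_sigma = noise_sigma),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$fields[[1]]$values)
  cat(sprintf("<projection_set> %d fields of %d x %d px (pitch %.4g um), lambda %g nm, sigma %.3g rad\n",
              length(x$fields), d[1], d[2], x$fields[[1]]$pixel_pitch,
              x$config$wavelength_nm, x$noise_sigma))
  invisible(x)
}
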