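# Angular-spectrum propagation: the exact scalar free-space propagator on
# a periodic grid. This is the kernel under both the multi-slice forward
# model and the frequency-domain reconstruction code.

# Transfer-function values exp(i kz d) on the DFT frequency grid.
# Evanescent components (kr > km) are attenuated for either propagation
# direction: exp(-|kappa| |d|), never amplified.
#' @noRd
asm_kernel <- function(nx, ny, pitch, distance, km) {
  kx <- fft_freq(nx, pitch)
  ky <- fft_freq(ny, pitch)
  kr2 <- outer(kx^2, ky^2, "+")
  kz2 <- km^2 - kr2
  H <- matrix(0 + 0i, nx, ny)
  prop <- kz2 >= 0
  H[prop] <- exp(1i * sqrt(kz2[prop]) * distance)
  H[!prop] <- exp(-sqrt(-kz2[!prop]) * abs(distance))
  H
}

#' Propagate a 2D complex field through a homogeneous medium
#'
#' Exact scalar angular-spectrum propagation over `distance` um in a
#' medium of refractive index `n0`, on the field's periodic grid (no
#' padding; pad upstream if wrap-around matters). Evanescent components
#' are attenuated regardless of the sign of `distance`.
#'
#' @param field a [complex_field()]
#' @param distance propagation distance, um (negative = backward)
#' @param wavelength_nm vacuum wavelength, nm
#' @param n0 medium refractive index
#' @return a [complex_field()] on the same grid
#' @export
angular_spectrum_propagate <- function(field, distance, wavelength_nm, n0) {
  km <- 2 * pi * n0 / (wavelength_nm / 1000)
  d <- dim(field$values)
  H <- asm_kernel(d[1], d[2], field$pixel_pitch, distance, km)
  out <- ifft2(fft2(field$values) * H)
  complex_field(out, field$pixel_pitch, field$direction, field$k_trans)
}

# Pupil low-pass: binary mask at radius k0 * NA on the DFT grid.
#' @noRd
pupil_mask <- function(nx, ny, pitch, na, wavelength_um) {
  kmax <- 2 * pi * na / wavelength_um
  kx <- fft_freq(nx, pitch)
  ky <- fft_freq(ny, pitch)
  outer(kx^2, ky^2, "+") <= kmax^2
}
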