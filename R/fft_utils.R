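# Internal FFT helpers shared by the propagation and inversion code.
# All spatial frequencies are angular (rad/um) and follow the unshifted
# DFT layout (frequency 0 in the first bin).

#' Angular DFT frequencies for a sampled axis
#'
#' @param n number of samples
#' @param pitch sample spacing (um)
#' @return numeric vector of length `n`, angular frequencies in rad/um,
#'   unshifted DFT order
#' @keywords internal
#' @noRd
fft_freq <- function(n, pitch) {
  m <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  2 * pi * m / (n * pitch)
}

#' @noRd
fft2 <- function(x) stats::fft(x)

#' @noRd
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fft3 <- function(x) stats::fft(x)

#' @noRd
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Zero-pad a matrix symmetrically to `dim_out`, keeping the original block
# in the centre; `unpad_center` is its exact adjoint up to zero insertion.
#' @noRd
pad_center <- function(x, dim_out) {
  d <- dim(x)
  out <- matrix(0 + 0i, dim_out[1], dim_out[2])
  if (is.double(x)) out <- matrix(0, dim_out[1], dim_out[2])
  i0 <- floor((dim_out[1] - d[1]) / 2)
  j0 <- floor((dim_out[2] - d[2]) / 2)
  out[(i0 + 1):(i0 + d[1]), (j0 + 1):(j0 + d[2])] <- x
  out
}

#' @noRd
unpad_center <- function(x, dim_out) {
  d <- dim(x)
  i0 <- floor((d[1] - dim_out[1]) / 2)
  j0 <- floor((d[2] - dim_out[2]) / 2)
  x[(i0 + 1):(i0 + dim_out[1]), (j0 + 1):(j0 + dim_out[2]), drop = FALSE]
}
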