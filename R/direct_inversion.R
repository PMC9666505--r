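# Direct Inversion (Wolf transform): single-pass reconstruction via the
# Fourier Diffraction Theorem. Each measured complex field is linearized
# with the Rytov approximation (complex logarithm of total / incident
# field, with least-squares phase unwrapping), its 2D spectrum is mapped
# onto the Ewald-sphere cap shifted by the illumination wavevector, and
# the accumulated 3D spectrum is inverse-transformed into delta-n.

#' @noRd
wrap_phase <- function(x) (x + pi) %% (2 * pi) - pi

# orthonormal DCT-II matrix (small grids; direct matrix product is fast)
#' @noRd
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Least-squares 2D phase unwrapping
#'
#' Ghiglia-Romero unweighted least-squares unwrapping: the Laplacian of
#' the wrapped phase gradients is inverted with a DCT (Neumann
#' boundaries). Exact for wrap-free phases and robust for the smooth
#' phase maps produced by the Rytov linearization.
#'
#' @param psi wrapped phase matrix, radians
#' @return unwrapped phase matrix (mean-adjusted to the input)
#' @export
unwrap_phase_ls <- function(psi) {
  d <- dim(psi)
  if (d[1] < 2 || d[2] < 2) return(psi)
  dx <- wrap_phase(psi[-1, ] - psi[-d[1], ])
  dy <- wrap_phase(psi[, -1] - psi[, -d[2]])
  rho <- matrix(0, d[1], d[2])
  rho[-d[1], ] <- rho[-d[1], ] + dx
  rho[-1, ]   <- rho[-1, ]   - dx
  rho[, -d[2]] <- rho[, -d[2]] + dy
  rho[, -1]   <- rho[, -1]   - dy
  Cx <- dct_matrix(d[1]); Cy <- dct_matrix(d[2])
  R <- Cx %*% rho %*% t(Cy)
  den <- outer(2 * cos(pi * (0:(d[1] - 1)) / d[1]) - 2,
               2 * cos(pi * (0:(d[2] - 1)) / d[2]) - 2, "+")
  den[1, 1] <- 1
  R <- R / den
  R[1, 1] <- 0
  out <- t(Cx) %*% R %*% Cy
  out + mean(wrap_phase(psi - out))
}

# Incident plane-wave reference at the registration (mid) plane for a
# field with snapped transverse wavevector, on the cropped grid.
#' @noRd
incident_reference <- function(field, km, thickness) {
  d <- dim(field$values)
  kt <- field$k_trans
  if (is.null(kt)) {
    dir <- field$direction
    kt <- km * dir[1:2]
  }
  kz <- sqrt(km^2 - sum(kt^2))
  xs <- (seq_len(d[1]) - 0.5) * field$pixel_pitch
  ys <- (seq_len(d[2]) - 0.5) * field$pixel_pitch
  list(u = exp(1i * (outer(kt[1] * xs, kt[2] * ys, "+") + kz * thickness / 2)),
       kt = kt, kz = kz)
}

#' @noRd
pset_geometry <- function(pset, nz = NULL, dz = NULL) {
  g <- attr(pset, "geometry")
  d <- dim(pset$fields[[1]]$values)
  pitch <- pset$fields[[1]]$pixel_pitch
  if (is.null(g)) {
    if (is.null(nz)) nz <- d[1]
    if (is.null(dz)) dz <- pitch
    g <- list(thickness_um = nz * dz, nz = nz, pitch_um = pitch, n = d)
  }
  if (!is.null(nz)) g$nz <- nz
  if (!is.null(dz)) g$thickness_um <- g$nz * dz
  g
}

#' Direct Inversion of a projection set
#'
#' First-order (Rytov) reconstruction based on the Fourier Diffraction
#' Theorem: for each projection the complex scattered-field spectrum is
#' placed on the Ewald-sphere cap shifted by the illumination wavevector;
#' multiply-hit frequency voxels are averaged (nearest-voxel gridding);
#' the inverse 3D transform of the filled spectrum yields the scattering
#' potential and hence `RI = sqrt(n_immersion^2 + V / k0^2)`.
#'
#' Pixels whose amplitude falls below `amp_floor` (where the Rytov
#' logarithm is undefined) are floored and counted in the returned
#' coverage object's `n_floored`.
#'
#' @param pset a [projection_set()]
#' @param nz,dz optional reconstruction depth sampling; default: the
#'   simulation geometry recorded in the set (isotropic voxel otherwise)
#' @param amp_floor amplitude floor applied before the logarithm
#' @return list with `volume` (an [ri_volume()]) and `coverage` (class
#'   `frequency_coverage`: `filled_mask`, `accumulated_spectrum` with
#'   averaged values, `weights`, `n_floored`)
#' @export
direct_inversion <- function(pset, nz = NULL, dz = NULL, amp_floor = 1e-6) {
  cfg <- pset$config
  km <- k_medium(cfg)
  k0 <- 2 * pi / wavelength_um(cfg)
  g <- pset_geometry(pset, nz, dz)
  d2 <- dim(pset$fields[[1]]$values)
  pitch <- pset$fields[[1]]$pixel_pitch
  nzv <- g$nz
  dzv <- g$thickness_um / g$nz
  dims <- c(d2[1], d2[2], nzv)
  pitch3 <- c(pitch, pitch, dzv)

  cvec <- dims * pitch3 / 2              # volume centre (phase reference)
  kx <- fft_freq(d2[1], pitch)
  ky <- fft_freq(d2[2], pitch)
  KX <- outer(kx, rep(1, d2[2]))
  KY <- outer(rep(1, d2[1]), ky)
  kr2 <- KX^2 + KY^2
  kmax <- 2 * pi * cfg$na / wavelength_um(cfg)
  band <- kr2 <= min(kmax, km)^2 * (1 - 1e-12)
  KZ <- sqrt(pmax(km^2 - kr2, 0))
  # spectrum phase reference: grid coordinates start at half a pixel
  ph_ref <- exp(-1i * (KX + KY) * 0.5 * pitch)

  acc <- array(0 + 0i, dims)
  cnt <- array(0L, dims)
  nfloor <- 0L

  for (f in pset$fields) {
    ref <- incident_reference(f, km, g$thickness_um)
    ratio <- f$values / ref$u
    amp <- Mod(ratio)
    low <- amp < amp_floor
    if (any(low)) { nfloor <- nfloor + sum(low); amp[low] <- amp_floor }
    psi <- log(amp) + 1i * unwrap_phase_ls(Arg(ratio))
    us <- ref$u * psi                           # Rytov-equivalent scattered field
    Us <- fft2(us) * pitch^2 * ph_ref
    # FDT with mid-plane registration: refer each bin back to the entrance
    Vt <- -2i * KZ * exp(-1i * KZ * g$thickness_um / 2) * Us
    Kx <- KX - ref$kt[1]; Ky <- KY - ref$kt[2]; Kz <- KZ - ref$kz
    # re-centre the potential phase on the volume centre so nearest-bin
    # gridding stays accurate for features near the middle of the cube
    Vt <- Vt * exp(1i * (Kx * cvec[1] + Ky * cvec[2] + Kz * cvec[3]))
    mi <- round(Kx * dims[1] * pitch3[1] / (2 * pi))
    mj <- round(Ky * dims[2] * pitch3[2] / (2 * pi))
    mk <- round(Kz * dims[3] * pitch3[3] / (2 * pi))
    ok <- band &
      mi >= -floor(dims[1] / 2) & mi <= floor((dims[1] - 1) / 2) &
      mj >= -floor(dims[2] / 2) & mj <= floor((dims[2] - 1) / 2) &
      mk >= -floor(dims[3] / 2) & mk <= floor((dims[3] - 1) / 2)
    # real potential: accumulate each sample and its Hermitian mirror
    mi2 <- c(mi[ok], -mi[ok]); mj2 <- c(mj[ok], -mj[ok]); mk2 <- c(mk[ok], -mk[ok])
    vals <- c(Vt[ok], Conj(Vt[ok]))
    keep <- mi2 >= -floor(dims[1] / 2) & mi2 <= floor((dims[1] - 1) / 2) &
      mj2 >= -floor(dims[2] / 2) & mj2 <= floor((dims[2] - 1) / 2) &
      mk2 >= -floor(dims[3] / 2) & mk2 <= floor((dims[3] - 1) / 2)
    ii <- (mi2[keep] %% dims[1]) + 1L
    jj <- (mj2[keep] %% dims[2]) + 1L
    kk <- (mk2[keep] %% dims[3]) + 1L
    lin <- ii + dims[1] * (jj - 1L) + dims[1] * dims[2] * (kk - 1L)
    vals <- vals[keep]
    # accumulate with duplicate handling
    sums <- rowsum(cbind(Re(vals), Im(vals)), lin)
    ns <- rowsum(rep(1L, length(lin)), lin)
    idx <- as.integer(rownames(sums))
    acc[idx] <- acc[idx] + complex(real = sums[, 1], imaginary = sums[, 2])
    cnt[idx] <- cnt[idx] + ns[, 1]
  }

  filled <- cnt > 0L
  spec <- acc
  spec[filled] <- spec[filled] / cnt[filled]
  vol <- spectrum_to_volume(spec, pitch3, cfg)
  coverage <- structure(list(filled_mask = filled, accumulated_spectrum = spec,
                             weights = cnt, n_floored = nfloor),
                        class = "frequency_coverage")
  list(volume = vol, coverage = coverage)
}

# Averaged scattering-potential spectrum (continuous-FT units, on the DFT
# grid of the reconstruction volume) -> RI volume.
#' @noRd
spectrum_to_volume <- function(spec, pitch3, cfg) {
  dims <- dim(spec)
  k0 <- 2 * pi / wavelength_um(cfg)
  n0 <- cfg$n_immersion
  # centre-referenced coordinates: x_j = (j - 0.5) * p - N p / 2
  phs <- lapply(1:3, function(a)
    exp(1i * fft_freq(dims[a], pitch3[a]) * (0.5 - dims[a] / 2) * pitch3[a]))
  G <- spec * outer(outer(phs[[1]], phs[[2]]), phs[[3]])
  V <- Re(stats::fft(G, inverse = TRUE)) / (prod(dims) * prod(pitch3))
  n <- sqrt(pmax(n0^2 + V / k0^2, 0))
  ri_volume(n, pitch3, origin = c(0, 0, 0), n_background = n0)
}

#' Map a volume to its potential-spectrum representation
#'
#' Forward counterpart of the inverse transform used by
#' [direct_inversion()]: RI volume -> scattering potential
#' `V = k0^2 (n^2 - n0^2)` -> continuous-FT-scaled spectrum on the DFT
#' grid. Used by the iterative frequency-domain constraints.
#'
#' @param vol an [ri_volume()]
#' @param cfg an [optical_config()]
#' @return complex 3D array
#' @keywords internal
#' @export
volume_to_spectrum <- function(vol, cfg) {
  k0 <- 2 * pi / wavelength_um(cfg)
  n0 <- cfg$n_immersion
  V <- k0^2 * (vol$values^2 - n0^2)
  dims <- dim(V)
  phs <- lapply(1:3, function(a)
    exp(-1i * fft_freq(dims[a], vol$voxel_pitch[a]) *
          (0.5 - dims[a] / 2) * vol$voxel_pitch[a]))
  stats::fft(V) * prod(vol$voxel_pitch) * outer(outer(phs[[1]], phs[[2]]), phs[[3]])
}
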