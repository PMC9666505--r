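# Multi-slice beam propagation (MSBP) forward model: the sample is a
# stack of thin phase screens, one per voxel slice, separated by exact
# angular-spectrum propagation through the immersion medium. Supports
# multiple scattering; the measured plane is the volume mid-plane.

# Core propagation shared by the forward model and its adjoint.
# Returns the cropped detector field; with keep_states = TRUE also the
# padded pre-screen fields u_j and the screens, for gradient computation.
#' @noRd
msbp_core <- function(volume, direction, config, apply_pupil = TRUE,
                      pad_factor = 2, keep_states = FALSE) {
  d <- dim(volume$values)
  p <- volume$voxel_pitch
  if (abs(p[1] - p[2]) > 1e-12)
    stop("lateral voxel pitch must be isotropic")
  pitch <- p[1]; dz <- p[3]; nz <- d[3]
  lam <- wavelength_um(config)
  km <- k_medium(config)
  k0 <- 2 * pi / lam

  if (length(direction) == 2L) {
    th <- direction[1] * pi / 180; ph <- direction[2] * pi / 180
    direction <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  direction <- direction / sqrt(sum(direction^2))
  sin_th <- sqrt(max(0, 1 - direction[3]^2))
  if (sin_th > config$na / config$n_immersion + 1e-9)
    stop("illumination outside NA")

  np <- pad_factor * d[1:2]
  i0 <- floor((np - d[1:2]) / 2)

  # snap transverse illumination wavevector to the padded frequency grid
  k_nom <- km * direction[1:2]
  snap <- function(k, n) 2 * pi * round(k * n * pitch / (2 * pi)) / (n * pitch)
  kxs <- snap(k_nom[1], np[1]); kys <- snap(k_nom[2], np[2])
  kz2 <- km^2 - kxs^2 - kys^2
  if (kz2 <= 0) stop("illumination outside NA")
  kzs <- sqrt(kz2)
  cos_tz <- kzs / km

  # coordinates chosen so the cropped region sees x = (j - 0.5) * pitch
  xs <- ((seq_len(np[1]) - i0[1]) - 0.5) * pitch
  ys <- ((seq_len(np[2]) - i0[2]) - 0.5) * pitch
  u <- exp(1i * outer(kxs * xs, kys * ys, "+"))

  Hdz <- asm_kernel(np[1], np[2], pitch, dz, km)
  dn_scale <- k0 * dz / cos_tz          # phase per unit delta-n, obliquity-corrected

  states <- if (keep_states) vector("list", nz) else NULL
  screens <- if (keep_states) vector("list", nz) else NULL
  xi <- i0[1] + seq_len(d[1]); yi <- i0[2] + seq_len(d[2])
  for (j in seq_len(nz)) {
    s <- matrix(1 + 0i, np[1], np[2])
    dn <- volume$values[, , j] - config$n_immersion
    s[xi, yi] <- exp(1i * dn_scale * dn)
    if (keep_states) { states[[j]] <- u; screens[[j]] <- s }
    u <- ifft2(fft2(u * s) * Hdz)
  }

  L <- nz * dz
  Hback <- asm_kernel(np[1], np[2], pitch, -L / 2, km)
  U <- fft2(u) * Hback
  if (apply_pupil) {
    pm <- pupil_mask(np[1], np[2], pitch, config$na, lam)
    U[!pm] <- 0
  }
  u_det <- ifft2(U)
  out <- complex_field(u_det[xi, yi, drop = FALSE], pitch,
                       direction, k_trans = c(kxs, kys))
  if (!keep_states) return(out)
  list(field = out, states = states, screens = screens,
       Hdz = Hdz, Hback = Hback,
       pupil = if (apply_pupil) pupil_mask(np[1], np[2], pitch, config$na, lam) else NULL,
       xi = xi, yi = yi, np = np, dn_scale = dn_scale, kzs = kzs)
}

#' Simulate one angle-resolved measurement with multi-slice beam propagation
#'
#' A unit-amplitude plane wave with the given illumination direction
#' (transverse wavevector snapped to the padded simulation grid so the
#' field is exactly periodic) is propagated slice by slice through the
#' volume -- per slice a phase screen `exp(i k0 dn dz / cos(theta_z))`
#' with `dn = n - n_immersion`, followed by one angular-spectrum step --
#' then back-propagated to the volume mid-plane (the registration plane)
#' and optionally low-passed by the objective pupil at `NA / lambda`.
#' For an index-matched volume the output is the incident plane wave with
#' unit amplitude everywhere.
#'
#' @param volume an [ri_volume()] with isotropic lateral pitch
#' @param direction unit 3-vector, or `c(zenith_deg, azimuth_deg)`
#' @param config an [optical_config()]
#' @param apply_pupil emulate the finite-NA imaging system (default TRUE)
#' @param pad_factor zero-padding factor for spectral propagation
#' @return a [complex_field()] on the volume's lateral grid; its
#'   `k_trans` records the snapped transverse illumination wavevector
#' @export
msbp_forward <- function(volume, direction, config, apply_pupil = TRUE,
                         pad_factor = 2) {
  msbp_core(volume, direction, config, apply_pupil, pad_factor,
            keep_states = FALSE)
}

#' Simulate a full circular-scan projection set
#'
#' Applies [msbp_forward()] over every direction from
#' [make_illumination_set()] and packages the results with their
#' metadata. The returned set carries a `geometry` attribute (volume
#' thickness and grid) consumed by the reconstruction code.
#'
#' @inheritParams msbp_forward
#' @param config an [optical_config()]
#' @return a [projection_set()]
#' @export
simulate_projection_set <- function(volume, config, apply_pupil = TRUE,
                                    pad_factor = 2) {
  dirs <- make_illumination_set(config)
  fields <- lapply(seq_len(nrow(dirs)), function(i)
    msbp_forward(volume, dirs[i, ], config, apply_pupil, pad_factor))
  ps <- projection_set(fields, config, noise_sigma = 0)
  attr(ps, "geometry") <- list(
    thickness_um = dim(volume$values)[3] * volume$voxel_pitch[3],
    nz = dim(volume$values)[3],
    pitch_um = volume$voxel_pitch[1],
    n = dim(volume$values)[1:2])
  ps
}

#' Add calibrated phase noise to a projection set
#'
#' Each pixel of each field is multiplied by `exp(i eta)` with
#' `eta ~ Normal(0, sigma^2)` i.i.d.; amplitudes are unchanged. With
#' `sigma = 0.10` rad this emulates the noise level measured for the
#' 633 nm system, `sigma = 0.08` rad that of the 835 nm system.
#'
#' @param pset a [projection_set()]
#' @param sigma phase-noise standard deviation, radians
#' @param seed integer seed (deterministic noise per seed)
#' @return a [projection_set()] with `noise_sigma` updated
#' @export
add_phase_noise <- function(pset, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(pset)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fields <- lapply(pset$fields, function(f) {
    eta <- matrix(stats::rnorm(length(f$values), 0, sigma), nrow(f$values))
    f$values <- f$values * exp(1i * eta)
    f
  })
  out <- projection_set(fields, pset$config,
                        noise_sigma = sqrt(pset$noise_sigma^2 + sigma^2))
  attr(out, "geometry") <- attr(pset, "geometry")
  out
}
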