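# Shared fixtures, built once per test run and memoized. All simulated
# data are generated in code; no files are shipped.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# --- small working-volume designs -------------------------------------

# strong-scattering working volume: 12 x 12 x 8 um cube of design-size
# rods (full delta RI 0.03) around a reduced cell target, 0.25 um voxels
strong_design <- function(seed = 4L) {
  scale_phantom_design(phantom_spec(seed = seed), cell_target_spec(),
                       0.2, scale_rods = FALSE)
}

# weak-scattering compact object: cell target alone at delta RI <= 0.006,
# centred in an otherwise empty 12 x 12 x 8 um cube (the regime where the
# first-order model is valid and the object support is informative)
weak_cell_design <- function() {
  list(spec = phantom_spec(cube_size = c(12, 12, 8), delta_ri_max = 0.006),
       cspec = cell_target_spec(
         ellipsoid_size = c(7, 6, 4), truncation = 0.1,
         line_group_frequencies = numeric(0),
         cytoplasm_delta_ri = 0.0016,
         nucleus_size = c(3, 2.5, 1.8),
         nucleus_center_offset = c(-1.5, 1, 0.3),
         nucleus_delta_ri = 0.0028,
         nucleoli_radii = c(0.5, 0.4), nucleoli_delta_ri = 0.0044,
         gradient_center = c(2, 1.5, 0), gradient_radius = 1.2,
         gradient_delta_ri_max = 0.003))
}

scan_config <- function(n_proj = 30L)
  optical_config(n_projections = n_proj, azimuth_step_deg = 360 / n_proj)

# weak compact phantom + noise-free scan + direct inversion
weak_fixture <- function() fixture("weak", function() {
  d <- weak_cell_design()
  truth <- build_cell_target(d$cspec, d$spec, 0.25)
  cfg <- scan_config(30L)
  ps <- simulate_projection_set(truth, cfg)
  di <- direct_inversion(ps)
  list(truth = truth, cfg = cfg, ps = ps, di = di,
       obj = truth$values > truth$n_background + 1e-12)
})

# strong rod phantom + noisy scan (633 nm emulation, sigma = 0.10)
strong_fixture <- function() fixture("strong", function() {
  d <- strong_design()
  truth <- generate_phantom(d$spec, d$cspec, voxel_pitch = 0.25)
  cfg <- scan_config(30L)
  ps_clean <- simulate_projection_set(truth, cfg)
  ps <- add_phase_noise(ps_clean, 0.10, seed = 11L)
  list(truth = truth, cfg = cfg, ps_clean = ps_clean, ps = ps,
       obj = truth$values > truth$n_background + 1e-12)
})

rmse_in <- function(vol, truth, mask)
  sqrt(mean((vol$values[mask] - truth$values[mask])^2))

# --- independent oracles ----------------------------------------------

# brute-force first-order (Born) scattered field of a weak object, by
# direct summation of the free-space Green function over its voxels;
# detector plane at z = zd (outside the object), normal incidence
born_field_bruteforce <- function(vol, cfg, zd) {
  n0 <- cfg$n_immersion
  lam <- cfg$wavelength_nm / 1000
  km <- 2 * pi * n0 / lam
  k0 <- 2 * pi / lam
  d <- dim(vol$values)
  p <- vol$voxel_pitch
  xs <- (seq_len(d[1]) - 0.5) * p[1]
  ys <- (seq_len(d[2]) - 0.5) * p[2]
  idx <- which(vol$values != n0, arr.ind = TRUE)
  src <- cbind(xs[idx[, 1]], ys[idx[, 2]], (idx[, 3] - 0.5) * p[3])
  Vv <- k0^2 * (vol$values[idx]^2 - n0^2)
  ui <- exp(1i * km * src[, 3])
  us <- matrix(0 + 0i, d[1], d[2])
  for (ix in seq_len(d[1])) {
    dx2 <- (xs[ix] - src[, 1])^2
    for (iy in seq_len(d[2])) {
      dist <- sqrt(dx2 + (ys[iy] - src[, 2])^2 + (zd - src[, 3])^2)
      us[ix, iy] <- sum(exp(1i * km * dist) / (4 * pi * dist) * ui * Vv) *
        prod(p)
    }
  }
  us
}

# synthetic fields on the Ewald model itself (analytic sphere spectrum),
# independent of the multi-slice code path; returns a projection_set
fdt_sphere_fields <- function(n = 48L, p = 0.25, dn0 = 0.002, R = 2,
                              zeniths = c(15, 30, 45),
                              azimuths = seq(0, 345, 15)) {
  n0 <- 1.5123; lam <- 0.633
  km <- 2 * pi * n0 / lam; k0 <- 2 * pi / lam
  L <- n * p; ctr <- c(L, L, L) / 2
  V0 <- k0^2 * ((n0 + dn0)^2 - n0^2)
  sphere_ft <- function(K) {
    out <- numeric(length(K)); s <- K > 1e-9
    out[s] <- 4 * pi * (sin(K[s] * R) - K[s] * R * cos(K[s] * R)) / K[s]^3
    out[!s] <- 4 / 3 * pi * R^3
    out
  }
  kv <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) * 2 * pi / (n * p)
  KX <- outer(kv, rep(1, n)); KY <- outer(rep(1, n), kv)
  kr2 <- KX^2 + KY^2; KZ <- sqrt(pmax(km^2 - kr2, 0))
  kmax <- 2 * pi * 1.3 / lam
  band <- kr2 <= min(kmax, km)^2 * (1 - 1e-12)
  xs <- (seq_len(n) - 0.5) * p
  snap <- function(k) 2 * pi * round(k * n * p / (2 * pi)) / (n * p)
  fields <- list()
  for (zen in zeniths) for (az in azimuths) {
    th <- zen * pi / 180; ph <- az * pi / 180
    kt <- c(snap(km * sin(th) * cos(ph)), snap(km * sin(th) * sin(ph)))
    kzin <- sqrt(km^2 - sum(kt^2))
    Kx <- KX - kt[1]; Ky <- KY - kt[2]; Kz <- KZ - kzin
    Vt <- V0 * sphere_ft(sqrt(Kx^2 + Ky^2 + Kz^2)) *
      exp(-1i * (Kx * ctr[1] + Ky * ctr[2] + Kz * ctr[3]))
    Us <- (1i / (2 * KZ)) * exp(1i * KZ * L / 2) * Vt
    Us[!band] <- 0
    ph_ref <- exp(-1i * (KX + KY) * 0.5 * p)
    us <- stats::fft(Us / p^2 / ph_ref, inverse = TRUE) / (n * n)
    uinc <- exp(1i * (outer(kt[1] * xs, kt[2] * xs, "+") + kzin * L / 2))
    fields[[length(fields) + 1L]] <- complex_field(
      uinc + us, p,
      c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)), k_trans = kt)
  }
  ps <- projection_set(fields, optical_config(), 0)
  attr(ps, "geometry") <- list(thickness_um = L, nz = n, pitch_um = p,
                               n = c(n, n))
  ps
}

# intensity-weighted centroid of the delta-n map above half maximum
dn_centroid <- function(vol) {
  dn <- vol$values - vol$n_background
  m <- dn > 0.5 * max(dn)
  w <- dn * m
  c(sum(slice.index(dn, 1) * w), sum(slice.index(dn, 2) * w),
    sum(slice.index(dn, 3) * w)) / sum(w)
}

fwhm_of_profile <- function(y, pitch) {
  y <- y - min(y)
  half <- max(y) / 2
  above <- which(y >= half)
  (max(above) - min(above) + 1) * pitch
}
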