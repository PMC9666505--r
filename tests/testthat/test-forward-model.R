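# Illumination geometry, angular-spectrum propagation and the multi-slice
# beam propagation forward model.

n0 <- 1.5123

test_that("circular scan produces the configured illumination directions", {
  dirs <- make_illumination_set(optical_config())
  expect_equal(nrow(dirs), 180L)
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, 180L))
  expect_equal(acos(dirs[, 3]) * 180 / pi, rep(47, 180L))
  expect_equal(attr(dirs, "azimuth_deg"), seq(0, 358, 2))

  d4 <- make_illumination_set(optical_config(n_projections = 4,
                                             azimuth_step_deg = 90))
  expect_equal(nrow(d4), 4L)
  expect_error(make_illumination_set(optical_config(zenith_deg = 70)),
               "outside NA")
})

test_that("angular-spectrum propagation matches the plane-wave closed form", {
  n <- 32L; p <- 0.25
  f0 <- complex_field(matrix(1 + 0i, n, n), p, c(0, 0, 1))
  expect_equal(angular_spectrum_propagate(f0, 0, 633, n0)$values, f0$values)

  km <- 2 * pi * n0 / 0.633
  kx <- 2 * pi * round(km * sin(10 * pi / 180) * n * p / (2 * pi)) / (n * p)
  xs <- (seq_len(n) - 0.5) * p
  f0$values <- exp(1i * outer(kx * xs, rep(0, n), "+"))
  out <- angular_spectrum_propagate(f0, 5, 633, n0)
  kz <- sqrt(km^2 - kx^2)
  expect_lt(max(Mod(out$values - f0$values * exp(1i * kz * 5))), 1e-12)
  # unitary on the propagating band
  expect_equal(sum(Mod(out$values)^2) / sum(Mod(f0$values)^2), 1,
               tolerance = 1e-10)
})

test_that("index-matched volumes transmit the incident wave unchanged", {
  vol <- ri_volume(array(n0, c(24, 24, 16)), 0.25, n_background = n0)
  cfg <- optical_config()
  f <- msbp_forward(vol, c(47, 0), cfg)
  expect_equal(Mod(f$values), matrix(1, 24, 24), tolerance = 1e-9)
})

test_that("slab phase matches the analytic optical path length", {
  cfg <- optical_config()
  slab <- ri_volume(array(n0 + 0.01, c(16, 16, 40)), c(0.25, 0.25, 0.25),
                    n_background = n0)
  empty <- ri_volume(array(n0, c(16, 16, 40)), c(0.25, 0.25, 0.25),
                     n_background = n0)
  ph <- Arg(msbp_forward(slab, c(0, 0, 1), cfg, apply_pupil = FALSE,
                         pad_factor = 1)$values[8, 8] /
            msbp_forward(empty, c(0, 0, 1), cfg, apply_pupil = FALSE,
                         pad_factor = 1)$values[8, 8])
  expect_lt(abs(ph - 2 * pi * 0.01 * 10 / 0.633), 1e-3)

  # discretization convergence: halving the slice thickness
  slab2 <- ri_volume(array(n0 + 0.01, c(16, 16, 80)), c(0.25, 0.25, 0.125),
                     n_background = n0)
  empty2 <- ri_volume(array(n0, c(16, 16, 80)), c(0.25, 0.25, 0.125),
                      n_background = n0)
  ph2 <- Arg(msbp_forward(slab2, c(0, 0, 1), cfg, apply_pupil = FALSE,
                          pad_factor = 1)$values[8, 8] /
             msbp_forward(empty2, c(0, 0, 1), cfg, apply_pupil = FALSE,
                          pad_factor = 1)$values[8, 8])
  expect_lt(abs(ph2 - ph), 1e-6)

  expect_error(msbp_forward(slab, c(70, 0), cfg), "outside NA")
})

test_that("weak-object field agrees with the brute-force first-order oracle", {
  # smooth weak blob whose spectrum stays in the paraxial band; the
  # brute-force Green-function sum is the independent reference
  n <- 48L; p <- 0.25
  cfg <- optical_config()
  L <- n * p
  cc <- (seq_len(n) - 0.5) * p - L / 2
  R2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  vol <- ri_volume(n0 + 5e-4 * exp(-R2 / (2 * 1.5^2)), p, n_background = n0)
  zd <- L + 2
  fm <- msbp_forward(vol, c(0, 0, 1), cfg, apply_pupil = FALSE)
  km <- 2 * pi * n0 / 0.633
  us_msbp <- angular_spectrum_propagate(fm, zd - L / 2, 633, n0)$values -
    exp(1i * km * zd)
  us_born <- born_field_bruteforce(vol, cfg, zd)
  rel <- sqrt(mean(Mod(us_msbp - us_born)^2)) / sqrt(mean(Mod(us_born)^2))
  expect_lt(rel, 0.01)
})

test_that("scattering is linear in the weak limit", {
  n <- 32L; p <- 0.25
  cfg <- optical_config()
  cc <- (seq_len(n) - 0.5) * p - n * p / 2
  R2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  base <- exp(-R2 / (2 * 1.2^2))
  ref <- msbp_forward(ri_volume(array(n0, c(n, n, n)), p, n_background = n0),
                      c(0, 0, 1), cfg, apply_pupil = FALSE)$values
  us <- lapply(c(5e-4, 1e-3), function(dn) {
    v <- ri_volume(n0 + dn * base, p, n_background = n0)
    msbp_forward(v, c(0, 0, 1), cfg, apply_pupil = FALSE)$values - ref
  })
  rel <- sqrt(mean(Mod(us[[2]] - 2 * us[[1]])^2)) / sqrt(mean(Mod(us[[2]])^2))
  expect_lt(rel, 0.05)
})

test_that("transmitted power never exceeds the incident power", {
  d <- strong_design()
  vol <- generate_phantom(d$spec, d$cspec, voxel_pitch = 0.25)
  cfg <- optical_config()
  # periodic domain so the crop covers the whole computational field
  f <- msbp_forward(vol, c(47, 0), cfg, apply_pupil = FALSE, pad_factor = 1)
  expect_lte(mean(Mod(f$values)^2), 1 + 1e-9)
  # index-matched: strict equality within the propagating band
  empty <- ri_volume(array(n0, dim(vol$values)), 0.25, n_background = n0)
  fe <- msbp_forward(empty, c(47, 0), cfg, apply_pupil = FALSE, pad_factor = 1)
  expect_equal(mean(Mod(fe$values)^2), 1, tolerance = 1e-10)
})

test_that("projection sets carry one field per direction with metadata", {
  vol <- ri_volume(array(n0, c(16, 16, 8)), 0.25, n_background = n0)
  cfg <- optical_config(n_projections = 5, azimuth_step_deg = 72)
  ps <- simulate_projection_set(vol, cfg)
  expect_length(ps$fields, 5L)
  expect_true(all(vapply(ps$fields, function(f)
    max(abs(Mod(f$values) - 1)) < 1e-9, logical(1))))
  g <- attr(ps, "geometry")
  expect_equal(g$thickness_um, 2)
  ps1 <- simulate_projection_set(vol, optical_config(n_projections = 1,
                                                     azimuth_step_deg = 360))
  expect_length(ps1$fields, 1L)
})

test_that("phase noise has the requested statistics and determinism", {
  vol <- ri_volume(array(n0, c(64, 64, 4)), 0.25, n_background = n0)
  cfg <- optical_config(n_projections = 250, azimuth_step_deg = 1.44)
  ps <- simulate_projection_set(vol, cfg)
  expect_identical(add_phase_noise(ps, 0)$fields[[1]]$values,
                   ps$fields[[1]]$values)
  expect_error(add_phase_noise(ps, -0.1), "sigma")

  noisy <- add_phase_noise(ps, 0.1, seed = 3L)
  eta <- unlist(lapply(seq_along(ps$fields), function(i)
    Arg(noisy$fields[[i]]$values / ps$fields[[i]]$values)))
  expect_gte(length(eta), 1e6)
  expect_equal(stats::sd(eta), 0.1, tolerance = 0.01)
  expect_equal(Mod(noisy$fields[[1]]$values), Mod(ps$fields[[1]]$values))

  noisy2 <- add_phase_noise(ps, 0.1, seed = 3L)
  expect_identical(noisy$fields[[10]]$values, noisy2$fields[[10]]$values)
})
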