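# tpmphantom

Simulation toolkit for benchmarking tomographic phase microscopy (TPM)
reconstruction algorithms on a biomimetic 3D scattering microphantom.

TPM reconstructs a specimen's 3D refractive index (RI) — in cells, a
proxy for dry-mass concentration — from complex optical fields measured
under many illumination angles. Weak-scattering algorithms built on the
Fourier Diffraction Theorem break down once light scatters multiple
times; multiple-scattering solvers are nonconvex and hard to validate
without ground truth. This package provides, entirely in software, the
benchmark object and protocol used to compare both families:

* **`phantom_geometry`** — a procedurally generated ground-truth RI
  volume: a 60 × 60 × 40 µm cube of pseudo-randomly spaced 0.5 × 1.8 µm
  polymer rods (edge-to-edge gaps Uniform(0.7, 3) µm, layers every
  1.4 µm with alternating orientation, polymer fill ≈ 25%) enclosing a
  30 × 25 × 12 µm truncated-ellipsoid cell target with bar resolution
  groups up to 1667 lp/mm, a nucleus with nucleoli, and a slow RI
  gradient; all RI offsets ≤ 0.03 above the immersion background
  (1.5123).
* **`forward model`** — multi-slice beam propagation (phase screen per
  voxel slice + angular-spectrum steps) under the instrument's circular
  scan: zenith 47°, 180 projections at 2°, NA 1.3, λ = 633 or 835 nm;
  calibrated phase-noise emulation (σ = 0.10 / 0.08 rad).
* **reconstruction** — three algorithms: Direct Inversion (Rytov + Ewald
  gridding) refined by Gerchberg–Papoulis with object support (GPSC,
  ε = 0.02), and Learning-Tomography-style multi-slice solvers driven by
  complex fields (MSBP-E) or amplitudes only (MSBP-I), both with TV
  regularization and the shared median-dynamics stopping rule
  (ε = 0.01).
* **evaluation** — ±4-pixel cross-section statistics, resolution
  readout on the generated line groups, RI error metrics, phase-noise
  estimation; TIFF + JSON I/O and a CLI wrapper
  (`inst/cli/phantom.R`).

## Worked example

A scaled working volume (12 × 12 × 8 µm cube of design-size rods around
a reduced cell target, 0.25 µm voxels) keeps the full pipeline at
desk scale:

```r
library(tpmphantom)

design <- scale_phantom_design(phantom_spec(seed = 4), cell_target_spec(),
                               factor = 0.2, scale_rods = FALSE)
truth <- generate_phantom(design$spec, design$cspec, voxel_pitch = 0.25)
truth
#> <ri_volume> 48 x 48 x 32 voxels, pitch (0.25, 0.25, 0.25) um
#>   extent 12 x 12 x 8 um; RI range [1.5123, 1.5423]
#>   n_background = 1.5123
compute_fill_factor(truth)
#> [1] 0.2291667

cfg <- optical_config(wavelength_nm = 633, n_projections = 30,
                      azimuth_step_deg = 12)
ps <- simulate_projection_set(truth, cfg)
ps <- add_phase_noise(ps, sigma = 0.10, seed = 1)   # 633 nm noise level

# the noise estimator recovers sigma from an object-free scan
blank <- ri_volume(array(1.5123, c(48, 48, 32)), 0.25, n_background = 1.5123)
ps_blank <- add_phase_noise(simulate_projection_set(blank, cfg), 0.10, seed = 1)
phase_noise_std(ps_blank, background_region = list(x = 9:40, y = 9:40))
#> [1] 0.1000696

di  <- direct_inversion(ps)
sup <- make_support(tv_initial_reconstruction(ps, 1e-2, di = di))
gp  <- gpsc_reconstruct(ps, sup, eps = 0.02, di = di)
me  <- msbp_reconstruct(ps, msbp_settings("field", step_size = 2e-4,
                                          max_iter = 10, init = di$volume))
mi  <- msbp_reconstruct(ps, msbp_settings("intensity", max_iter = 10))

obj <- truth$values > truth$n_background
for (nm in c("direct_inversion", "gpsc", "msbp_e", "msbp_i")) {
  r <- switch(nm, direct_inversion = di$volume, gpsc = gp$volume,
              msbp_e = me$volume, msbp_i = mi$volume)
  m <- ri_error_metrics(r, truth, obj)
  cat(sprintf("%-16s RMSE %.5f  bias %+.5f\n", nm, m$rmse, m$bias))
}
#> direct_inversion RMSE 0.01900  bias -0.01465
#> gpsc             RMSE 0.01959  bias -0.01286
#> msbp_e           RMSE 0.01523  bias -0.01229
#> msbp_i           RMSE 0.02248  bias -0.02152
```

Reading the numbers: at the design contrast (ΔRI = 0.03) the phantom is
strongly scattering, so the first-order methods (Direct Inversion,
GPSC) underestimate RI inside the object (negative bias, a missing-cone
plus model-error effect) and GPSC's constraints cannot make up for the
invalid weak-scattering model — the regime the phantom was designed to
expose at 633 nm. The multiple-scattering MSBP-E, initialized from
Direct Inversion, reduces the RMSE; amplitude-only MSBP-I pays for the
missing phase with a larger low-frequency error. Re-running the same
pipeline at one-fifth contrast (near-infrared-like weak scattering)
reverses the picture in favour of the first-order methods; the test
suite asserts that trend.

The methods vignette (`vignettes/tpm-microphantom-methods.Rmd`)
documents the model, the parameter defaults and their rationale, and
the numerical choices.

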