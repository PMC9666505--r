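---
title: "Simulating and reconstructing a biomimetic scattering microphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing a biomimetic scattering microphantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmphantom)
```

## The problem

Tomographic phase microscopy (TPM) reconstructs the 3D refractive index
(RI) of a semi-transparent specimen from complex optical fields measured
under many illumination angles. In cells the RI maps dry-mass
concentration, which makes TPM a quantitative, label-free imaging
modality. The catch is that every reconstruction algorithm embeds a
scattering model: weak-scattering methods built on the Fourier
Diffraction Theorem fail when light scatters more than once inside the
specimen, while multiple-scattering solvers are nonconvex and their
accuracy is hard to establish on real samples whose ground truth is
unknown.

A way out is a *microphantom*: a fabricated object with known geometry
and calibrated RI that mimics the structural complexity of real
multicellular samples. This package implements such a phantom — a
cell-like imaging target embedded in a cube of pseudo-randomly placed
polymer rods — purely in software, as a ground-truth RI volume, together
with a physical forward model of the limited-angle TPM measurement and
the three reconstruction algorithms whose comparison the phantom was
designed to support. Everything needed to study algorithm behaviour
end-to-end (generation, simulation, reconstruction, evaluation) runs on
synthetic data.

## The phantom

The scattering region is a 60 × 60 × 40 µm cube of rods with a
0.5 × 1.8 µm rectangular cross-section. Rods lie in horizontal layers
stacked every 1.4 µm; consecutive layers alternate between x-aligned and
y-aligned rods. Within a layer the edge-to-edge gaps between adjacent
rods are drawn i.i.d. from Uniform(0.7, 3.0) µm. Two readings of the
printed "lateral distance" are possible; the edge-to-edge reading
reproduces the design's stated fill factor of roughly 25% (the
centre-to-centre reading gives ~35% and was rejected). With 1.8 µm rods
on a 1.4 µm pitch, adjacent orthogonal layers overlap in depth, and the
expected polymer fraction works out to ≈ 26%, which the generator
reproduces (`compute_fill_factor` over seeds: mean ≈ 0.25, asserted in
`[0.20, 0.30]`).

The imaging target is a truncated ellipsoid ("cytoplasm") with external
dimensions 30 × 25 × 12 µm containing:

* bar resolution groups at {417, 595, 833, 1190, 1667} lp/mm (the paper-
  stated maximum is 1667 lp/mm, i.e. a 0.6 µm period; the lower members
  of the series are not printed anywhere and were chosen once as an
  approximately geometric ladder), one row per lateral axis, bar width =
  half period;
* a nucleus with three suspended nucleoli;
* a region of slow RI variation (linear radial ramp).

RI offsets above the immersion background (1.5123, index oil) are capped
at ΔRI = 0.03; the resolution bars carry the full 0.03 so the phantom's
global contrast equals the design value exactly. The internal feature
offsets (cytoplasm 0.008, nucleus 0.014, nucleoli 0.022, gradient peak
0.015) are not printed in the design and are package defaults spanning
(0, 0.03], all configurable. The truncation removes the bottom 10% of
the *full* ellipsoid height; the stated 30 × 25 × 12 µm are interpreted
as the dimensions of the truncated solid (the full ellipsoid is taller
by 1/0.9), otherwise the printed bounding box and a nonzero truncation
could not hold simultaneously.

Rods are suppressed within a 0.5 µm clearance of the cell target
(FFT-based ball dilation of the cell mask; equivalent to a voxel-centre
distance test) and never overwrite cell voxels. Voxelization is a
voxel-centre-inside test with half-open intervals — exact, testable
geometry with no anti-aliasing. Generation is deterministic per
`(spec, seed)`.

### Scaled working volumes

Full-scale rendering (0.1 µm pitch, 600 × 600 × 400 voxels) is used only
where a test needs the printed geometry (fill factor, bar widths). The
simulation and reconstruction studies run on a 12 × 12 × 8 µm cube at
0.25 µm pitch (48 × 48 × 32 voxels, 30 projections). When scaling the
design down, the cube and the cell target shrink but rods keep their
printed cross-section (`scale_phantom_design(..., scale_rods = FALSE)`):
scaling the rods too would push them below two voxels at any practical
pitch, and keeping them full-size preserves the scattering strength per
unit length. These sizes were chosen so the whole test suite and the
acceptance script run in minutes on one CPU core.

## Forward model

Measurements are simulated with multi-slice beam propagation (MSBP): the
volume is a stack of thin phase screens, one per voxel slice
(`exp(i k0 Δn dz / cos θz)` with Δn relative to the immersion medium and
an obliquity correction for the tilted illumination), separated by exact
scalar angular-spectrum propagation through the immersion medium.
Evanescent components are attenuated for either propagation direction.
The illumination follows the instruments' circular scan: zenith 47°
(defined inside the immersion medium — the reference medium is not
stated in the design), azimuths 0°..358° in 2° steps, 180 projections,
at 633 or 835 nm with NA 1.3.

Numerical choices:

* fields are zero-padded 2× before spectral steps to suppress
  wrap-around; the transverse illumination wavevector is snapped to the
  padded frequency grid so the incident wave is exactly periodic (the
  snapped wavevector is stored with each field and used by the
  inversion);
* the detector (registration) plane is the volume mid-plane; the
  experimental focus plane is not stated;
* a binary pupil at NA/λ emulates the finite-NA imaging system
  (toggleable);
* slice thickness equals the voxel pitch; the slab-phase oracle is exact
  and invariant under slice-halving (asserted to 1e-6 rad).

Validation: the analytic plane-wave propagator and slab optical-path
phases are reproduced to machine precision; against a brute-force
free-space Green-function first-order integral the MSBP field of a
smooth weak object (Gaussian blob, Δn = 5e-4) agrees to < 1% RMS of the
scattered amplitude. For sharp-edged objects at this NA the agreement
degrades to several percent — that discrepancy is the paraxial obliquity
error inherent to beam-propagation models, not a numerical artifact, and
is why the quantitative oracle test uses a smooth object.

Phase noise is emulated per pixel as `exp(i η)`, η ~ N(0, σ²), matching
the noise levels measured on the two instruments (σ = 0.10 rad at
633 nm, 0.08 rad at 835 nm); the `phase_noise_std` estimator recovers
them within 2% after removing the best-fit phase plane (tilt removal —
without it the off-axis carrier residual dominates).

## Reconstruction algorithms

**Direct Inversion (Wolf transform).** Each measured field is linearized
with the Rytov approximation — complex log of total/incident field, the
phase unwrapped with DCT-based least-squares unwrapping — and its 2D
spectrum mapped onto the Ewald-sphere cap shifted by the illumination
wavevector (Fourier Diffraction Theorem). The Born/Rytov choice is not
stated in the reference description ("first-order scattering
approximation"); Rytov is the standard choice for cell-scale phase
objects. Gridding is nearest-voxel with hit-count averaging, plus two
details that matter in practice: the real-valued scattering potential is
completed Hermitianly (each sample is also placed conjugated at −K), and
the potential phase is re-centred on the volume centre before rounding —
without re-centring, the half-box linear phase turns rounding errors
into an axial shift of the reconstruction. The 47° circular scan leaves
the classic missing cone: axially elongated points and underestimated
RI, both asserted as properties.

**GPSC.** A TV-regularized initial reconstruction (Chambolle–Pock
primal-dual on the linearized problem; "strong" weight 1e-2 relative to
the data scale) is binarized (Otsu), reduced to its largest connected
component and dilated by 2 voxels to form the object support — the
binarization method and dilation are package choices; the design states
only "binarization". Gerchberg–Papoulis iterations then alternate
signal-domain constraints (Δn ≥ 0, zero outside support) with
replenishment of the measured frequencies. The loop state is the
scattering potential V = k0²(n² − n0²), in which both constraint sets
are convex, so the measured-frequency misfit is non-increasing
(asserted). Stopping level ε = 0.02.

**MSBP-E / MSBP-I (Learning Tomography).** Sequential per-projection
gradient updates through the exact adjoint of the discrete forward chain
(verified against central finite differences to 1e-4 relative in both
modes), TV proximal step once per cycle, optional nonnegativity of Δn,
stopping level ε = 0.01. MSBP-E fits complex fields and starts from the
Direct Inversion estimate; MSBP-I fits amplitudes only (`(|u| − a)²`,
mirroring the use of amplitude components rather than squared
intensities) and starts from zeros. Step sizes are not stated in the
reference description; the defaults (field 3e-4, intensity 2e-4,
interpreted as the maximal Δn moved by the first per-projection update,
then fixed and halved whenever an epoch's misfit increases) come from a
convergence study on the weak fixture: larger steps make the
amplitude-only mode diverge from its zero start and let the field mode
wander in the missing-cone null space after the data are fit.

**Stopping rule.** All three loops share one criterion: stop when the
median of the dynamics over the last 10 iterations falls below ε. The
dynamics of iteration k is ‖x_k − x_{k−1}‖₂ normalized by the first
update's norm — the normalization makes ε scale-free and forces d₁ = 1;
the rule never fires before 10 iterations, and the even-window median is
the standard midpoint of the 5th/6th order statistics. The exact
normalization of the original procedure is not reproducible from the
available description; this package's definition is stated here and used
consistently everywhere, including the enumeration oracle test
(geometric dynamics 0.5^k stop at k = 12 for ε = 0.01).

## Evaluation protocol

* `cross_section_profile`: mean ± population standard deviation over the
  ±4-pixel window around a profile line — the statistic behind the
  shaded bands of the reference cross-sections.
* `resolved_frequency`: a group counts as resolved when the single-bin
  Fourier modulation amplitude at its design frequency, relative to the
  group's mean Δn, exceeds 0.1. A raw peak-to-trough Michelson ratio was
  rejected: smooth pedestals bleeding in from the ellipsoid edge keep it
  high even when the bars are gone. The 0.1 threshold substitutes for
  the visual judgement used with the fabricated target.
* `ri_error_metrics`: RMSE and signed bias over the object mask.
* `phase_noise_std`: see above.

Profile lines are anchored to the generated geometry (the `line_groups`
metadata of the cell target); the pixel coordinates of the published
figure's section lines are not recoverable and are irrelevant for
simulated volumes.

## What the synthetic study does and does not show

The generator reproduces the *design* of the fabricated phantom, not its
realization: no fabrication shrinkage or proximity effects, no RI
dispersion of the polymer (the absolute polymer RI is not printed; the
package uses background + ΔRI_max = 1.5423 by default), no camera/
hologram chain (complex fields are the interface), no partial coherence,
polarization or absorption. Phase noise is i.i.d. Gaussian per pixel,
which matches the reported summary statistic but not any spatial
correlation a real interferometer would show. Consequently, passing
tests demonstrate correctness of the algorithms under the stated models
and the qualitative trends (missing cone, scattering-strength dependence
of GPSC, low-frequency artifacts of amplitude-only data) — they do not
certify accuracy on experimental data.

Two observed behaviours deserve emphasis because they mirror the
physical study. First, on the full-contrast (ΔRI = 0.03) rod phantom the
GP iterations do not improve on Direct Inversion — the phantom is simply
too strongly scattering for a first-order method, which is exactly the
conclusion the phantom was designed to expose at 633 nm; GPSC's benefit
shows on weak-scattering compact objects, and the package asserts the
corresponding wavelength trend (GPSC error at one-fifth contrast ≤ its
error at full contrast, same noise). Second, amplitude-only MSBP-I
shows a larger low-spatial-frequency error than MSBP-E on the same noisy
data (asserted as a spectral-shell ratio > 1), the known failure mode of
intensity-only phase imaging.

## Problem sizes

Fixed choices used by the shipped tests and the acceptance script: the
full-size cube is rasterized at 0.2 µm (5 seeds) for the fill-factor
number; resolution geometry is checked at 0.1 µm on a 32 × 28 × 14 µm
cube; all reconstruction studies use 48 × 48 × 32 voxels at 0.25 µm with
30 projections; gradient checks run on 12 × 12 × 6 grids with 2
projections. These were chosen once as the smallest sizes at which every
tested property is comfortably away from its discretization floor.
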