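---
title: "Models and methods behind iscatr"
author: "iscatr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iscatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscatr)
```

# The image-formation model

Interferometric scattering microscopy detects the coherent sum of a
reference field (the reflection of the illumination at the
cover-glass/medium interface, relative amplitude $r$) and the field
scattered by the sample (relative amplitude $|s|$, proportional to the
polarizability of the scatterer). The normalized detector intensity is

$$I_\det = r^2 + |s|^2 + 2 r |s| \cos\Delta\varphi, \qquad
\Delta\varphi = \frac{4\pi n}{\lambda} z + \varphi_G,$$

with $z$ the height of the scatterer above the cover glass, $n$ the medium
index, $\lambda$ the illumination wavelength and $\varphi_G$ the Gouy
phase. The analyses work on the contrast
$C = (I_\det - I_{bg}) / I_{bg}$; with $I_{bg} = r^2$ and $|s| \ll r$ this
linearizes to $C \approx 2 (|s|/r) \cos\Delta\varphi$, so the sign of the
contrast encodes the interferometric phase. `interferometric_intensity()`
and `iscat_contrast()` implement these identities and are tested against a
complex-arithmetic oracle.

## The parametric axial iPSF

Empirically, the axial response of a point-like interface is an oscillation
under a decaying envelope. `ipsf_model()` parameterizes it as

$$C(z) = A \left[1 + (z/z_{env})^2\right]^{-p/2}
\cos\!\big(k_z z + \arctan(z/z_R) + a_{sa} (z/z_{env})^3 + \varphi_0\big),$$

truncated to exactly zero outside $\pm$`truncation_halfwidth`, with
$k_z = 4\pi n/\lambda$ (fringe spacing $\lambda/2n \approx 167$ nm at
defaults, i.e. zero crossings every $\lambda/4n \approx 84$ nm).

Choices worth stating:

- **Envelope exponent.** The detected confocal intensity falls off
  quadratically with defocus; we therefore use the exponent $-p/2$ with
  $p = 2$ for confocal (asymptotically $z^{-2}$) and $p = 1$ for
  wide-field ($z^{-1}$, the spherical-wave/plane-wave case). With this
  parameterization the envelope ratio between 10 and 20 envelope scales is
  $401/101 = 3.97 \approx 4$, the quadratic-drop signature the tests
  assert.
- **Gouy phase** is modeled as $\arctan(z/z_R)$ with $z_R$ free (default
  $\lambda/2$). The experiment calibrates the iPSF empirically; a smooth
  parametric form keeps simulation and inversion consistent without
  claiming vectorial rigor.
- **Spherical aberration** is reduced to a single cubic phase coefficient
  (default 0). It produces the axial asymmetry seen deep in samples;
  per-window refits of this coefficient are possible because
  `reconstruct_surface()` accepts any `ipsf_model`.
- **Scalar optics throughout.** High-NA vectorial diffraction, polarization
  and pupil engineering are out of scope; the lateral confocal response is
  the scalar product $h_{ill} \cdot (h_{det} \otimes \mathrm{pinhole})$ of
  Airy amplitudes ($2 J_1(v)/v$), which reproduces the qualitative pinhole
  behaviour (a nearly closed pinhole sharpens the response; FWHM is
  monotone in pinhole diameter over 0.1–2 AU).
- **z convention:** $z = 0$ at the cover glass, increasing into the sample;
  defocus = structure height − focus height.

## Units

All lengths are nm, times s, diffusion nm²/s; contrast and reflectance are
dimensionless. Default instrument constants: $\lambda = 445$ nm, NA 1.45,
$n = 1.33$ (1.365 for index-matched cytoplasm), 30 nm pixels and z-steps,
$r$ from the Fresnel coefficient of glass/water ($\approx 0.067$).

# The synthetic-data generator

Because the raw recordings behind this kind of experiment are not publicly
deposited, every stage is validated by parameter recovery on rendered
phantoms:

- **Membranes** (`make_membrane_phantom()`): a smooth bow plus band-limited
  Gaussian ripples with prescribed RMS amplitude and correlation length,
  emulating nuclear-envelope corrugations (hundreds of nm over micrometer
  scales). Defaults: 200 nm RMS, 1 µm correlation — the regime in which
  envelope height variation spans most of an axial stack.
- **Staircases** (`make_staircase_phantom()`): 50 nm steps, the height
  calibration target.
- **Tubule networks** (`make_tubule_phantom()`): branching random walks
  whose internal nodes are exactly three-way junctions (ER topology), radii
  25–50 nm (diameters 50–100 nm), rendered as dark structures
  (default contrast −12%).
- **Particles** (`make_particle_ensemble()`): Brownian motion
  ($\sigma^2 = 2 D \Delta t$ per axis) with optional drift; `lateral_only`
  confines motion to the image plane for membrane-bound species. Axial
  diffusion makes particles genuinely vanish when their phase crosses the
  contrast zero — the simulator reproduces this because particles are
  rendered *coherently*: each adds
  $s_i\,e^{i(k_z z_i + \varphi_G + \varphi_i)}$ times a defocus-widened
  Gaussian footprint to the reference field before squaring.

Interfaces and tubules, by contrast, are rendered through the axial iPSF as
multiplicative thin-interface contrast — the same approximation the
inversion assumes — keeping rendering O(pixels) per plane. Shot noise is
Poisson at a per-pixel photon budget (default $10^4$, i.e. 1% contrast
noise, which makes 2% microtubule-level contrasts detectable). What the
phantoms deliberately do **not** model: speckle from out-of-focus cell
bodies beyond envelope attenuation, refractive-index heterogeneity inside
volumes, fluorescence channels, or camera electronics. Passing recovery
tests on these phantoms therefore demonstrates correctness of the inverse
methods under the stated forward model, not performance on arbitrary real
recordings.

# Background estimation and contrast

`estimate_background()` low-pass filters each plane with a Gaussian whose
FWHM is a multiple (default 24, recommended range 16–32) of the lateral PSF
FWHM; values outside the range warn rather than fail. Boundaries are
mirror-padded to avoid edge contrast artifacts, and the blur is applied per
z-plane. A caveat the tests make explicit: a laterally *uniform* interface
has all its signal at DC, so blurring subtracts the signal itself — for
such scenes (bare glass, ideal planar interfaces) the median reference
intensity $r^2$ should be used as background instead, which
`contrast_map()` accepts directly.

# Multi-plane interface reconstruction

The observed axial profile of an interface at height $h$ is
$A\,u(h - z_f)$ as the focus $z_f$ scans, with $u$ the unit iPSF. Two
inversion routes are provided by `locate_interface()` /
`reconstruct_surface()`:

- **Ridge** (default, fully vectorized). At 30 nm z-steps the fringes are
  sampled only ~2.8 times per lobe and adjacent lobes differ by a few
  percent in envelope, so a bare arg-max over $|C|$ misassigns the fringe
  order. The implementation therefore (1) rectifies and demodulates the
  profile — Gaussian smoothing of $|C|$ over one lobe spacing — yielding a
  lobe-free envelope whose peak gives a coarse, unambiguous estimate;
  (2) median-filters the coarse map laterally (radius 2) when a full frame
  is available, exploiting the spatial smoothness of real surfaces to
  suppress fringe-order errors under shot noise; (3) refines on the
  contrast lobe nearest the coarse estimate by 3-point parabolic
  interpolation and resolves which model lobe it is by matching candidate
  heights against the coarse estimate. All offsets (envelope peak, lobe
  positions) are self-calibrated by pushing the model through the identical
  pipeline, so Gouy and truncation biases cancel by construction.
- **Fit**: Levenberg–Marquardt least squares over $(z_0, A, \varphi_0)$ of
  the truncated oscillatory model, initialized from the ridge result and
  bounded to the search window. It is exact on noiseless model data and is
  intended for line cuts and small regions (it loops over pixels).

Validity: a pixel is kept when its extremum exceeds 3× a robust noise
floor. The noise floor is taken from the signal-poor planes (envelope below
25% of its peak), capped by the lateral high-frequency noise of the planes;
estimating it from the profile at large would confuse oscillating signal
with noise. Pixels failing the threshold are `NA` in the height map, never
exceptions. Tie-breaks: when two lobes match equally, the candidate nearest
the coarse estimate wins. A radius-1 lateral median filter on the final
heights is on by default.

Problem sizes used in the recovery tests: 256² membranes for the headline
RMSE check (≤ 30 nm at $10^4$ photons; measured ≈ 6 nm), 64² and smaller
elsewhere — small enough to run in seconds yet large enough for stable
statistics.

`edge_sharpness_1090()` measures lateral sharpness as the 10%→90% crossing
distance with plateau levels from the first/last decile of samples
(2.563σ for a Gaussian-blurred step, 0.8L for a linear ramp).

# Segmentation, localization, tracking

- `hessian_ridge_segment()`: scale-normalized principal Hessian eigenvalue
  at a Gaussian scale comparable to the tubule radius, polarity-aware
  (dark tubules have positive transverse curvature), followed by
  small-object removal.
- `radial_variance_transform()`: per pixel, the variance across annulus
  radius of annular mean intensities (annulus width 1 px). It scores
  centers of radially symmetric patterns regardless of contrast sign —
  essential because iPSFs flip sign with defocus — and is invariant to
  intensity offsets (scores scale as gain²).
- `localize_particles()`: local maxima above threshold, greedy non-maximum
  suppression (default separation one PSF FWHM), separable 3-point
  quadratic sub-pixel refinement on the score map; contrast is read off the
  contrast image bilinearly.
- `link_trajectories()`: greedy per-frame assignment in order of increasing
  displacement within a gate (scaled by bridged gap length), memory for
  brief disappearances, and a hard minimum of 25 localizations per
  trajectory. At the sparse densities targeted here this reproduces
  optimal-assignment linking while staying dependency-free; each detection
  joins at most one trajectory by construction.
- `contrast_to_dz()`: inverts $C(t) = C_{max} \cos(\pi z/L + \varphi_0)$,
  $L$ = `full_inversion_distance()` = $\lambda/(4 n_{eff})$ (111.25 nm at
  445 nm with $n_{eff} = 1$; the calibration is quoted as 110 nm). The
  starting phase takes the branch nearest focus
  ($\varphi_0 = \arccos(C_1/C_{max}) \in [0, \pi]$) and is reported as an
  attribute; subsequent phases take the smallest increment, assuming
  per-frame steps below $L/2$. The cosine is even, so at the branch points
  the direction is unidentifiable from contrast alone — the `inward_only`
  prior (endocytic pits can only move into the cell) resolves it by
  forbidding reversals of cumulative displacement. $|C| > C_{max}$ by up to
  10% is clipped with a warning (noise at the calibration limit); beyond
  that it is an error. The effective index is left explicit: the quoted
  110 nm corresponds to $n_{eff} \approx 1$, although imaging media have
  $n = 1.33$–1.365; near focus the Gouy slope adds to the phase rate, and
  an empirical calibration absorbs both.

# Dynamics maps

- `persistency_map()`: per pixel, the longest occupancy run where
  interruptions strictly shorter than the lag period are tolerated (the
  merged run spans first to last occupied frame). The rule reduces to plain
  run length at lag = frame interval; since "persistency with a lag" admits
  other readings, a `total` occupancy variant is provided behind a flag and
  the mode is recorded in the output.
- `oscillation_map()`: Schmitt-trigger counting of sign changes of the
  mean-subtracted contrast: a crossing registers only after the signal
  exceeds the opposite hysteresis threshold. A pixel starting inside the
  band counts its first excursion (so a noiseless sinusoid of $f$ cycles
  counts exactly $2f$); a pixel already beyond a threshold at the first
  frame does not. Default hysteresis is 0.25× the per-pixel temporal
  standard deviation — enough to reject shot-noise crossings while keeping
  ≥2σ oscillations.

# Pipeline and I/O

`run_pipeline()` chains simulate → contrast → reconstruct → track → maps
under a single YAML-able configuration; unknown keys are errors (typo
protection), the CLI wrapper lives at `inst/cli/iscat.R`, and every run
writes a log with package version, seed, parameters and a config hash.
Randomness flows from one top-level seed through fixed per-stage offsets.
Stacks travel as multi-page TIFF plus a JSON sidecar (axis order, voxel
sizes, frame interval, value scaling, metadata); float data are min/max
scaled into [0, 1] for 32-bit storage with the scaling stated in the
sidecar, and the sidecar is required on read because TIFF pages alone
cannot distinguish z from t.

# Known limitations

- The forward model is scalar and the iPSF parametric; systematic
  deviations of a real instrument (vectorial effects, apodization,
  aberrations beyond the cubic term) are absorbed only insofar as the
  parametric family can express them.
- Volumetric contrast inside extended bodies is not inverted — only
  interfaces carry a well-defined axial signature.
- Single-plane axial tracking is relative and branch-limited: it cannot
  cross contrast extrema without a prior, and assigns no absolute height.
- The tracker is designed for sparse scenes; at high densities merged
  detections bias positions before linking quality degrades.
- Background estimation assumes the structures of interest are laterally
  compact relative to the kernel; laterally uniform signal is removed with
  the background (use a reference-intensity background instead).
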