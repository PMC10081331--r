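# iscatr

Simulation and analysis of confocal interferometric scattering (iSCAT)
microscopy of living cells.

iSCAT images the interference between a reference wave — the reflection of
the illumination at the cover-glass/medium interface — and the light
scattered by cellular nano-structures. On the detector,

    I_det / |E_inc|^2 = r^2 + |s|^2 + 2 r |s| cos(Δφ),
    Δφ = (4π n / λ) z + φ_G,

where `r` is the field reflectance of the reference interface, `s` the
relative scattered field amplitude (proportional to the polarizability of
the scatterer), `z` the height of the object above the cover glass, `n` the
medium refractive index, `λ` the wavelength, and `φ_G` the Gouy phase. The
working quantity is the contrast `C = (I_det − I_bg) / I_bg`. Because Δφ
advances by π for every λ/(4n) of axial travel, the contrast of a structure
*reverses sign* through focus — a nuisance for naive intensity analysis, and
the signal that makes label-free 3D measurement possible.

The package provides, in one consistent framework:

- **Optical model** — the interferometric intensity law, a parametric axial
  iPSF (oscillation under a confocal envelope with Gouy-phase reversal and
  an optional spherical-aberration term), and the scalar lateral confocal
  response including the pinhole.
- **Synthetic data** — phantoms (rippled membranes, staircase calibration
  targets, three-way-junction tubule networks, diffusing/drifting particle
  ensembles) rendered into noisy intensity stacks through the optical model,
  with Poisson shot noise and ground truth attached.
- **Preprocessing** — Gaussian low-pass background estimation (kernel 16–32
  PSF FWHM), contrast maps, flat-fielding.
- **3D reconstruction** — per-pixel localization of interface signatures in
  contrast z-stacks (envelope-demodulated ridge detection, or nonlinear
  least-squares fits of the truncated oscillatory iPSF), height maps with
  validity masks, and 10–90% edge-sharpness analysis.
- **Nanoparticle tracking** — Hessian-eigenvalue ridge segmentation of
  tubules, radial variance transform (RVT) particle localization with
  sub-pixel refinement, greedy nearest-neighbour trajectory linking
  (minimum 25 localizations per trajectory), and contrast-calibrated axial
  tracking: inverting `C(t) = C_max cos(π z / L + φ0)` on a continuous
  branch, where `L = λ/(4 n_eff)` is the axial travel per full contrast
  inversion (110 nm at λ = 445 nm).
- **Dynamics maps** — pixelwise gap-tolerant persistency of network
  occupancy and Schmitt-trigger counting of contrast inversions.
- **Pipeline** — a configuration-driven front end
  (`run_pipeline()`; thin CLI at `inst/cli/iscat.R`) with TIFF + JSON-sidecar
  I/O and provenance logging.

## Worked example: recover a membrane topography from a simulated z-stack

```r
library(iscatr)

cfg  <- optical_config()             # 445 nm, NA 1.45, 30 nm pixels
ipsf <- ipsf_model(amplitude = 0.1)  # 10% peak interface contrast

ph    <- make_membrane_phantom(extent_px = c(64, 64), ripple_rms = 150,
                               correlation_length = 1000,
                               base_height = 1000, seed = 1)
truth <- ph$interfaces[[1]]$heights
focus <- seq(min(truth) - 400, max(truth) + 400, by = cfg$z_step)

stack <- render_acquisition(ph, acquisition_plan(focus_nm = focus,
                                                 photon_budget = 1e4),
                            cfg, ipsf, seed = 2)
cmap  <- compute_contrast(stack, psf_fwhm = lateral_fwhm(cfg))
hmap  <- reconstruct_surface(cmap$values, focus_nm = focus, ipsf = ipsf)
hmap
#> Height map (ridge): 64 x 64 px, 100.0% valid
#>   heights: 694 .. 1317 nm (median 999)

err <- (hmap$heights - truth)[hmap$validity]
sqrt(mean(err^2, na.rm = TRUE))
#> 3.2 nm
```

A 64×64 px membrane with 150 nm RMS ripples, imaged as a 48-plane z-stack
(Δz = 30 nm) at 10⁴ detected photons/pixel, is recovered with ~3 nm height
RMSE: the axial fringes of the iPSF localize each interface far below the
z-step. `full_inversion_distance(cfg, 1.0)` returns 111.25 nm — the axial
displacement corresponding to one full contrast inversion, ≈110 nm at this
wavelength — which `contrast_to_dz()` uses to turn single-plane contrast
time series of tracked nanoparticles into axial displacements.

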