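#' Optical configuration of an iSCAT microscope
#'
#' Bundles the instrument constants needed by the forward model and by the
#' analysis stages: illumination wavelength, objective numerical aperture,
#' refractive index of the imaging medium, confocal pinhole size, lateral and
#' axial sampling, and the field reflectance of the cover-glass/medium
#' interface that supplies the reference wave.
#'
#' @param wavelength Illumination wavelength in nm (vacuum).
#' @param numerical_aperture Objective NA (dimensionless).
#' @param medium_index Refractive index of the imaging medium; 1.33 for water,
#'   about 1.365 for iodixanol-adjusted medium matching the cytoplasm.
#' @param pinhole Confocal pinhole diameter in Airy units (1 AU =
#'   1.22 wavelength / NA).
#' @param pixel_size Lateral sampling in nm per pixel.
#' @param z_step Axial sampling of z-stacks in nm.
#' @param reference_reflectivity Field (amplitude) reflectance `r` of the
#'   reference interface, in (0, 1]. The default is the normal-incidence
#'   Fresnel amplitude coefficient for glass (n = 1.52) against water.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' airy_unit_nm(cfg)
#' @export
optical_config <- function(wavelength = 445,
                           numerical_aperture = 1.45,
                           medium_index = 1.33,
                           pinhole = 1,
                           pixel_size = 30,
                           z_step = 30,
                           reference_reflectivity = NULL) {
  if (is.null(reference_reflectivity)) {
    n_glass <- 1.52
    reference_reflectivity <- abs(n_glass - medium_index) / (n_glass + medium_index)
  }
  stopifnot(
    wavelength > 0, numerical_aperture > 0, medium_index > 0,
    pinhole > 0, pixel_size > 0, z_step > 0
  )
  if (reference_reflectivity <= 0 || reference_reflectivity > 1)
    stop("reference_reflectivity must lie in (0, 1]")
  structure(
    list(
      wavelength = wavelength,
      numerical_aperture = numerical_aperture,
      medium_index = medium_index,
      pinhole = pinhole,
      pixel_size = pixel_size,
      z_step = z_step,
      reference_reflectivity = reference_reflectivity
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("iSCAT optical configuration\n")
  cat(sprintf("  wavelength       : %g nm\n", x$wavelength))
  cat(sprintf("  NA               : %g\n", x$numerical_aperture))
  cat(sprintf("  medium index     : %g\n", x$medium_index))
  cat(sprintf("  pinhole          : %g AU (%.1f nm)\n", x$pinhole,
              x$pinhole * airy_unit_nm(x)))
  cat(sprintf("  pixel / z step   : %g / %g nm\n", x$pixel_size, x$z_step))
  cat(sprintf("  reference r      : %g\n", x$reference_reflectivity))
  invisible(x)
}

#' One Airy unit in nm
#'
#' @param cfg An [optical_config()].
#' @return Pinhole diameter of 1 AU, `1.22 * wavelength / NA`, in nm.
#' @export
airy_unit_nm <- function(cfg) 1.22 * cfg$wavelength / cfg$numerical_aperture

#' Parametric interferometric point spread function (iPSF) model
#'
#' The axial iSCAT response of a point-like interface or scatterer is an
#' oscillation of the interferometric phase under a decaying envelope:
#' \deqn{C(z) = A\,[1+(z/z_{env})^2]^{-p/2}\cos(k_z z + \arctan(z/z_R) +
#'   a_{sa}(z/z_{env})^3 + \varphi_0)}
#' truncated to zero outside `truncation_halfwidth`. The cosine carries the
#' round-trip interferometric phase (`axial_wavevector` = 4*pi*n/lambda), the
#' arctan term is the Gouy phase responsible for contrast reversal through
#' focus, and the cubic term is a single-coefficient spherical-aberration
#' asymmetry. `envelope_power` 2 gives the confocal quadratic intensity drop
#' with defocus, 1 the wide-field ~1/z drop.
#'
#' @param amplitude Signed peak contrast A.
#' @param wavelength,medium_index Used for the default axial wavevector and
#'   Gouy range; ignored for fields passed explicitly.
#' @param axial_wavevector Interferometric phase rate 4*pi*n/lambda (rad/nm).
#' @param gouy_range Axial scale z_R of the arctan Gouy term (nm);
#'   default wavelength/2.
#' @param envelope_scale Axial envelope scale z_env (nm).
#' @param envelope_power 2 = confocal, 1 = wide-field.
#' @param sa_coefficient Cubic-phase spherical-aberration weight
#'   (dimensionless; 0 = symmetric iPSF).
#' @param phase_offset Phase offset phi0 in rad.
#' @param truncation_halfwidth Support half-width in nm; the model is exactly
#'   zero beyond it.
#' @param lateral_sigma In-focus lateral Gaussian width (nm).
#' @param lateral_growth Lateral width increase per nm of defocus
#'   (dimensionless nm/nm).
#' @return An object of class `ipsf_model`.
#' @examples
#' m <- ipsf_model(amplitude = 0.1)
#' axial_ipsf(c(-200, 0, 200), m)
#' @export
ipsf_model <- function(amplitude = 0.1,
                       wavelength = 445,
                       medium_index = 1.33,
                       axial_wavevector = 4 * pi * medium_index / wavelength,
                       gouy_range = wavelength / 2,
                       envelope_scale = 400,
                       envelope_power = 2,
                       sa_coefficient = 0,
                       phase_offset = 0,
                       truncation_halfwidth = 1500,
                       lateral_sigma = 70,
                       lateral_growth = 0.15) {
  stopifnot(
    envelope_scale > 0, truncation_halfwidth > 0, lateral_sigma > 0,
    axial_wavevector > 0, gouy_range > 0, lateral_growth >= 0
  )
  structure(
    list(
      amplitude = amplitude,
      axial_wavevector = axial_wavevector,
      gouy_range = gouy_range,
      envelope_scale = envelope_scale,
      envelope_power = envelope_power,
      sa_coefficient = sa_coefficient,
      phase_offset = phase_offset,
      truncation_halfwidth = truncation_halfwidth,
      lateral_sigma = lateral_sigma,
      lateral_growth = lateral_growth
    ),
    class = "ipsf_model"
  )
}

#' @export
print.ipsf_model <- function(x, ...) {
  cat("Parametric iPSF model\n")
  cat(sprintf("  amplitude A      : %g\n", x$amplitude))
  cat(sprintf("  k_z              : %g rad/nm (period %.1f nm)\n",
              x$axial_wavevector, 2 * pi / x$axial_wavevector))
  cat(sprintf("  Gouy range z_R   : %g nm\n", x$gouy_range))
  cat(sprintf("  envelope         : scale %g nm, power %g\n",
              x$envelope_scale, x$envelope_power))
  cat(sprintf("  SA coefficient   : %g, phase offset %g rad\n",
              x$sa_coefficient, x$phase_offset))
  cat(sprintf("  truncation       : +/- %g nm\n", x$truncation_halfwidth))
  cat(sprintf("  lateral          : sigma %g nm, growth %g nm/nm\n",
              x$lateral_sigma, x$lateral_growth))
  invisible(x)
}

#' Detected iSCAT intensity from reference and scattered fields
#'
#' Normalized detector intensity for a reference field of amplitude
#' reflectance `r` interfering with a scattered field of relative amplitude
#' `s_mag` at phase difference `dphi`:
#' `I_det / |E_inc|^2 = r^2 + s_mag^2 + 2 r s_mag cos(dphi)`.
#'
#' @param r Field reflectance of the reference interface (> 0).
#' @param s_mag Scattered field amplitude relative to the incident field
#'   (>= 0; proportional to the polarizability of the scatterer).
#' @param dphi Phase difference between scattered and reference fields (rad).
#' @return Normalized intensity (vectorized over the inputs).
#' @examples
#' interferometric_intensity(1, 0.1, pi) # 0.81
#' @export
interferometric_intensity <- function(r, s_mag, dphi) {
  if (any(r <= 0)) stop("invalid configuration: reference reflectance r must be positive")
  if (any(s_mag < 0)) stop("scattered amplitude s_mag must be non-negative")
  r^2 + s_mag^2 + 2 * r * s_mag * cos(dphi)
}

#' iSCAT contrast
#'
#' `C = (I_det - I_bg) / I_bg`, the normalized deviation of the detected
#' intensity from the local background.
#'
#' @param i_det Detected intensity.
#' @param i_bg Background intensity (> 0).
#' @return Dimensionless contrast, vectorized.
#' @export
iscat_contrast <- function(i_det, i_bg) {
  if (any(i_bg <= 0)) stop("degenerate background: i_bg must be positive")
  (i_det - i_bg) / i_bg
}

.ipsf_envelope <- function(z, model) {
  (1 + (z / model$envelope_scale)^2)^(-model$envelope_power / 2)
}

.ipsf_phase <- function(z, model) {
  model$axial_wavevector * z + atan(z / model$gouy_range) +
    model$sa_coefficient * (z / model$envelope_scale)^3 + model$phase_offset
}

#' Axial iPSF contrast profile
#'
#' Evaluates the parametric axial iPSF of [ipsf_model()] at defocus
#' `z_defocus` (structure position minus focus position). The profile is
#' exactly zero outside the model's truncation window.
#'
#' @param z_defocus Defocus in nm (vectorized).
#' @param model An [ipsf_model()].
#' @return Signed contrast values.
#' @export
axial_ipsf <- function(z_defocus, model) {
  stopifnot(inherits(model, "ipsf_model"))
  out <- model$amplitude * .ipsf_envelope(z_defocus, model) *
    cos(.ipsf_phase(z_defocus, model))
  out[abs(z_defocus) > model$truncation_halfwidth] <- 0
  out
}

#' Defocus offset of the dominant iPSF extremum
#'
#' Location (in defocus nm) of the global extremum of `|axial_ipsf|`,
#' used by ridge-based interface localization to map the observed extremum
#' back to the interface position.
#'
#' @param model An [ipsf_model()].
#' @return Defocus in nm of the strongest extremum.
#' @keywords internal
ipsf_extremum_offset <- function(model) {
  zz <- seq(-model$truncation_halfwidth, model$truncation_halfwidth, by = 1)
  v <- abs(axial_ipsf(zz, model))
  z0 <- zz[which.max(v)]
  opt <- stats::optimize(function(z) -abs(axial_ipsf(z, model)),
                         interval = c(z0 - 2, z0 + 2))
  opt$minimum
}

# Airy field amplitude 2 J1(v)/v with the v -> 0 limit.
.airy_amp <- function(v) {
  out <- rep(1, length(v))
  nz <- abs(v) > 1e-8
  out[nz] <- 2 * besselJ(abs(v[nz]), 1) / abs(v[nz])
  out
}

# Detection amplitude profile: Airy amplitude convolved (2D) with the
# pinhole disk, evaluated on radii r_nm by polar quadrature.
.pinhole_detection_profile <- function(r_nm, cfg, n_rho = 40, n_theta = 60) {
  R <- cfg$pinhole * airy_unit_nm(cfg) / 2
  kv <- 2 * pi * cfg$numerical_aperture / cfg$wavelength
  rho <- (seq_len(n_rho) - 0.5) / n_rho * R
  theta <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  w <- rho / sum(rho) # area weights for uniform disk, theta uniform
  vapply(r_nm, function(r) {
    d2 <- outer(rho^2, rep(1, n_theta)) + r^2 -
      2 * r * outer(rho, cos(theta))
    sum(.airy_amp(kv * sqrt(pmax(d2, 0))) * w) / n_theta
  }, numeric(1))
}

#' Lateral confocal iSCAT amplitude profile
#'
#' Scalar-model lateral response: product of the illumination Airy amplitude
#' and the detection Airy amplitude convolved with the pinhole disk,
#' normalized to 1 at radius 0 in focus. Defocus widens the profile by
#' scaling the radial coordinate according to `lateral_growth` (width growth
#' per nm defocus, relative to the in-focus Airy radius 0.61 lambda/NA).
#'
#' @param radius Lateral radius in nm (vectorized).
#' @param z_defocus Defocus in nm (scalar).
#' @param cfg An [optical_config()]; its `pinhole` sets the disk size.
#' @param lateral_growth Width growth per nm defocus; default 0.
#' @return Field amplitude, 1 at `radius = 0`, `z_defocus = 0`.
#' @export
lateral_confocal_amplitude <- function(radius, z_defocus = 0, cfg = optical_config(),
                                       lateral_growth = 0) {
  stopifnot(cfg$pinhole > 0)
  r_airy <- 0.61 * cfg$wavelength / cfg$numerical_aperture
  scale <- 1 + lateral_growth * abs(z_defocus) / r_airy
  r_eff <- radius / scale
  kv <- 2 * pi * cfg$numerical_aperture / cfg$wavelength
  h_ill <- .airy_amp(kv * r_eff)
  h_det <- .pinhole_detection_profile(r_eff, cfg)
  h_det0 <- .pinhole_detection_profile(0, cfg)
  h_ill * h_det / h_det0
}

#' Lateral FWHM of the confocal amplitude profile
#'
#' Full width at half maximum of [lateral_confocal_amplitude()] at a given
#' pinhole setting, found by dense evaluation and linear interpolation.
#'
#' @param cfg An [optical_config()].
#' @param z_defocus Defocus in nm.
#' @param lateral_growth See [lateral_confocal_amplitude()].
#' @return FWHM in nm.
#' @export
lateral_fwhm <- function(cfg = optical_config(), z_defocus = 0, lateral_growth = 0) {
  r <- seq(0, 2 * airy_unit_nm(cfg), by = 1)
  a <- lateral_confocal_amplitude(r, z_defocus, cfg, lateral_growth)
  i <- which(a < 0.5)[1]
  if (is.na(i)) stop("profile does not fall below half maximum in range")
  # linear interpolation between samples i-1 and i
  r_half <- r[i - 1] + (0.5 - a[i - 1]) / (a[i] - a[i - 1]) * (r[i] - r[i - 1])
  2 * r_half
}

#' Axial displacement for one full contrast inversion
#'
#' The axial displacement that changes the interferometric phase
#' `4 pi n z / lambda` by pi, i.e. `lambda / (4 n_eff)`. This is the
#' calibration that converts a full swing of the iSCAT contrast (from +Cmax
#' to -Cmax) into nm of axial travel for single-plane 3D tracking.
#'
#' @param cfg An [optical_config()] (supplies the wavelength).
#' @param effective_index Effective refractive index entering the phase;
#'   exposed explicitly because the empirical calibration of tracking data
#'   may differ from the nominal medium index.
#' @return Displacement in nm.
#' @examples
#' full_inversion_distance(optical_config(wavelength = 445), 1.0) # 111.25
#' @export
full_inversion_distance <- function(cfg = optical_config(), effective_index = 1.0) {
  stopifnot(effective_index > 0)
  cfg$wavelength / (4 * effective_index)
}

#' Serialize optics parameters to a flat key-value text file
#'
#' Writes one `key: value` pair per line (nm units) for an
#' [optical_config()] or [ipsf_model()]; [read_optics_config()] restores the
#' object.
#'
#' @param x An `optical_config` or `ipsf_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_optics_config <- function(x, path) {
  stopifnot(inherits(x, "optical_config") || inherits(x, "ipsf_model"))
  rec <- c(list(.class = class(x)[1]), unclass(x))
  yaml::write_yaml(rec, path, precision = 15)
  invisible(path)
}

#' @rdname write_optics_config
#' @export
read_optics_config <- function(path) {
  rec <- yaml::read_yaml(path)
  cls <- rec$.class
  rec$.class <- NULL
  if (is.null(cls) || !cls %in% c("optical_config", "ipsf_model"))
    stop("file does not contain a serialized optics configuration")
  do.call(cls, rec)
}
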