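test_that("interferometric intensity matches the complex-field oracle", {
  # oracle: |r + s e^{i dphi}|^2 by complex arithmetic
  set.seed(11)
  n <- 1000
  r <- runif(n, 0.01, 1)
  s <- runif(n, 0, 0.5)
  dphi <- runif(n, -2 * pi, 2 * pi)
  oracle <- Mod(complex(real = r, imaginary = 0) + s * exp(1i * dphi))^2
  expect_equal(interferometric_intensity(r, s, dphi), oracle,
               tolerance = 1e-12)
  expect_equal(interferometric_intensity(1, 0, 123.4), 1.0)
  expect_equal(interferometric_intensity(1, 0.1, pi), 0.81)
  expect_error(interferometric_intensity(0, 0.1, 0), "positive")
})

test_that("contrast definition and its linearized small-signal limit hold", {
  expect_equal(iscat_contrast(0.81, 1.0), -0.19)
  expect_equal(iscat_contrast(0.5, 0.5), 0)
  i <- interferometric_intensity(0.2, 0.02, 0)
  expect_equal(iscat_contrast(i, 0.04), 0.21)
  expect_error(iscat_contrast(1, 0), "background")
  # for s << r, C -> 2 (s/r) cos(dphi) to relative accuracy |s/r|
  r <- 0.3
  for (s in c(1e-3, 1e-4)) for (dphi in c(0, 1, 2.5)) {
    C <- iscat_contrast(interferometric_intensity(r, s, dphi), r^2)
    lin <- 2 * (s / r) * cos(dphi)
    if (abs(lin) > 0)
      expect_lt(abs(C - lin) / abs(2 * s / r), abs(s / r) * 1.01)
  }
})

test_that("axial iPSF has the stated envelope, truncation and fringe spacing", {
  m <- test_ipsf(amplitude = 0.07)
  expect_equal(axial_ipsf(0, m), 0.07)
  expect_identical(axial_ipsf(c(-1501, 1600, 5000), m), c(0, 0, 0))
  # near-focus zero-crossing spacing = lambda / (4 n), numerical root oracle
  free <- ipsf_model(amplitude = 1, gouy_range = 1e9, envelope_scale = 1e9,
                     truncation_halfwidth = 1e9)
  f <- function(z) axial_ipsf(z, free)
  z1 <- uniroot(f, c(10, 100))$root
  z2 <- uniroot(f, c(z1 + 10, z1 + 150))$root
  expect_equal(z2 - z1, 445 / (4 * 1.33), tolerance = 0.02)
  # confocal envelope drops quadratically: ratio 4 between 10 and 20 scales
  conf <- ipsf_model(amplitude = 1, envelope_scale = 100, envelope_power = 2,
                     truncation_halfwidth = 1e5)
  env <- function(z) abs(axial_ipsf(z, conf)) /
    abs(cos(conf$axial_wavevector * z + atan(z / conf$gouy_range)))
  expect_equal(env(1000) / env(2000), 4, tolerance = 0.01)
  # symmetric envelope and sign-alternating extrema when SA = 0
  zz <- seq(-1400, 1400, by = 1)
  v <- axial_ipsf(zz, m)
  ex <- which(diff(sign(diff(v))) != 0) + 1
  big <- ex[abs(v[ex]) > 0.05 * max(abs(v))]
  expect_true(all(diff(sign(v[big])) != 0))
  envv <- (1 + (zz / m$envelope_scale)^2)^(-m$envelope_power / 2)
  expect_equal(envv, rev(envv))
})

test_that("lateral confocal profile is normalized and narrows with pinhole", {
  cfg <- test_cfg()
  expect_equal(lateral_confocal_amplitude(0, 0, cfg), 1.0)
  expect_equal(airy_unit_nm(cfg), 1.22 * 445 / 1.45)
  f03 <- lateral_fwhm(optical_config(pinhole = 0.3))
  f12 <- lateral_fwhm(optical_config(pinhole = 1.2))
  expect_lt(f03, f12)
  # monotone non-decreasing FWHM over pinhole settings
  fw <- vapply(c(0.1, 0.5, 1, 1.5, 2),
               function(p) lateral_fwhm(optical_config(pinhole = p)),
               numeric(1))
  expect_true(all(diff(fw) >= -1e-9))
})

test_that("full-inversion distance follows lambda / (4 n_eff)", {
  cfg <- test_cfg()
  expect_equal(full_inversion_distance(cfg, 1.0), 111.25)
  expect_equal(round(full_inversion_distance(cfg, 1.0) / 10) * 10, 110)
  expect_equal(full_inversion_distance(cfg, 1.365), 445 / (4 * 1.365))
  cfg2 <- optical_config(wavelength = 890)
  expect_equal(full_inversion_distance(cfg2, 1.0),
               2 * full_inversion_distance(cfg, 1.0))
})

test_that("optics objects serialize to flat key-value files and back", {
  p1 <- file.path(tempdir(), "cfg.yaml")
  p2 <- file.path(tempdir(), "ipsf.yaml")
  cfg <- optical_config(wavelength = 520, medium_index = 1.365)
  write_optics_config(cfg, p1)
  expect_equal(read_optics_config(p1), cfg)
  m <- ipsf_model(amplitude = -0.12, sa_coefficient = 0.3,
                  phase_offset = 0.4)
  write_optics_config(m, p2)
  expect_equal(read_optics_config(p2), m)
  bad <- file.path(tempdir(), "bad.yaml")
  yaml::write_yaml(list(a = 1), bad)
  expect_error(read_optics_config(bad), "optics configuration")
})

test_that("configuration invariants are enforced", {
  expect_error(optical_config(wavelength = -1))
  expect_error(optical_config(reference_reflectivity = 1.5), "0, 1")
  expect_error(ipsf_model(envelope_scale = -5))
  expect_error(ipsf_model(lateral_sigma = 0))
})
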