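# Shared fixtures: a default instrument, iPSF model, and small renderers.

test_cfg <- function(...) optical_config(...)

test_ipsf <- function(amplitude = 0.1, ...) ipsf_model(amplitude = amplitude, ...)

# Contrast of a noiseless rendered stack against the bare-glass background.
raw_contrast <- function(stack, cfg = test_cfg()) {
  r <- cfg$reference_reflectivity
  (stack$values - r^2) / r^2
}

# Noiseless z-stack of a single planar interface at height z0.
planar_interface_stack <- function(z0 = 1000, focus = seq(0, 2000, by = 30),
                                   extent = c(12, 12), amplitude = 0.1,
                                   cfg = test_cfg(), ipsf = test_ipsf(amplitude)) {
  ph <- make_membrane_phantom(extent_px = extent, ripple_rms = 0,
                              base_height = z0, amplitude = amplitude)
  render_acquisition(ph, acquisition_plan(focus_nm = focus,
                                          photon_budget = Inf),
                     cfg, ipsf, noise = FALSE)
}

# A single particle at a pixel-centre position, one rendered frame.
single_particle_stack <- function(x_nm = 945, y_nm = 945, z_nm = 0,
                                  s_mag = 0.01, focus = 0,
                                  extent = c(64, 64),
                                  photon_budget = Inf, seed = 1,
                                  cfg = test_cfg(), ipsf = test_ipsf()) {
  ph <- phantom(particles = list(times = 0,
                                 positions = array(c(x_nm, y_nm, z_nm),
                                                   c(1, 3, 1)),
                                 s_mag = s_mag, phase = 0),
                extent_px = extent, pixel_size = 30)
  render_acquisition(ph, acquisition_plan(focus_nm = focus, n_frames = 1,
                                          photon_budget = photon_budget),
                     cfg, ipsf, seed = seed,
                     noise = is.finite(photon_budget))
}
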