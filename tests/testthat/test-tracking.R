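test_that("Hessian ridge segmentation recovers tubule centerlines", {
  cfg <- test_cfg(); ipsf <- test_ipsf()
  expect_true(all(!hessian_ridge_segment(matrix(0.5, 32, 32), 80, 0.001)))
  ph <- phantom(tubules = list(list(path = rbind(c(240, 960), c(3600, 960)),
                                    radius = 40, amplitude = -0.12,
                                    z = 200)),
                extent_px = c(64, 128), pixel_size = 30)
  st <- render_acquisition(ph, acquisition_plan(focus_nm = 200,
                                                photon_budget = Inf),
                           cfg, ipsf, noise = FALSE)
  cmv <- raw_contrast(st)[, , 1]
  mask <- hessian_ridge_segment(cmv, scale_nm = 80, threshold = 0.005,
                                pixel_size = 30, polarity = "dark")
  centre <- mask[32, 10:118]
  expect_gte(mean(centre), 0.95)
  # false positives: area beyond 5 px of the centerline
  far <- mask[c(1:24, 40:64), ]
  expect_lte(mean(far), 0.02)
  # X-crossing: both arms present
  phx <- phantom(tubules = list(
    list(path = rbind(c(240, 240), c(3600, 3600)), radius = 40,
         amplitude = -0.12, z = 200),
    list(path = rbind(c(240, 3600), c(3600, 240)), radius = 40,
         amplitude = -0.12, z = 200)),
    extent_px = c(128, 128), pixel_size = 30)
  stx <- render_acquisition(phx, acquisition_plan(focus_nm = 200,
                                                  photon_budget = Inf),
                            cfg, ipsf, noise = FALSE)
  mx <- hessian_ridge_segment(raw_contrast(stx)[, , 1], 80, 0.005,
                              polarity = "dark")
  diag_on <- mean(mx[cbind(20:108, 20:108)])
  anti_on <- mean(mx[cbind(20:108, 128 - (20:108) + 1)])
  expect_gt(diag_on, 0.8)
  expect_gt(anti_on, 0.8)
})

test_that("radial variance transform scores ringed patterns at their centre", {
  expect_true(all(radial_variance_transform(matrix(3, 32, 32), 0, 6) == 0))
  # synthetic ringed iPSF, centre at a known subpixel-free position
  st <- single_particle_stack(x_nm = 945, y_nm = 945, z_nm = 500,
                              s_mag = 0.01)
  cmv <- raw_contrast(st)[, , 1]
  sc <- radial_variance_transform(cmv, 0, 10)
  det <- localize_particles(sc, cmv, threshold = 0.5 * max(sc))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 32), 0.1)
  expect_lt(abs(det$y_px - 32), 0.1)
  # sign insensitivity: inverted pattern gives the identical score map
  expect_equal(radial_variance_transform(-cmv, 0, 10), sc)
  # affine invariance: a * I + b scales scores by a^2
  sc2 <- radial_variance_transform(3 * cmv + 0.7, 0, 10)
  expect_equal(sc2, 9 * sc, tolerance = 1e-8)
  expect_error(radial_variance_transform(matrix(1, 16, 16), 0, 20),
               "too large")
})

test_that("particle localization separates neighbours and is shot-noise limited", {
  cfg <- test_cfg()
  ph <- phantom(particles = list(
    times = 0,
    positions = array(c(645, 945, 0, 1665, 945, 0), c(1, 3, 2)),
    s_mag = c(0.01, 0.01), phase = c(0, 0)),
    extent_px = c(64, 64), pixel_size = 30)
  st <- render_acquisition(ph, acquisition_plan(focus_nm = 0,
                                                photon_budget = Inf),
                           cfg, test_ipsf(), noise = FALSE)
  cmv <- raw_contrast(st)[, , 1]
  sc <- radial_variance_transform(cmv, 0, 8)
  det <- localize_particles(sc, cmv, threshold = 0.2 * max(sc),
                            min_separation_px = 5)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_px), ]
  expect_lt(abs(det$x_px[1] - 22), 0.2)
  expect_lt(abs(det$x_px[2] - 56), 0.2)
  expect_identical(
    nrow(localize_particles(matrix(0, 32, 32) + 1e-12,
                            matrix(0, 32, 32), threshold = 1)), 0L)
})

test_that("linking yields complete single trajectories and respects min length", {
  # one slowly moving particle across 100 frames
  det <- data.frame(frame = 1:100, x = seq(0, 990, by = 10), y = 50)
  lk <- link_trajectories(det, max_disp = 50, min_length = 25)
  expect_equal(length(unique(lk$trajectory)), 1)
  expect_equal(nrow(lk), 100)
  # tracks shorter than min_length are dropped entirely
  det2 <- rbind(det, data.frame(frame = 1:10, x = 5000, y = 5000))
  lk2 <- link_trajectories(det2, max_disp = 50, min_length = 25)
  expect_equal(length(unique(lk2$trajectory)), 1)
  expect_true(all(table(lk2$trajectory) >= 25))
  # partition property: each detection in at most one trajectory
  expect_lte(nrow(lk2), nrow(det2))
  expect_false(any(duplicated(lk2[, c("frame", "x", "y")])))
})

test_that("linking preserves ground-truth identities at sparse density", {
  pe <- make_particle_ensemble(n = 10, diffusion = 2e3, duration = 3,
                               dt = 0.05, extent_px = c(128, 128),
                               seed = 7, lateral_only = TRUE)
  tr <- pe$particles$positions
  nt <- dim(tr)[1]
  det <- do.call(rbind, lapply(seq_len(nt), function(t)
    data.frame(frame = t, x = tr[t, 1, ], y = tr[t, 2, ], id = 1:10)))
  lk <- link_trajectories(det, max_disp = 300, min_length = 25)
  purity <- tapply(lk$id, lk$trajectory, function(v) mean(v == v[1]))
  expect_gte(mean(unlist(purity)), 0.95)
})

test_that("contrast-to-z inversion is the left inverse of the phase model", {
  cal <- iscat_calibration(c_max = 0.2, full_inversion_nm = 111.25)
  expect_true(all(contrast_to_dz(rep(0.15, 20), cal) == 0))
  # full swing +c_max -> -c_max equals one full inversion distance
  sw <- 0.2 * cos(seq(0, pi, length.out = 50))
  z <- contrast_to_dz(sw, cal)
  expect_equal(max(abs(z)), 111.25)
  # property: random walks with |dz| < L/4 per step invert exactly while the
  # phase stays on one cosine branch (reflected at 8 and 103 nm; at the
  # branch points 0 and L the cosine is even and the sign is unidentifiable)
  set.seed(17)
  L <- 111.25
  for (rep in 1:20) {
    dz <- runif(60, -L / 4, L / 4)
    zt <- numeric(61); zt[1] <- 40
    for (i in 1:60) {
      z <- zt[i] + dz[i]
      if (z > 103) z <- 2 * 103 - z
      if (z < 8) z <- 2 * 8 - z
      zt[i + 1] <- z
    }
    cc <- 0.2 * cos(pi * zt / L)
    zr <- contrast_to_dz(cc, cal)
    expect_equal(as.numeric(zr), zt - zt[1], tolerance = 1e-9)
  }
  # inward-only prior produces monotone non-decreasing displacement
  cc <- 0.2 * cos(seq(0.2, 2.8, length.out = 40))
  zi <- contrast_to_dz(cc, iscat_calibration(0.2, 111.25, "inward_only"))
  expect_true(all(diff(zi) >= -1e-9))
  # violations
  expect_error(contrast_to_dz(c(0.1, 0.25), cal), "calibration violation")
  expect_warning(contrast_to_dz(c(0.1, 0.21), cal), "clipped")
})

test_that("contrast-calibrated axial tracking recovers a rendered descent", {
  cfg <- test_cfg(); ipsf <- test_ipsf()
  # particle descending 40 nm in 1 nm steps, constant focus; phase chosen
  # mid-branch so the cosine inversion is well conditioned
  n_eff_slope <- (ipsf$axial_wavevector +
                    1 / ipsf$gouy_range) * 445 / (4 * pi)
  L <- 445 / (4 * n_eff_slope)
  z_start <- 25
  zs <- z_start + seq(0, 40, by = 1)
  pos <- array(0, c(length(zs), 3, 1))
  pos[, 1, ] <- 945; pos[, 2, ] <- 945; pos[, 3, ] <- zs
  s_mag <- 0.002  # keep |s|^2 / r^2 offset negligible against 2 s/r
  ph <- phantom(particles = list(times = seq_along(zs) - 1, positions = pos,
                                 s_mag = s_mag, phase = 0),
                extent_px = c(48, 48), pixel_size = 30)
  plan <- acquisition_plan(focus_nm = 0, n_frames = length(zs),
                           frame_interval = 1, photon_budget = Inf)
  st <- render_acquisition(ph, plan, cfg, ipsf, noise = FALSE)
  cmv <- raw_contrast(st)
  cc <- cmv[32, 32, ]
  r <- cfg$reference_reflectivity
  c_max <- 2 * s_mag / r   # small-signal calibration at this envelope
  cal <- iscat_calibration(c_max = c_max, full_inversion_nm = L)
  z_rel <- suppressWarnings(contrast_to_dz(cc, cal))
  rmse <- sqrt(mean((as.numeric(z_rel) - (zs - zs[1]))^2))
  expect_lt(rmse, 5)
})

test_that("trajectory statistics match their generators", {
  still <- data.frame(frame = 1:30, x = 3, y = 4, contrast = 0.1)
  s <- trajectory_stats(still, frame_interval = 0.1)
  expect_equal(s$rmsd, 0)
  expect_equal(s$contrast_swing, 0)
  # Brownian ensemble: mean lag-1 MSD = 4 D dt within 10%
  D <- 4e3; dt <- 0.05
  pe <- make_particle_ensemble(n = 100, diffusion = D, duration = 3,
                               dt = dt, seed = 23, lateral_only = TRUE)
  tr <- pe$particles$positions
  nt <- dim(tr)[1]
  det <- do.call(rbind, lapply(seq_len(nt), function(t)
    data.frame(frame = t, x = tr[t, 1, ], y = tr[t, 2, ],
               trajectory = 1:100)))
  expect_equal(ensemble_msd(det, 1), 4 * D * dt, tolerance = 0.1)
  # constant-velocity track: mean speed within 5%
  v <- 2000
  tt <- seq(0, 2, by = 0.05)
  mov <- data.frame(frame = seq_along(tt), t_s = tt, x = v * tt, y = 0)
  expect_equal(trajectory_stats(mov)$mean_speed, v, tolerance = 0.05)
})

test_that("colocalization fraction matches binomial expectation", {
  mask <- matrix(FALSE, 64, 64); mask[, 1:16] <- TRUE
  det_in <- data.frame(x_px = runif(20, 2, 15), y_px = runif(20, 2, 63))
  expect_equal(colocalization_fraction(det_in, mask, 0, 30), 1.0)
  det_out <- data.frame(x_px = runif(20, 30, 63), y_px = runif(20, 2, 63))
  expect_equal(colocalization_fraction(det_out, mask, 0, 30), 0.0)
  expect_error(colocalization_fraction(det_out[0, ], mask, 0, 30),
               "undefined")
  set.seed(3)
  det_u <- data.frame(x_px = runif(1000, 1, 64), y_px = runif(1000, 1, 64))
  p <- mean(mask)
  f <- colocalization_fraction(det_u, mask, 0, 30)
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / 1000) + 0.02)
})
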