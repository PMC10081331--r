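test_that("interface localization recovers a noiseless rendered interface", {
  ipsf <- test_ipsf(0.1)
  foc <- seq(0, 2000, by = 30)
  st <- planar_interface_stack(z0 = 1000, focus = foc, ipsf = ipsf)
  prof <- raw_contrast(st)[6, 6, ]
  ridge <- locate_interface(foc, prof, ipsf, method = "ridge")
  expect_true(ridge$valid)
  expect_lt(abs(ridge$z0 - 1000), 15)
  fit <- locate_interface(foc, prof, ipsf, method = "fit")
  expect_true(fit$valid)
  expect_lt(abs(fit$z0 - 1000), 5)
  # fit and ridge agree within one z-step on noiseless profiles
  expect_lt(abs(fit$z0 - ridge$z0), 30)
  # model self-consistency: profile that is exactly the iPSF centred at 0
  zz <- seq(-900, 900, by = 30)
  prof0 <- axial_ipsf(0 - zz, ipsf)
  self <- locate_interface(zz, prof0, ipsf, method = "ridge")
  expect_lt(abs(self$z0), 1)
})

test_that("two interfaces in one profile are separated by search windows", {
  ipsf <- test_ipsf(0.1)
  zz <- seq(0, 7000, by = 30)
  prof <- axial_ipsf(1000 - zz, ipsf) + 0.6 * axial_ipsf(6000 - zz, ipsf)
  lo <- locate_interface(zz, prof, ipsf, search_window = c(0, 3000))
  hi <- locate_interface(zz, prof, ipsf, search_window = c(4000, 7000))
  expect_lt(abs(lo$z0 - 1000), 15)
  expect_lt(abs(hi$z0 - 6000), 15)
})

test_that("staircase steps are recovered within 10 nm", {
  ipsf <- test_ipsf(0.1)
  ph <- make_staircase_phantom(extent_px = c(24, 48), step_height = 50,
                               n_steps = 4, base_height = 600)
  foc <- seq(0, 1600, by = 30)
  st <- render_acquisition(ph, acquisition_plan(focus_nm = foc,
                                                photon_budget = Inf),
                           test_cfg(), ipsf, noise = FALSE)
  hm <- reconstruct_surface(raw_contrast(st), focus_nm = foc, ipsf = ipsf)
  truth <- ph$interfaces[[1]]$heights
  expect_gt(mean(hm$validity), 0.95)
  est <- tapply(hm$heights[hm$validity], truth[hm$validity], median)
  expect_true(all(abs(est - as.numeric(names(est))) < 10))
  steps <- diff(est)
  expect_true(all(abs(steps - 50) < 10))
})

test_that("planar interface reconstructs flat at realistic photon budget", {
  ipsf <- test_ipsf(0.1)
  foc <- seq(0, 2000, by = 30)
  ph <- make_membrane_phantom(extent_px = c(48, 48), ripple_rms = 0,
                              base_height = 1000)
  st <- render_acquisition(ph, acquisition_plan(focus_nm = foc,
                                                photon_budget = 1e4),
                           test_cfg(), ipsf, seed = 6)
  # a laterally uniform interface has no high-frequency content, so the
  # bare-glass reflectivity serves as the background (blurring would
  # subtract the signal itself)
  r <- test_cfg()$reference_reflectivity
  cm <- contrast_map(st$values, array(r^2, dim(st$values)))
  hm <- reconstruct_surface(cm$values, focus_nm = foc, ipsf = ipsf)
  err <- hm$heights - 1000
  rmse <- sqrt(mean(err[hm$validity]^2, na.rm = TRUE))
  expect_lt(rmse, 15)   # z_step / 2
})

test_that("rippled membranes are recovered with correct peak-to-valley", {
  ipsf <- test_ipsf(0.1)
  ph <- make_membrane_phantom(extent_px = c(64, 64), ripple_rms = 150,
                              correlation_length = 1000,
                              base_height = 1000, seed = 13)
  truth <- ph$interfaces[[1]]$heights
  foc <- seq(min(truth) - 400, max(truth) + 400, by = 30)
  st <- render_acquisition(ph, acquisition_plan(focus_nm = foc,
                                                photon_budget = 1e4),
                           test_cfg(), ipsf, seed = 14)
  cm <- compute_contrast(st, psf_fwhm = lateral_fwhm(test_cfg()))
  hm <- reconstruct_surface(cm$values, focus_nm = foc, ipsf = ipsf)
  expect_gt(mean(hm$validity), 0.9)
  p2v_true <- diff(range(truth))
  p2v_est <- diff(range(hm$heights[hm$validity], na.rm = TRUE))
  expect_lt(abs(p2v_est - p2v_true) / p2v_true, 0.15)
})

test_that("reconstruction error decreases with photon budget and is scale-free", {
  ipsf <- test_ipsf(0.1)
  foc <- seq(0, 2000, by = 30)
  ph <- make_membrane_phantom(extent_px = c(32, 32), ripple_rms = 0,
                              base_height = 1000)
  r <- test_cfg()$reference_reflectivity
  rmse <- vapply(c(1e2, 1e3, 1e4), function(pb) {
    st <- render_acquisition(ph, acquisition_plan(focus_nm = foc,
                                                  photon_budget = pb),
                             test_cfg(), ipsf, seed = 20)
    cm <- contrast_map(st$values, array(r^2, dim(st$values)))
    hm <- reconstruct_surface(cm$values, focus_nm = foc, ipsf = ipsf,
                              noise_floor = 1 / sqrt(pb))
    sqrt(stats::median((hm$heights[hm$validity] - 1000)^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  # invariance to global contrast rescaling
  st <- planar_interface_stack(z0 = 1000, focus = foc, extent = c(8, 8),
                               ipsf = ipsf)
  cmv <- raw_contrast(st)
  h1 <- reconstruct_surface(cmv, focus_nm = foc, ipsf = ipsf)
  h5 <- reconstruct_surface(5 * cmv, focus_nm = foc, ipsf = ipsf)
  expect_equal(h1$heights, h5$heights, tolerance = 1e-10)
})

test_that("edge sharpness matches closed forms and benefits from averaging", {
  # Gaussian-blurred step: width = 2 * 1.2816 sigma
  x <- seq(-3000, 3000, by = 10)
  sigma <- 400
  y <- pnorm(x / sigma)
  expect_equal(edge_sharpness_1090(x, y), 2 * qnorm(0.9) * sigma,
               tolerance = 0.02)
  # linear ramp of length L -> 0.8 L
  L <- 1200
  ramp <- approxfun(c(-2000, -L / 2, L / 2, 2000), c(0, 0, 1, 1), rule = 2)
  expect_equal(edge_sharpness_1090(x, ramp(x)), 0.8 * L, tolerance = 0.01)
  expect_error(edge_sharpness_1090(x, rep(1, length(x))), "transition")
  # averaging three parallel cuts reduces estimator variance
  set.seed(40)
  w_single <- replicate(60, {
    edge_sharpness_1090(x, pnorm(x / sigma) + rnorm(length(x), 0, 0.02))
  })
  w_avg <- replicate(60, {
    yy <- (pnorm(x / sigma) + rnorm(length(x), 0, 0.02) +
             pnorm(x / sigma) + rnorm(length(x), 0, 0.02) +
             pnorm(x / sigma) + rnorm(length(x), 0, 0.02)) / 3
    edge_sharpness_1090(x, yy)
  })
  expect_lt(var(w_avg), var(w_single))
})

test_that("rendered lateral membrane edge width tracks the lateral PSF", {
  cfg <- test_cfg(); ipsf <- test_ipsf(0.1)
  # a wide dark strip (rendered through the in-focus lateral PSF) provides a
  # sharp membrane-like edge; cut a lateral line profile across it
  ny <- 32; nx <- 64
  ph2 <- phantom(tubules = list(list(path = rbind(c(1500, -100), c(1500, 2000)),
                                     radius = 450, amplitude = -0.1,
                                     z = 1000)),
                 extent_px = c(ny, nx), pixel_size = 30)
  st <- render_acquisition(ph2, acquisition_plan(focus_nm = 1000,
                                                 photon_budget = Inf),
                           cfg, ipsf, noise = FALSE)
  prof <- raw_contrast(st)[16, 1:40, 1]
  w <- edge_sharpness_1090(seq_along(prof) * 30, -prof)
  # 10-90% width of a PSF-blurred edge: 2.563 * lateral sigma
  expect_equal(w, 2 * qnorm(0.9) * ipsf$lateral_sigma, tolerance = 0.2)
})
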