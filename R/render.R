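# Forward image formation: phantom + acquisition plan + optics -> intensity
# stack. Particles are summed coherently in the field (so Gouy-phase contrast
# reversal emerges from the model); interfaces and tubules act through the
# axial iPSF as multiplicative thin-interface contrast, which is how the
# inverse analyses treat them and keeps rendering O(pixels).

# Unit-amplitude axial iPSF (phase structure only).
.unit_ipsf <- function(z, model) axial_ipsf(z, model) / model$amplitude

# Min distance from every pixel center to a polyline, in nm.
.polyline_distance <- function(ny, nx, pixel_size, path) {
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  X <- outer(rep(1, ny), px)
  Y <- outer(py, rep(1, nx))
  d2 <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    ab <- b - a; len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- pmin(d2, (X - a[1])^2 + (Y - a[2])^2)
    } else {
      t <- pmin(pmax(((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2, 0), 1)
      d2 <- pmin(d2, (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2)
    }
  }
  sqrt(d2)
}

# Lateral footprint of each tubule: indicator(d <= radius) blurred with the
# in-focus lateral PSF, peak-normalized. Computed once per phantom.
.tubule_profiles <- function(ph, ipsf) {
  lapply(ph$tubules, function(tb) {
    d <- .polyline_distance(ph$extent_px[1], ph$extent_px[2], ph$pixel_size,
                            tb$path)
    occ <- (d <= tb$radius) * 1
    prof <- .gblur_mirror(occ, ipsf$lateral_sigma / ph$pixel_size)
    m <- max(prof)
    if (m > 0) prof <- prof / m
    prof
  })
}

#' Render a phantom into a noisy iSCAT intensity stack
#'
#' Simulates the acquisition described by `plan`: per frame, point
#' scatterers add coherently to the reference field `r` with lateral
#' Gaussian footprints, axial envelope attenuation and the full
#' interferometric phase `k_z z + Gouy + intrinsic`; interfaces and tubules
#' multiply the background by `1 + A * ipsf(z_structure - focus)` (tubule
#' cross-sections are blurred with the in-focus lateral PSF). Poisson shot
#' noise is applied at the plan's photon budget, so the returned intensities
#' have background mean `r^2` and relative pixel noise
#' `1/sqrt(photon_budget)`.
#'
#' @param ph A [phantom()].
#' @param plan An [acquisition_plan()].
#' @param cfg An [optical_config()].
#' @param ipsf An [ipsf_model()]; for wide-field plans use
#'   `envelope_power = 1`.
#' @param seed Integer seed for the shot noise.
#' @param noise If `FALSE` (or `photon_budget = Inf`), return the noiseless
#'   expectation.
#' @return An [iscat_stack()] with axes `(y, x, z)` for z-stacks or
#'   `(y, x, t)` for time series. Ground-truth particle pixel coordinates
#'   (if any) are stored in `$meta$truth`.
#' @export
render_acquisition <- function(ph, plan, cfg = optical_config(),
                               ipsf = ipsf_model(), seed = 1, noise = TRUE) {
  stopifnot(inherits(ph, "phantom"), inherits(plan, "acquisition_plan"))
  ny <- ph$extent_px[1]; nx <- ph$extent_px[2]
  is_zstack <- length(plan$focus_nm) > 1
  nframe <- if (is_zstack) length(plan$focus_nm) else plan$n_frames
  r <- cfg$reference_reflectivity
  tub_prof <- .tubule_profiles(ph, ipsf)
  px <- (seq_len(nx) - 0.5) * ph$pixel_size
  py <- (seq_len(ny) - 0.5) * ph$pixel_size
  out <- array(0, dim = c(ny, nx, nframe))
  set.seed(seed)
  for (k in seq_len(nframe)) {
    focus <- if (is_zstack) plan$focus_nm[k] else plan$focus_nm[1]
    t_s <- if (is_zstack) 0 else (k - 1) * plan$frame_interval
    field <- matrix(complex(real = r, imaginary = 0), ny, nx)
    if (!is.null(ph$particles)) {
      ti <- .nearest_time_index(ph$particles$times, t_s)
      n <- dim(ph$particles$positions)[3]
      for (i in seq_len(n)) {
        p <- ph$particles$positions[ti, , i]
        dz <- p[3] - focus
        if (abs(dz) > ipsf$truncation_halfwidth) next
        sig <- ipsf$lateral_sigma + ipsf$lateral_growth * abs(dz)
        half <- ceiling(4 * sig / ph$pixel_size)
        cx <- round(p[1] / ph$pixel_size + 0.5)
        cy <- round(p[2] / ph$pixel_size + 0.5)
        xs <- max(1, cx - half):min(nx, cx + half)
        ys <- max(1, cy - half):min(ny, cy + half)
        if (!length(xs) || !length(ys)) next
        rho2 <- outer((py[ys] - p[2])^2, rep(1, length(xs))) +
          outer(rep(1, length(ys)), (px[xs] - p[1])^2)
        env <- .ipsf_envelope(dz, ipsf)
        phase <- ipsf$axial_wavevector * p[3] + atan(dz / ipsf$gouy_range) +
          ipsf$sa_coefficient * (dz / ipsf$envelope_scale)^3 +
          ph$particles$phase[i]
        amp <- ph$particles$s_mag[i] * env * exp(-rho2 / (2 * sig^2))
        field[ys, xs] <- field[ys, xs] + amp * exp(1i * phase)
      }
    }
    intensity <- Mod(field)^2
    cmul <- matrix(1, ny, nx)
    for (f in ph$interfaces)
      cmul <- cmul * (1 + f$amplitude * .unit_ipsf(f$heights - focus, ipsf))
    for (j in seq_along(ph$tubules)) {
      tb <- ph$tubules[[j]]
      cmul <- cmul * (1 + tb$amplitude * .unit_ipsf(tb$z - focus, ipsf) *
                        tub_prof[[j]])
    }
    intensity <- intensity * cmul
    if (noise && is.finite(plan$photon_budget)) {
      lam <- plan$photon_budget * intensity / r^2
      intensity <- matrix(stats::rpois(ny * nx, lam), ny, nx) /
        plan$photon_budget * r^2
    }
    out[, , k] <- intensity
  }
  meta <- list(mode = plan$mode, photon_budget = plan$photon_budget,
               seed = seed, reference_reflectivity = r)
  if (!is.null(ph$particles))
    meta$truth <- .particle_truth(ph, plan)
  iscat_stack(out,
              axes = c("y", "x", if (is_zstack) "z" else "t"),
              pixel_size = ph$pixel_size,
              focus_nm = plan$focus_nm,
              frame_interval = if (is_zstack) NA_real_ else plan$frame_interval,
              meta = meta)
}

.nearest_time_index <- function(times, t_s) {
  which.min(abs(times - t_s))
}

# Ground-truth particle pixel positions per rendered frame.
.particle_truth <- function(ph, plan) {
  is_zstack <- length(plan$focus_nm) > 1
  nframe <- if (is_zstack) length(plan$focus_nm) else plan$n_frames
  n <- dim(ph$particles$positions)[3]
  recs <- vector("list", nframe)
  for (k in seq_len(nframe)) {
    t_s <- if (is_zstack) 0 else (k - 1) * plan$frame_interval
    ti <- .nearest_time_index(ph$particles$times, t_s)
    recs[[k]] <- data.frame(
      frame = k, particle = seq_len(n),
      x_px = ph$particles$positions[ti, 1, ] / ph$pixel_size + 0.5,
      y_px = ph$particles$positions[ti, 2, ] / ph$pixel_size + 0.5,
      z_nm = ph$particles$positions[ti, 3, ]
    )
  }
  do.call(rbind, recs)
}
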