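# Multi-plane interface reconstruction: invert contrast z-stacks into height
# maps by locating, per pixel, the axial position of the iPSF signature.

# 3-point parabolic vertex offset (in sample units) around index i of y.
.parabolic_delta <- function(y_m1, y_0, y_p1) {
  den <- y_m1 - 2 * y_0 + y_p1
  d <- ifelse(abs(den) > 0, 0.5 * (y_m1 - y_p1) / den, 0)
  pmin(pmax(d, -1), 1)
}

# Gaussian smoothing matrix along the z axis (columns normalized), used to
# rectify-and-demodulate |C| profiles into their slowly varying envelope.
.z_smoother <- function(nz, sigma_samples) {
  S <- outer(seq_len(nz), seq_len(nz),
             function(i, j) exp(-(i - j)^2 / (2 * sigma_samples^2)))
  sweep(S, 2, colSums(S), `/`)
}

# Defocus positions of the local extrema of |unit iPSF|, strongest lobes
# first (positions in nm, refined on a 1 nm grid by parabolic interpolation).
.ipsf_lobe_offsets <- function(model, n_lobes = 9) {
  zz <- seq(-model$truncation_halfwidth, model$truncation_halfwidth, by = 1)
  v <- abs(axial_ipsf(zz, model))
  n <- length(v)
  loc <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  if (!length(loc)) return(0)
  ord <- order(v[loc], decreasing = TRUE)
  loc <- loc[ord][seq_len(min(n_lobes, length(loc)))]
  d <- .parabolic_delta(v[loc - 1], v[loc], v[loc + 1])
  zz[loc] + d
}

# k-radius NA-tolerant 2D median filter.
.median_filter <- function(h, rad = 1) {
  ny <- nrow(h); nx <- ncol(h)
  offs <- expand.grid(dy = -rad:rad, dx = -rad:rad)
  st <- array(NA_real_, c(ny, nx, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    iy <- pmin(pmax(seq_len(ny) + offs$dy[k], 1), ny)
    ix <- pmin(pmax(seq_len(nx) + offs$dx[k], 1), nx)
    st[, , k] <- h[iy, ix]
  }
  apply(st, c(1, 2), function(v) stats::median(v, na.rm = TRUE))
}

# Vectorized ridge localization of one interface per axial profile.
#
# P: npix x nz matrix of contrast profiles as a function of focus z
# (strictly increasing, uniform spacing). The observed profile of an
# interface at height h is A * u(h - z) with u the unit iPSF, so the fringes
# oscillate with lobe spacing pi / k_z -- less than 3 z-steps at the default
# sampling. A bare arg-max over |C| therefore suffers lobe ambiguity; this
# routine first demodulates the rectified profile (Gaussian smoothing over
# one lobe spacing) into a lobe-free envelope for a coarse estimate, then
# refines on the contrast lobe nearest the coarse estimate and resolves
# which model lobe it is by matching against the coarse estimate. All
# offsets (envelope peak, lobe positions) are self-calibrated on the model
# evaluated through the identical pipeline, so Gouy-phase and truncation
# biases cancel.
# When `shape = c(ny, nx)` is given (full-frame reconstruction), the coarse
# envelope estimate is median-filtered laterally before lobe selection:
# interface height varies smoothly across neighbouring pixels, which
# suppresses fringe-order misassignment under shot noise.
.ridge_locate <- function(P, z, ipsf, shape = NULL) {
  npix <- nrow(P); nz <- ncol(P)
  dz <- z[2] - z[1]
  lobe_nm <- pi / ipsf$axial_wavevector
  sig_s <- max(lobe_nm / dz, 0.75)
  S <- .z_smoother(nz, sig_s)
  E <- abs(P) %*% S
  ie <- max.col(E, ties.method = "first")
  il <- pmax(ie - 1, 1); ir <- pmin(ie + 1, nz)
  pix <- seq_len(npix)
  de <- .parabolic_delta(E[cbind(pix, il)], E[cbind(pix, ie)],
                         E[cbind(pix, ir)])
  de[ie == 1 | ie == nz] <- 0
  zf_env <- z[ie] + de * dz
  # self-calibration of the envelope peak offset on the model
  gg <- seq(-ipsf$truncation_halfwidth - dz, ipsf$truncation_halfwidth + dz,
            by = dz)
  pm <- abs(axial_ipsf(-gg, ipsf))
  Sm <- .z_smoother(length(gg), sig_s)
  Em <- as.numeric(pm %*% Sm)
  im <- which.max(Em)
  dm <- .parabolic_delta(Em[im - 1], Em[im], Em[im + 1])
  env_offset <- -(gg[im] + dm * dz)
  z0_coarse <- zf_env + env_offset
  if (!is.null(shape) && all(shape > 4))
    z0_coarse <- as.numeric(.median_filter(matrix(z0_coarse, shape[1],
                                                  shape[2]), rad = 2))
  # robust noise floor from the signal-poor (low-envelope) planes
  Emax <- E[cbind(pix, ie)]
  nf <- vapply(pix, function(p) {
    low <- which(E[p, ] <= 0.25 * Emax[p])
    if (length(low) < 5) low <- order(E[p, ])[seq_len(min(5, nz))]
    stats::mad(P[p, low])
  }, numeric(1))
  # nearest observed contrast lobe
  A <- abs(P)
  L <- matrix(FALSE, npix, nz)
  L[, 2:(nz - 1)] <- A[, 2:(nz - 1), drop = FALSE] >=
    A[, 1:(nz - 2), drop = FALSE] &
    A[, 2:(nz - 1), drop = FALSE] >= A[, 3:nz, drop = FALSE]
  D <- abs(outer(rep(1, npix), z) - zf_env)
  D[!L] <- Inf
  has_lobe <- is.finite(apply(D, 1, min))
  je <- max.col(-D, ties.method = "first")
  peak <- P[cbind(pix, je)]
  sgn <- sign(peak); sgn[sgn == 0] <- 1
  dl <- .parabolic_delta(sgn * P[cbind(pix, pmax(je - 1, 1))], sgn * peak,
                         sgn * P[cbind(pix, pmin(je + 1, nz))])
  dl[je == 1 | je == nz] <- 0
  zf_ext <- z[je] + dl * dz
  # which model lobe was caught: candidate z0 = zf_ext + lobe offset
  lobes <- .ipsf_lobe_offsets(ipsf)
  cand <- outer(zf_ext, lobes, `+`)
  pickm <- max.col(-abs(cand - z0_coarse), ties.method = "first")
  z0 <- cand[cbind(pix, pickm)]
  z0[!has_lobe] <- z0_coarse[!has_lobe]
  list(z0 = z0, amplitude = peak, peak_abs = abs(peak), noise = nf)
}

#' Locate an interface along one axial contrast profile
#'
#' Two methods mirror the two reconstruction routes. `"ridge"` locates the
#' strongest contrast extremum: the rectified profile is first demodulated
#' into its lobe-free envelope (Gaussian smoothing over one fringe spacing)
#' for a coarse, unambiguous position, then the estimate is refined by
#' 3-point parabolic interpolation on the contrast lobe nearest the coarse
#' position and mapped to the interface height via the model's known lobe
#' offsets. `"fit"` runs nonlinear least squares of the truncated
#' oscillatory iPSF model over (z0, amplitude, phase offset), initialized
#' from the ridge estimate.
#'
#' A profile whose extremum does not rise above `3 * noise_floor` is marked
#' invalid rather than raising an error, as is a non-convergent fit.
#'
#' @param z_positions Focus positions in nm, strictly increasing, uniformly
#'   spaced.
#' @param contrast Contrast values, same length (>= 5 samples).
#' @param ipsf An [ipsf_model()].
#' @param method `"ridge"` or `"fit"`.
#' @param noise_floor Robust noise estimate of the profile; `NULL` estimates
#'   it as the median absolute deviation of the profile (conservative when
#'   signal fills the axial window).
#' @param search_window Optional `c(lo, hi)` nm restricting the search (used
#'   e.g. to separate two interfaces in one profile).
#' @return A list with `z0` (interface height, nm), `amplitude` (signed),
#'   `quality` (extremum prominence in noise units, or fit R^2), `valid`,
#'   `method`.
#' @export
locate_interface <- function(z_positions, contrast, ipsf,
                             method = c("ridge", "fit"),
                             noise_floor = NULL, search_window = NULL) {
  method <- match.arg(method)
  stopifnot(length(z_positions) == length(contrast), length(contrast) >= 5)
  if (is.unsorted(z_positions, strictly = TRUE))
    stop("z_positions must be strictly increasing")
  keep <- if (is.null(search_window)) rep(TRUE, length(z_positions))
          else z_positions >= search_window[1] & z_positions <= search_window[2]
  z <- z_positions[keep]; cc <- contrast[keep]
  if (length(z) < 5)
    return(list(z0 = NA_real_, amplitude = NA_real_, quality = 0,
                valid = FALSE, method = method))
  rl <- .ridge_locate(matrix(cc, 1), z, ipsf)
  if (is.null(noise_floor)) noise_floor <- rl$noise
  quality <- if (noise_floor > 0) rl$peak_abs / noise_floor else Inf
  if (quality < 3)
    return(list(z0 = NA_real_, amplitude = NA_real_, quality = quality,
                valid = FALSE, method = method))
  if (method == "ridge")
    return(list(z0 = rl$z0, amplitude = rl$amplitude, quality = quality,
                valid = TRUE, method = method))
  # nonlinear least squares of the truncated oscillatory model
  base <- ipsf
  resid_fn <- function(par) {
    m <- base
    m$amplitude <- par[2]; m$phase_offset <- par[3]
    axial_ipsf(par[1] - z, m) - cc
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(rl$z0, rl$amplitude, base$phase_offset),
    lower = c(min(z) - base$truncation_halfwidth, -Inf, -pi),
    upper = c(max(z) + base$truncation_halfwidth, Inf, pi),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) {
    message("iPSF fit did not converge; pixel marked invalid")
    return(list(z0 = NA_real_, amplitude = NA_real_, quality = 0,
                valid = FALSE, method = method))
  }
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((cc - mean(cc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(z0 = fit$par[1], amplitude = fit$par[2], quality = r2, valid = TRUE,
       method = method, phase_offset = fit$par[3])
}

#' Reconstruct an interface height map from a contrast z-stack
#'
#' Applies [locate_interface()] at every pixel of a background-corrected
#' contrast z-stack. The `"ridge"` method is fully vectorized (the default
#' for full frames); `"fit"` loops over pixels and is intended for small
#' regions or line cuts. Heights at invalid pixels (extremum below the noise
#' threshold) are `NA` and masked in `validity`.
#'
#' @param cstack A `contrast_map` over a z-stack, an [iscat_stack()] of
#'   contrast, or a plain `[y, x, z]` array.
#' @param focus_nm Focus position per plane (taken from stack metadata when
#'   available); must be uniformly spaced.
#' @param ipsf An [ipsf_model()].
#' @param method `"ridge"` or `"fit"`.
#' @param noise_floor Robust per-profile noise level; `NULL` to estimate
#'   per pixel as the median absolute deviation of the profile.
#' @param search_window Optional `c(lo, hi)` nm.
#' @param median_filter Apply a radius-1 lateral median filter to the
#'   heights (default `TRUE`).
#' @return An object of class `height_map`: `heights` (nm, `NA` when
#'   invalid), `amplitude`, `validity`, `method`, `focus_nm`.
#' @export
reconstruct_surface <- function(cstack, focus_nm = NULL, ipsf = ipsf_model(),
                                method = c("ridge", "fit"),
                                noise_floor = NULL, search_window = NULL,
                                median_filter = TRUE) {
  method <- match.arg(method)
  if (inherits(cstack, "contrast_map") && !is.null(cstack$stack) &&
      is.null(focus_nm)) focus_nm <- cstack$stack$focus_nm
  if (inherits(cstack, "iscat_stack") && is.null(focus_nm))
    focus_nm <- cstack$focus_nm
  v <- .values(cstack)
  if (length(dim(v)) != 3) stop("a [y, x, z] contrast stack is required")
  if (dim(v)[3] < 2 || prod(dim(v)) == 0) stop("empty or degenerate stack")
  if (is.null(focus_nm) || length(focus_nm) != dim(v)[3])
    stop("focus_nm must give one focus position per plane")
  ny <- dim(v)[1]; nx <- dim(v)[2]; nz <- dim(v)[3]
  keep <- if (is.null(search_window)) rep(TRUE, nz)
          else focus_nm >= search_window[1] & focus_nm <= search_window[2]
  z <- focus_nm[keep]
  m <- matrix(v, ny * nx, nz)[, keep, drop = FALSE]
  nzk <- ncol(m)
  if (nzk < 5) stop("fewer than 5 planes in the search window")
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-6 * abs(dz[1]))
    stop("focus positions must be uniformly spaced")
  if (method == "fit") {
    res <- apply(matrix(seq_len(ny * nx)), 1, function(p) {
      fit <- locate_interface(z, m[p, ], ipsf, method = "fit",
                              noise_floor = noise_floor)
      c(fit$z0, fit$amplitude, fit$quality, as.numeric(fit$valid))
    })
    heights <- matrix(res[1, ], ny, nx)
    amplitude <- matrix(res[2, ], ny, nx)
    valid <- matrix(res[4, ] > 0, ny, nx)
  } else {
    rl <- .ridge_locate(m, z, ipsf, shape = c(ny, nx))
    if (is.null(noise_floor)) {
      # per-profile tail estimate, capped by the lateral high-frequency
      # noise of the planes (tighter when signal fills the axial window)
      spat <- stats::median(vapply(seq_len(nzk), function(k) {
        pl <- matrix(m[, k], ny, nx)
        stats::mad(pl[, -1] - pl[, -nx]) / sqrt(2)
      }, numeric(1)))
      nf <- pmin(rl$noise, spat)
    } else nf <- rep(noise_floor, ny * nx)
    quality <- ifelse(nf > 0, rl$peak_abs / nf, Inf)
    valid_v <- quality >= 3
    heights <- matrix(ifelse(valid_v, rl$z0, NA_real_), ny, nx)
    amplitude <- matrix(rl$amplitude, ny, nx)
    valid <- matrix(valid_v, ny, nx)
  }
  if (median_filter && any(valid)) heights <- .median_filter(heights, 1)
  structure(
    list(heights = heights, amplitude = amplitude, validity = valid,
         method = method, focus_nm = z),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("Height map (%s): %d x %d px, %.1f%% valid\n",
              x$method, nrow(x$heights), ncol(x$heights),
              100 * mean(x$validity)))
  if (any(x$validity)) {
    h <- x$heights[x$validity]
    cat(sprintf("  heights: %.0f .. %.0f nm (median %.0f)\n",
                min(h, na.rm = TRUE), max(h, na.rm = TRUE),
                stats::median(h, na.rm = TRUE)))
  }
  invisible(x)
}

#' 10-90% edge sharpness of a line profile
#'
#' Measures the lateral sharpness of a plateau-to-plateau transition as the
#' distance between the points where the profile crosses 10% and 90% of the
#' plateau difference, with linear interpolation between samples. Plateau
#' levels are taken as medians of the first and last 10% of samples.
#'
#' @param position Sample positions in nm (strictly increasing).
#' @param value Intensity or contrast values.
#' @return Edge width in nm. For a step blurred with a Gaussian of width
#'   sigma this is `2 * 1.2816 * sigma = 2.563 sigma`; for a linear ramp of
#'   length L it is `0.8 L`.
#' @export
edge_sharpness_1090 <- function(position, value) {
  stopifnot(length(position) == length(value), length(value) >= 5)
  n <- length(value)
  k <- max(2, floor(n * 0.1))
  lo <- stats::median(value[seq_len(k)])
  hi <- stats::median(value[(n - k + 1):n])
  if (abs(hi - lo) <= 1e-12 * max(abs(c(hi, lo, 1))))
    stop("no monotone transition found: plateaus are equal")
  y <- (value - lo) / (hi - lo)
  cross_up <- function(th) {
    i <- which(y[-n] < th & y[-1] >= th)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    position[i] + (th - y[i]) / (y[i + 1] - y[i]) * (position[i + 1] - position[i])
  }
  x10 <- cross_up(0.1)
  x90 <- cross_up(0.9)
  if (is.na(x10) || is.na(x90) || x90 <= x10)
    stop("no monotone transition found between the plateaus")
  x90 - x10
}
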