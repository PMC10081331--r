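# Tubule segmentation, RVT particle localization, trajectory linking and
# contrast-calibrated axial tracking.

#' Hessian ridge segmentation of tubular structures
#'
#' Smooths the contrast image at a Gaussian scale comparable to the tubule
#' radius, computes the Hessian, and keeps pixels whose principal
#' (largest-magnitude) eigenvalue indicates a ridge of the requested
#' polarity with scale-normalized magnitude above `threshold`. Connected
#' components smaller than `min_size_px` are removed.
#'
#' @param image Contrast matrix.
#' @param scale_nm Gaussian scale in nm (comparable to the tubule radius).
#' @param threshold Threshold on the scale-normalized principal eigenvalue
#'   (`|lambda| * sigma_px^2`, contrast units).
#' @param pixel_size nm per pixel.
#' @param polarity `"dark"` (negative-contrast tubules, the usual case for
#'   background-corrected confocal iSCAT of ER), `"bright"`, or `"both"`.
#' @param min_size_px Minimum connected-component size kept.
#' @return Logical matrix mask.
#' @export
hessian_ridge_segment <- function(image, scale_nm, threshold,
                                  pixel_size = 30,
                                  polarity = c("dark", "bright", "both"),
                                  min_size_px = 5) {
  polarity <- match.arg(polarity)
  sig <- scale_nm / pixel_size
  sm <- .gblur_mirror(image, sig)
  ny <- nrow(sm); nx <- ncol(sm)
  shift <- function(m, dy, dx) {
    iy <- pmin(pmax(seq_len(ny) + dy, 1), ny)
    ix <- pmin(pmax(seq_len(nx) + dx, 1), nx)
    m[iy, ix, drop = FALSE]
  }
  ixx <- shift(sm, 0, 1) - 2 * sm + shift(sm, 0, -1)
  iyy <- shift(sm, 1, 0) - 2 * sm + shift(sm, -1, 0)
  ixy <- (shift(sm, 1, 1) - shift(sm, 1, -1) -
            shift(sm, -1, 1) + shift(sm, -1, -1)) / 4
  tr <- ixx + iyy
  disc <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  principal <- ifelse(abs(l1) >= abs(l2), l1, l2)
  resp <- principal * sig^2
  mask <- switch(polarity,
    dark = resp > threshold,    # dark line: positive curvature across it
    bright = resp < -threshold,
    both = abs(resp) > threshold
  )
  if (any(mask) && min_size_px > 1) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size_px)
    mask <- matrix(lab %in% keep, ny, nx)
  }
  mask
}

#' Radial variance transform (RVT)
#'
#' Per-pixel score of radial symmetry: for every pixel, the mean intensity
#' over each concentric annulus of radius `r_min .. r_max` (width 1 px) is
#' computed, and the score is the variance of those annular means across
#' radius. Centers of ringed, radially symmetric patterns such as iPSFs
#' score highly regardless of contrast sign; the score is invariant under
#' intensity offsets and scales with the square of an intensity gain.
#'
#' @param image Intensity or contrast matrix.
#' @param r_min,r_max Annulus radius range in px
#'   (`0 <= r_min < r_max <=` half the image size).
#' @return Score matrix (same size; non-negative).
#' @export
radial_variance_transform <- function(image, r_min = 0, r_max = 8) {
  ny <- nrow(image); nx <- ncol(image)
  if (!(r_min >= 0 && r_min < r_max)) stop("need 0 <= r_min < r_max")
  if (2 * r_max + 1 > min(ny, nx))
    stop("r_max too large for the image")
  radii <- r_min:r_max
  sz <- 2 * r_max + 1
  off <- seq_len(sz) - (r_max + 1)
  d <- sqrt(outer(off^2, rep(1, sz)) + outer(rep(1, sz), off^2))
  sum_m <- matrix(0, ny, nx)
  sum_m2 <- matrix(0, ny, nx)
  n_ann <- 0
  for (k in radii) {
    ker <- (d >= k - 0.5 & d < k + 0.5) * 1
    npx <- sum(ker)
    if (npx == 0) next
    m_k <- EBImage::filter2(image, ker / npx, boundary = "replicate")
    sum_m <- sum_m + m_k
    sum_m2 <- sum_m2 + m_k^2
    n_ann <- n_ann + 1
  }
  if (n_ann < 2) stop("fewer than two non-empty annuli in range")
  v <- sum_m2 / n_ann - (sum_m / n_ann)^2
  pmax(v, 0)
}

# Bilinear interpolation of matrix m at (y, x) in pixel units.
.bilinear <- function(m, y, x) {
  ny <- nrow(m); nx <- ncol(m)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Localize particles from an RVT score map
#'
#' Finds local maxima of the score map above `threshold`, applies
#' non-maximum suppression at `min_separation_px` (strongest detection
#' wins), and refines each position to sub-pixel precision by separable
#' 3-point quadratic interpolation. The signed contrast is read from the
#' contrast image at the refined position (bilinear).
#'
#' @param score RVT score matrix.
#' @param contrast Contrast matrix of the same size.
#' @param threshold Minimum score (> 0).
#' @param min_separation_px Minimum distance between detections, px; a
#'   sensible default is one PSF FWHM.
#' @return `data.frame(x_px, y_px, score, contrast)`; possibly empty.
#' @export
localize_particles <- function(score, contrast, threshold,
                               min_separation_px = 5) {
  stopifnot(threshold > 0, identical(dim(score), dim(contrast)))
  ny <- nrow(score); nx <- ncol(score)
  shift <- function(m, dy, dx) {
    iy <- pmin(pmax(seq_len(ny) + dy, 1), ny)
    ix <- pmin(pmax(seq_len(nx) + dx, 1), nx)
    m[iy, ix, drop = FALSE]
  }
  is_max <- score > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (score >= shift(score, dy, dx))
  }
  # exclude the border where quadratic refinement is undefined
  is_max[c(1, ny), ] <- FALSE
  is_max[, c(1, nx)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0), contrast = numeric(0)))
  s <- score[idx]
  ord <- order(s, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; s <- s[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j][d2 < min_separation_px^2] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]; s <- s[keep]
  dy <- .parabolic_delta(score[cbind(idx[, 1] - 1, idx[, 2])], s,
                         score[cbind(idx[, 1] + 1, idx[, 2])])
  dx <- .parabolic_delta(score[cbind(idx[, 1], idx[, 2] - 1)], s,
                         score[cbind(idx[, 1], idx[, 2] + 1)])
  dy <- pmin(pmax(dy, -0.5), 0.5); dx <- pmin(pmax(dx, -0.5), 0.5)
  y <- idx[, 1] + dy; x <- idx[, 2] + dx
  data.frame(x_px = x, y_px = y, score = s,
             contrast = .bilinear(contrast, y, x))
}

#' Detect particles in every frame of a time series
#'
#' Runs [radial_variance_transform()] and [localize_particles()] on each
#' frame of a contrast time series.
#'
#' @param cstack `contrast_map`, [iscat_stack()] or `[y, x, t]` array of
#'   contrast.
#' @param r_min,r_max,threshold,min_separation_px Passed to the per-frame
#'   detectors.
#' @return `data.frame(frame, x_px, y_px, score, contrast)`.
#' @export
detect_stack <- function(cstack, r_min = 0, r_max = 8, threshold,
                         min_separation_px = 5) {
  v <- .values(cstack)
  if (length(dim(v)) != 3) stop("a [y, x, t] contrast stack is required")
  res <- lapply(seq_len(dim(v)[3]), function(k) {
    sc <- radial_variance_transform(v[, , k], r_min, r_max)
    det <- localize_particles(sc, v[, , k], threshold, min_separation_px)
    if (nrow(det)) cbind(frame = k, det) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), score = numeric(0),
                      contrast = numeric(0))
  out
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking with per-frame optimal assignment on the
#' candidate set: for each frame, candidate track-detection pairs within
#' `max_disp` (scaled by the bridged gap length) are assigned in order of
#' increasing displacement; unmatched detections seed new tracks and tracks
#' missing for more than `memory_frames` frames are closed. Trajectories
#' shorter than `min_length` localizations are discarded. Each detection is
#' assigned to at most one trajectory.
#'
#' @param detections `data.frame` with columns `frame`, `x`, `y` (any
#'   consistent length unit; `x_px`/`y_px` are accepted) and optionally
#'   `contrast`, `score`.
#' @param max_disp Maximum frame-to-frame displacement, same unit as x/y.
#' @param memory_frames Frames a vanished track may be bridged over.
#' @param min_length Minimum localizations per trajectory (default 25).
#' @return A `data.frame` of the retained detections with a `trajectory`
#'   id column, of class `trajectory_set`.
#' @export
link_trajectories <- function(detections, max_disp, memory_frames = 0,
                              min_length = 25) {
  stopifnot(max_disp > 0)
  d <- as.data.frame(detections)
  if (!"x" %in% names(d) && "x_px" %in% names(d)) d$x <- d$x_px
  if (!"y" %in% names(d) && "y_px" %in% names(d)) d$y <- d$y_px
  stopifnot(all(c("frame", "x", "y") %in% names(d)))
  d <- d[order(d$frame), , drop = FALSE]
  d$trajectory <- NA_integer_
  frames <- sort(unique(d$frame))
  # active tracks: id, last x, y, last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    frame = integer(0))
  next_id <- 1L
  for (f in frames) {
    rows <- which(d$frame == f)
    act <- act[f - act$frame <= memory_frames + 1, , drop = FALSE]
    if (nrow(act) && length(rows)) {
      gap <- f - act$frame
      dist <- outer(act$x, d$x[rows], `-`)^2 + outer(act$y, d$y[rows], `-`)^2
      lim <- (max_disp * gap)^2
      dist[dist > matrix(lim, nrow(act), length(rows))] <- Inf
      while (any(is.finite(dist))) {
        k <- arrayInd(which.min(dist), dim(dist))
        ti <- k[1]; di <- k[2]
        d$trajectory[rows[di]] <- act$id[ti]
        act$x[ti] <- d$x[rows[di]]; act$y[ti] <- d$y[rows[di]]
        act$frame[ti] <- f
        dist[ti, ] <- Inf; dist[, di] <- Inf
      }
    }
    new <- rows[is.na(d$trajectory[rows])]
    for (ri in new) {
      d$trajectory[ri] <- next_id
      act <- rbind(act, data.frame(id = next_id, x = d$x[ri], y = d$y[ri],
                                   frame = f))
      next_id <- next_id + 1L
    }
  }
  len <- table(d$trajectory)
  keep_ids <- as.integer(names(len)[len >= min_length])
  d <- d[d$trajectory %in% keep_ids, , drop = FALSE]
  d$trajectory <- match(d$trajectory, sort(unique(d$trajectory)))
  rownames(d) <- NULL
  structure(d, class = c("trajectory_set", "data.frame"),
            min_length = min_length, max_disp = max_disp)
}

#' @export
print.trajectory_set <- function(x, ...) {
  if ("trajectory" %in% names(x))
    cat(sprintf("Trajectory set: %d trajectories, %d localizations\n",
                length(unique(x$trajectory)), nrow(x)))
  NextMethod()
}

#' Contrast-to-axial-displacement calibration
#'
#' @param c_max Maximum absolute contrast of the tracked species (e.g. 0.20
#'   for clathrin-coated pits).
#' @param full_inversion_nm Axial travel per full contrast inversion (pi of
#'   interferometric phase); default [full_inversion_distance()] at the
#'   445 nm default wavelength.
#' @param direction_prior `"free"` or `"inward_only"` (cumulative axial
#'   displacement forbidden from reversing sign, as for internalizing
#'   endocytic pits).
#' @return An object of class `iscat_calibration`.
#' @export
iscat_calibration <- function(c_max = 0.20,
                              full_inversion_nm = full_inversion_distance(),
                              direction_prior = c("free", "inward_only")) {
  stopifnot(c_max > 0, full_inversion_nm > 0)
  direction_prior <- match.arg(direction_prior)
  structure(list(c_max = c_max, full_inversion_nm = full_inversion_nm,
                 direction_prior = direction_prior),
            class = "iscat_calibration")
}

#' Convert a contrast time series to relative axial displacement
#'
#' Inverts `C(t) = c_max * cos(pi * z(t) / L + phi0)` (L =
#' `full_inversion_nm`) on a continuous phase branch: the starting phase is
#' the branch nearest focus (`phi0 = acos(C_1/c_max)` in `[0, pi]`), and
#' each subsequent phase is the candidate `+/- acos(C_t/c_max) + 2 pi k`
#' with the smallest phase increment, assuming per-frame `|dz| <
#' full_inversion_nm / 2` (no wrap). With `direction_prior = "inward_only"`
#' the cumulative phase is constrained to be non-decreasing.
#'
#' Contrast values exceeding `c_max` by up to 10% are clipped with a
#' warning (noise at the calibration limit); larger excursions raise a
#' calibration-violation error.
#'
#' @param contrast Contrast time series.
#' @param cal An [iscat_calibration()].
#' @return Numeric vector of z displacements (nm) relative to the first
#'   frame, with attributes `phi0` (starting phase, rad) and `phase`.
#' @export
contrast_to_dz <- function(contrast, cal = iscat_calibration()) {
  stopifnot(inherits(cal, "iscat_calibration"), length(contrast) >= 1)
  x <- contrast / cal$c_max
  over <- abs(x) - 1
  if (any(over > 0.1))
    stop("calibration violation: |contrast| exceeds c_max by more than 10%")
  if (any(over > 0)) {
    warning("contrast clipped to +/- c_max (", sum(over > 0), " frame(s))")
    x <- pmin(pmax(x, -1), 1)
  }
  theta <- acos(x)          # in [0, pi]
  n <- length(x)
  phase <- numeric(n)
  phase[1] <- theta[1]      # branch nearest focus
  inward <- cal$direction_prior == "inward_only"
  for (t in seq_len(n)[-1]) {
    k0 <- round((phase[t - 1]) / (2 * pi))
    cand <- c(theta[t] + 2 * pi * (k0 + (-1:1)),
              -theta[t] + 2 * pi * (k0 + (-1:1)))
    if (inward) cand <- cand[cand >= phase[t - 1] - 1e-9]
    phase[t] <- cand[which.min(abs(cand - phase[t - 1]))]
  }
  z <- (phase - phase[1]) * cal$full_inversion_nm / pi
  attr(z, "phi0") <- phase[1]
  attr(z, "phase") <- phase
  z
}

#' Per-trajectory summary statistics
#'
#' Root-mean-square displacement about the mean position (over the
#' available spatial dimensions), total contrast swing `|Cmax - Cmin|`, and
#' mean speed (net displacement over duration).
#'
#' @param traj `data.frame` for one trajectory with columns `x`, `y`
#'   (or `x_px`/`y_px`), optionally `z`, `contrast`, and either `t_s` or
#'   `frame` plus `frame_interval`.
#' @param frame_interval Frame interval in s (used when `t_s` is absent).
#' @return A one-row `data.frame(n, rmsd, contrast_swing, mean_speed)`.
#' @export
trajectory_stats <- function(traj, frame_interval = 1) {
  d <- as.data.frame(traj)
  if (!"x" %in% names(d)) d$x <- d$x_px
  if (!"y" %in% names(d)) d$y <- d$y_px
  if (!"t_s" %in% names(d)) d$t_s <- (d$frame - d$frame[1]) * frame_interval
  cols <- cbind(d$x, d$y, if ("z" %in% names(d)) d$z)
  ctr <- colMeans(cols)
  rmsd <- sqrt(mean(rowSums(sweep(cols, 2, ctr)^2)))
  swing <- if ("contrast" %in% names(d) && nrow(d) > 0)
    diff(range(d$contrast)) else NA_real_
  dur <- diff(range(d$t_s))
  net <- sqrt(sum((cols[nrow(cols), ] - cols[1, ])^2))
  data.frame(n = nrow(d), rmsd = rmsd, contrast_swing = swing,
             mean_speed = if (dur > 0) net / dur else 0)
}

#' Ensemble mean squared displacement at a fixed lag
#'
#' @param traj_set A [link_trajectories()] result (or any data.frame with
#'   `trajectory`, `frame`, `x`, `y` columns).
#' @param lag Lag in frames.
#' @return Mean squared displacement (unit of x/y squared) across all
#'   trajectory pairs at that lag.
#' @export
ensemble_msd <- function(traj_set, lag = 1) {
  d <- as.data.frame(traj_set)
  if (!"x" %in% names(d)) d$x <- d$x_px
  if (!"y" %in% names(d)) d$y <- d$y_px
  sq <- unlist(lapply(split(d, d$trajectory), function(tr) {
    tr <- tr[order(tr$frame), ]
    i <- match(tr$frame + lag, tr$frame)
    ok <- !is.na(i)
    (tr$x[i[ok]] - tr$x[ok])^2 + (tr$y[i[ok]] - tr$y[ok])^2
  }))
  mean(sq)
}

#' Fraction of detections colocalizing with a reference mask
#'
#' The mask is dilated by `tolerance_nm` (via a distance transform) and the
#' fraction of detections falling inside is returned.
#'
#' @param detections `data.frame` with `x_px`, `y_px` (or `x`, `y` in px).
#' @param mask Logical or 0/1 matrix in the same pixel frame.
#' @param tolerance_nm Dilation tolerance in nm.
#' @param pixel_size nm per pixel.
#' @return Fraction in \[0, 1\].
#' @export
colocalization_fraction <- function(detections, mask, tolerance_nm = 0,
                                    pixel_size = 30) {
  d <- as.data.frame(detections)
  if (!"x_px" %in% names(d)) d$x_px <- d$x
  if (!"y_px" %in% names(d)) d$y_px <- d$y
  if (nrow(d) == 0)
    stop("undefined fraction: no detections supplied")
  # distance of every pixel to the nearest mask pixel
  dist_px <- EBImage::distmap(1 - (mask * 1))
  tol_px <- tolerance_nm / pixel_size
  iy <- pmin(pmax(round(d$y_px), 1), nrow(mask))
  ix <- pmin(pmax(round(d$x_px), 1), ncol(mask))
  mean(dist_px[cbind(iy, ix)] <= tol_px)
}
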