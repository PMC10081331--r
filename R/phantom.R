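#' Phantom scenes for the forward iSCAT simulator
#'
#' A `phantom` collects the scene content rendered by
#' [render_acquisition()]: reflective interfaces (height fields), tubule
#' networks (centerline polylines with radii), and point scatterers with a
#' motion model. Generators below build the scene types the analyses are
#' validated on; all are deterministic for a fixed seed.
#'
#' @param interfaces List of interfaces, each
#'   `list(heights = <ny x nx matrix, nm>, amplitude = <peak contrast>)`.
#' @param tubules List of tubules, each `list(path = <n x 2 matrix of (x, y)
#'   nm>, radius = <nm>, amplitude = <peak contrast>, z = <height nm>)`.
#' @param particles `NULL` or a list with elements `times` (s), `positions`
#'   (`nt x 3 x n` array of (x, y, z) nm), `s_mag` (field-amplitude ratio per
#'   particle), `phase` (intrinsic scattering phase, rad).
#' @param extent_px `c(ny, nx)` lateral grid size.
#' @param pixel_size nm per pixel.
#' @return An object of class `phantom`.
#' @export
phantom <- function(interfaces = list(), tubules = list(), particles = NULL,
                    extent_px = c(128, 128), pixel_size = 30) {
  for (f in interfaces) {
    stopifnot(is.matrix(f$heights), all(is.finite(f$heights)))
    if (!all(dim(f$heights) == extent_px))
      stop("interface height field must match extent_px")
  }
  for (tb in tubules) stopifnot(tb$radius > 0)
  if (!is.null(particles)) {
    stopifnot(all(particles$s_mag >= 0))
    if (any(particles$positions[, 3, ] < 0))
      stop("particle z positions must be >= 0 (above the cover glass)")
  }
  structure(
    list(interfaces = interfaces, tubules = tubules, particles = particles,
         extent_px = extent_px, pixel_size = pixel_size),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  np <- if (is.null(x$particles)) 0 else dim(x$particles$positions)[3]
  cat(sprintf(
    "Phantom: %d x %d px (%g nm/px), %d interface(s), %d tubule(s), %d particle(s)\n",
    x$extent_px[1], x$extent_px[2], x$pixel_size,
    length(x$interfaces), length(x$tubules), np))
  invisible(x)
}

# Band-limited Gaussian random field with correlation length ell (nm),
# scaled to exact RMS about its mean. Periodic via FFT.
.gaussian_random_field <- function(ny, nx, pixel_size, ell, rms) {
  wn <- matrix(stats::rnorm(ny * nx), ny, nx)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * pixel_size)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * pixel_size)
  k2 <- outer((2 * pi * fy)^2, rep(1, nx)) + outer(rep(1, ny), (2 * pi * fx)^2)
  filt <- exp(-k2 * ell^2 / 8)   # spatial correlation ~ exp(-2 r^2 / ell^2)
  f <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / (ny * nx)
  f <- f - mean(f)
  if (stats::sd(f) > 0) f <- f * rms / sqrt(mean(f^2))
  f
}

#' Rippled-membrane phantom
#'
#' A single reflective interface: a smooth global bow plus band-limited
#' Gaussian random ripples of a requested RMS amplitude and lateral
#' correlation length, emulating the nanoscale corrugation of a nuclear
#' envelope (axial modulations of hundreds of nm over micrometer lateral
#' scales).
#'
#' @param extent_px `c(ny, nx)` grid size.
#' @param pixel_size nm per pixel.
#' @param ripple_rms RMS ripple amplitude in nm (0 gives an exactly planar
#'   surface).
#' @param correlation_length Lateral correlation length of the ripples in nm;
#'   must be at least `2 * pixel_size` (sampling limit).
#' @param global_bow Peak height in nm of a smooth paraboloidal bow (0 =
#'   flat).
#' @param base_height Mean interface height above the cover glass, nm.
#' @param amplitude Peak iSCAT contrast of the interface.
#' @param seed Integer seed; fixed seed reproduces the field exactly.
#' @return A [phantom()] with one interface.
#' @export
make_membrane_phantom <- function(extent_px = c(128, 128), pixel_size = 30,
                                  ripple_rms = 200, correlation_length = 1000,
                                  global_bow = 0, base_height = 1000,
                                  amplitude = 0.1, seed = 1) {
  stopifnot(ripple_rms >= 0)
  if (correlation_length < 2 * pixel_size)
    stop("aliasing: correlation_length must be >= 2 * pixel_size")
  ny <- extent_px[1]; nx <- extent_px[2]
  h <- matrix(base_height, ny, nx)
  if (global_bow != 0) {
    yy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
    xx <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
    rho2 <- outer(yy^2, rep(1, nx)) + outer(rep(1, ny), xx^2)
    h <- h + global_bow * (1 - rho2 / max(rho2))
  }
  if (ripple_rms > 0) {
    set.seed(seed)
    h <- h + .gaussian_random_field(ny, nx, pixel_size, correlation_length,
                                    ripple_rms)
  }
  phantom(interfaces = list(list(heights = h, amplitude = amplitude)),
          extent_px = extent_px, pixel_size = pixel_size)
}

#' Staircase phantom
#'
#' A reflective interface with discrete height steps along x, mirroring the
#' nanofabricated staircase used to validate multi-plane height extraction.
#'
#' @param extent_px `c(ny, nx)` grid size.
#' @param pixel_size nm per pixel.
#' @param step_height Height increment per step, nm.
#' @param n_steps Number of steps across the field.
#' @param base_height Height of the lowest step, nm.
#' @param amplitude Peak iSCAT contrast.
#' @return A [phantom()] with one interface.
#' @export
make_staircase_phantom <- function(extent_px = c(64, 128), pixel_size = 30,
                                   step_height = 50, n_steps = 4,
                                   base_height = 600, amplitude = 0.1) {
  ny <- extent_px[1]; nx <- extent_px[2]
  step_of_col <- pmin(floor((seq_len(nx) - 1) / (nx / n_steps)), n_steps - 1)
  h <- matrix(base_height + step_height * rep(step_of_col, each = ny), ny, nx)
  phantom(interfaces = list(list(heights = h, amplitude = amplitude)),
          extent_px = extent_px, pixel_size = pixel_size)
}

#' Tubule-network phantom
#'
#' Grows a random planar network by branching random walks: active tips
#' advance with angular wiggle and occasionally split in two, so every
#' internal node of the resulting graph is a three-way junction (matching ER
#' network topology); endpoints have degree 1. Edge radii are sampled
#' uniformly from `radius_range` (defaults give 50--100 nm diameters).
#'
#' @param extent_px `c(ny, nx)` grid size.
#' @param pixel_size nm per pixel.
#' @param node_density Target three-way junctions per um^2.
#' @param radius_range Tubule radius range in nm.
#' @param amplitude Peak contrast of the tubules (ER tubules are dark,
#'   ~ -0.12, in background-corrected confocal iSCAT).
#' @param z Height of the tubule plane above the cover glass, nm.
#' @param step_nm Polyline step length, nm.
#' @param seed Integer seed.
#' @return A [phantom()] whose `tubules` are polyline segments; the network
#'   graph (nodes with degrees) is attached as attribute `"network"`.
#' @export
make_tubule_phantom <- function(extent_px = c(128, 128), pixel_size = 30,
                                node_density = 0.3, radius_range = c(25, 50),
                                amplitude = -0.12, z = 200, step_nm = 120,
                                seed = 1) {
  stopifnot(all(radius_range > 0), length(radius_range) == 2)
  ny <- extent_px[1]; nx <- extent_px[2]
  if (ny < 2 || nx < 2) stop("empty domain")
  Lx <- nx * pixel_size; Ly <- ny * pixel_size
  area_um2 <- Lx * Ly / 1e6
  target_junctions <- max(1, round(node_density * area_um2))
  set.seed(seed)
  nodes <- data.frame(x = numeric(0), y = numeric(0), degree = integer(0),
                      internal = logical(0))
  add_node <- function(x, y, degree, internal) {
    nodes[nrow(nodes) + 1, ] <<- list(x, y, degree, internal)
    nrow(nodes)
  }
  edges <- list()
  inside <- function(p) p[1] > 0 && p[1] < Lx && p[2] > 0 && p[2] < Ly
  # seed tip at a random interior point
  start <- c(stats::runif(1, 0.3, 0.7) * Lx, stats::runif(1, 0.3, 0.7) * Ly)
  root <- add_node(start[1], start[2], 1L, FALSE)
  tips <- list(list(pos = start, dir = stats::runif(1, 0, 2 * pi),
                    path = matrix(start, 1), from = root))
  junctions <- 0L
  guard <- 0L
  while (length(tips) > 0 && guard < 20000) {
    guard <- guard + 1L
    tip <- tips[[1]]; tips <- tips[-1]
    finished <- FALSE
    while (!finished) {
      tip$dir <- tip$dir + stats::rnorm(1, 0, 0.25)
      p <- tip$pos + step_nm * c(cos(tip$dir), sin(tip$dir))
      if (!inside(p)) {
        p <- pmin(pmax(p, c(1, 1)), c(Lx - 1, Ly - 1))
        tip$path <- rbind(tip$path, p)
        end <- add_node(p[1], p[2], 1L, FALSE)
        edges[[length(edges) + 1]] <- list(path = tip$path,
                                           from = tip$from, to = end)
        finished <- TRUE
      } else {
        tip$pos <- p
        tip$path <- rbind(tip$path, p)
        if (junctions < target_junctions && stats::runif(1) < 0.12 &&
            nrow(tip$path) > 3) {
          # branch: close the edge at a new 3-way junction, spawn two tips
          j <- add_node(p[1], p[2], 1L, TRUE)
          edges[[length(edges) + 1]] <- list(path = tip$path,
                                             from = tip$from, to = j)
          junctions <- junctions + 1L
          spread <- stats::runif(1, 0.5, 1.1)
          for (ddir in c(-spread, spread)) {
            tips[[length(tips) + 1]] <- list(
              pos = p, dir = tip$dir + ddir, path = matrix(p, 1), from = j)
            nodes$degree[j] <- nodes$degree[j] + 1L
          }
          finished <- TRUE
        } else if (nrow(tip$path) > 60) {
          end <- add_node(p[1], p[2], 1L, FALSE)
          edges[[length(edges) + 1]] <- list(path = tip$path,
                                             from = tip$from, to = end)
          finished <- TRUE
        }
      }
    }
  }
  # the root only ever spawned one edge; treat as endpoint
  radii <- stats::runif(length(edges), radius_range[1], radius_range[2])
  tubules <- lapply(seq_along(edges), function(i)
    list(path = edges[[i]]$path, radius = radii[i], amplitude = amplitude,
         z = z))
  ph <- phantom(tubules = tubules, extent_px = extent_px,
                pixel_size = pixel_size)
  attr(ph, "network") <- list(nodes = nodes, n_edges = length(edges))
  ph
}

#' Diffusing / drifting particle ensemble
#'
#' Point scatterers following Brownian motion with optional constant drift:
#' `x(t+dt) = x(t) + drift*dt + N(0, 2 D dt)` per axis. Positions start
#' uniformly in the lateral field of view at height `z0`; z excursions below
#' the cover glass are reflected.
#'
#' @param n Number of particles (>= 1).
#' @param diffusion Diffusion coefficient D, nm^2/s.
#' @param drift Drift velocity `c(vx, vy, vz)` in nm/s.
#' @param duration Total time, s.
#' @param dt Frame interval, s (> 0).
#' @param extent_px,pixel_size Lateral domain.
#' @param z0 Initial height, nm.
#' @param s_mag Scattered field-amplitude ratio per particle (scalar or
#'   length n).
#' @param lateral_only If `TRUE`, diffusion and drift act only in the image
#'   plane and z stays at `z0` (membrane-confined species); otherwise z
#'   diffuses too and particles can cross the zero-contrast phase of the
#'   interferometric response.
#' @param seed Integer seed.
#' @return A [phantom()] with `particles` filled; ground-truth positions are
#'   in `$particles$positions` (`nt x 3 x n`, nm).
#' @export
make_particle_ensemble <- function(n, diffusion = 1e4, drift = c(0, 0, 0),
                                   duration = 5, dt = 0.05,
                                   extent_px = c(128, 128), pixel_size = 30,
                                   z0 = 0, s_mag = 0.007, lateral_only = FALSE,
                                   seed = 1) {
  stopifnot(n >= 1, diffusion >= 0)
  if (dt <= 0) stop("dt must be positive")
  set.seed(seed)
  nt <- max(2, round(duration / dt) + 1)
  times <- (seq_len(nt) - 1) * dt
  Lx <- extent_px[2] * pixel_size; Ly <- extent_px[1] * pixel_size
  pos <- array(0, dim = c(nt, 3, n))
  sdstep <- sqrt(2 * diffusion * dt)
  for (i in seq_len(n)) {
    p <- matrix(0, nt, 3)
    p[1, ] <- c(stats::runif(1, 0.1, 0.9) * Lx, stats::runif(1, 0.1, 0.9) * Ly, z0)
    steps <- matrix(stats::rnorm((nt - 1) * 3, 0, sdstep), nt - 1, 3)
    steps <- sweep(steps, 2, drift * dt, `+`)
    cs <- apply(steps, 2, cumsum)
    if (is.null(dim(cs))) dim(cs) <- c(1, 3)
    p[-1, ] <- matrix(p[1, ], nt - 1, 3, byrow = TRUE) + cs
    if (lateral_only) p[, 3] <- z0
    p[, 3] <- abs(p[, 3])  # reflect at the cover glass
    pos[, , i] <- p
  }
  s_mag <- rep_len(s_mag, n)
  phantom(particles = list(times = times, positions = pos, s_mag = s_mag,
                           phase = rep(0, n)),
          extent_px = extent_px, pixel_size = pixel_size)
}

#' Acquisition plan
#'
#' Describes how a phantom is imaged: modality, focus position(s), timing and
#' photon budget. A plan with several focus positions and one frame time is a
#' z-stack; one focus position and several frame times is a constant-focus
#' time series.
#'
#' @param mode `"confocal"` or `"widefield"`.
#' @param focus_nm Focus position(s) above the cover glass, nm.
#' @param n_frames Number of time frames.
#' @param frame_interval Frame interval, s.
#' @param photon_budget Expected detected photons per pixel at background
#'   level (> 0); relative shot noise is `1/sqrt(photon_budget)`. Use `Inf`
#'   for noiseless rendering.
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(mode = c("confocal", "widefield"),
                             focus_nm = 0, n_frames = 1,
                             frame_interval = 0.25, photon_budget = 1e4) {
  mode <- match.arg(mode)
  if (photon_budget <= 0) stop("photon_budget must be positive")
  if (length(focus_nm) > 1 && n_frames > 1)
    stop("plan must be a z-stack (many foci, one frame) or a time series (one focus)")
  structure(
    list(mode = mode, focus_nm = focus_nm, n_frames = n_frames,
         frame_interval = frame_interval, photon_budget = photon_budget),
    class = "acquisition_plan"
  )
}
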