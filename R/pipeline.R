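# Configuration-driven pipeline front end chaining the analysis stages.

.pipeline_defaults <- function() {
  list(
    seed = 1,
    output_dir = "iscat_output",
    optical = unclass(optical_config()),
    ipsf = unclass(ipsf_model()),
    simulate = list(scene = "membrane", extent_px = c(128, 128),
                    ripple_rms = 200, correlation_length = 1000,
                    n_particles = 10, diffusion = 1e4, duration = 5,
                    dt = 0.05, focus_min = 0, focus_max = 2000,
                    photon_budget = 1e4, mode = "confocal"),
    contrast = list(kernel_fwhm_multiple = 24),
    reconstruct = list(method = "ridge", median_filter = TRUE),
    track = list(r_min = 0, r_max = 8, threshold = NULL,
                 min_separation_px = 5, max_disp_nm = 600,
                 memory_frames = 3, min_length = 25,
                 c_max = 0.2, direction_prior = "free"),
    maps = list(lag_s = 5, frame_interval_s = 0.25, hysteresis = NULL),
    input = NULL
  )
}

#' Pipeline configuration
#'
#' Reads (or accepts) a nested key-value configuration for [run_pipeline()].
#' Unknown keys are rejected to protect against silent typos; omitted keys
#' take package defaults.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .pipeline_defaults()
  merge <- function(def, usr, path = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(usr)) {
      if (is.list(def[[k]]) && is.list(usr[[k]]) && !is.null(names(def[[k]])))
        def[[k]] <- merge(def[[k]], usr[[k]], paste0(path, k, "."))
      else def[[k]] <- usr[[k]]
    }
    def
  }
  out <- merge(defaults, config)
  structure(out, class = "pipeline_config")
}

.stage_seed <- function(cfg, stage) {
  offs <- c(simulate = 101L, contrast = 211L, reconstruct = 307L,
            track = 401L, maps = 503L)
  (as.integer(cfg$seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the iSCAT analysis pipeline
#'
#' Chains the package stages under one configuration, writing TIFF/CSV
#' artifacts and a JSON run log (parameters, seed, package version, config
#' hash) to `config$output_dir`. Subcommands: `"simulate"` (phantom ->
#' intensity stacks plus ground truth), `"contrast"` (raw -> contrast),
#' `"reconstruct"` (contrast z-stack -> height map), `"track"` (time series
#' -> trajectories), `"maps"` (contrast series -> persistency and
#' oscillation maps), `"all"`.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param command One of `simulate`, `contrast`, `reconstruct`, `track`,
#'   `maps`, `all`.
#' @return Invisibly, a list of in-memory results per executed stage.
#' @export
run_pipeline <- function(config,
                         command = c("all", "simulate", "contrast",
                                     "reconstruct", "track", "maps")) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  optical <- do.call(optical_config, cfg$optical)
  ipsf <- do.call(ipsf_model, cfg$ipsf)
  res <- list()
  log <- list(package = "iscatr",
              version = as.character(utils::packageVersion("iscatr")),
              seed = cfg$seed, command = command,
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  steps <- if (command == "all") c("simulate", "contrast", "reconstruct",
                                   "track", "maps") else command
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% steps) wrap("simulate", {
    sc <- cfg$simulate
    seed <- .stage_seed(cfg, "simulate")
    zs <- NULL; ts <- NULL
    if (sc$scene %in% c("membrane", "all")) {
      ph <- make_membrane_phantom(
        extent_px = unlist(sc$extent_px), pixel_size = optical$pixel_size,
        ripple_rms = sc$ripple_rms,
        correlation_length = sc$correlation_length,
        base_height = mean(c(sc$focus_min, sc$focus_max)), seed = seed)
      plan <- acquisition_plan(
        mode = sc$mode,
        focus_nm = seq(sc$focus_min, sc$focus_max, by = optical$z_step),
        photon_budget = sc$photon_budget)
      zs <- render_acquisition(ph, plan, optical, ipsf, seed = seed)
      write_stack(zs, file.path(cfg$output_dir, "simulated_zstack.tif"))
      res$phantom <- ph
    }
    if (sc$scene %in% c("particles", "all")) {
      ph <- make_particle_ensemble(
        n = sc$n_particles, diffusion = sc$diffusion,
        duration = sc$duration, dt = sc$dt,
        extent_px = unlist(sc$extent_px), pixel_size = optical$pixel_size,
        seed = seed)
      plan <- acquisition_plan(
        mode = sc$mode, focus_nm = sc$focus_min,
        n_frames = length(ph$particles$times), frame_interval = sc$dt,
        photon_budget = sc$photon_budget)
      ts <- render_acquisition(ph, plan, optical, ipsf, seed = seed + 1L)
      write_stack(ts, file.path(cfg$output_dir, "simulated_timeseries.tif"))
      utils::write.csv(ts$meta$truth,
                       file.path(cfg$output_dir, "ground_truth.csv"),
                       row.names = FALSE)
      res$particle_phantom <- ph
    }
    res$zstack <- zs; res$timeseries <- ts
  })

  input_stack <- function() {
    if (!is.null(res$zstack)) return(res$zstack)
    if (!is.null(res$timeseries)) return(res$timeseries)
    if (is.null(cfg$input)) stop("no input stack: set config$input")
    if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
    read_stack(cfg$input)
  }

  if ("contrast" %in% steps) wrap("contrast", {
    stk <- input_stack()
    cm <- compute_contrast(stk, psf_fwhm = lateral_fwhm(optical),
                           kernel_fwhm_multiple =
                             cfg$contrast$kernel_fwhm_multiple)
    cs <- stk; cs$values <- cm$values
    write_stack(cs, file.path(cfg$output_dir, "contrast.tif"))
    res$contrast <- cm
  })

  if ("reconstruct" %in% steps) wrap("reconstruct", {
    cm <- res$contrast
    src <- if (!is.null(res$zstack)) res$zstack
           else if (is.null(res$timeseries)) input_stack()
    if (is.null(cm) || is.null(src) || !"z" %in% src$axes) {
      if (length(steps) > 1) {
        message("reconstruct: no contrast z-stack available; skipped")
      } else stop("reconstruct requires the contrast stage on a z-stack input")
    } else {
    hm <- reconstruct_surface(cm$values, focus_nm = src$focus_nm,
                              ipsf = ipsf,
                              method = cfg$reconstruct$method,
                              median_filter = cfg$reconstruct$median_filter)
    hs <- iscat_stack(array(ifelse(is.na(hm$heights), 0, hm$heights),
                            dim = c(dim(hm$heights), 1)),
                      axes = c("y", "x", "z"),
                      pixel_size = optical$pixel_size)
    write_stack(hs, file.path(cfg$output_dir, "height_map.tif"))
    vm <- iscat_stack(array(hm$validity * 1L, c(dim(hm$validity), 1)),
                      axes = c("y", "x", "z"),
                      pixel_size = optical$pixel_size)
    write_stack(vm, file.path(cfg$output_dir, "height_map_validity.tif"))
    res$height_map <- hm
    }
  })

  time_series <- function() {
    if (!is.null(res$timeseries)) return(res$timeseries)
    stk <- input_stack()
    if (!"t" %in% stk$axes) return(NULL)
    stk
  }

  if ("track" %in% steps) wrap("track", {
    ts <- time_series()
    if (is.null(ts) && length(steps) > 1) {
      message("track: no time-series input available; skipped")
    } else if (is.null(ts)) {
      stop("track requires a time-series (t axis) input")
    } else {
    cm <- compute_contrast(ts, psf_fwhm = lateral_fwhm(optical),
                           kernel_fwhm_multiple =
                             cfg$contrast$kernel_fwhm_multiple)
    tp <- cfg$track
    thr <- tp$threshold
    if (is.null(thr)) {
      sc1 <- radial_variance_transform(cm$values[, , 1], tp$r_min, tp$r_max)
      thr <- 10 * stats::median(sc1)
    }
    det <- detect_stack(cm$values, tp$r_min, tp$r_max, thr,
                        tp$min_separation_px)
    det$x <- det$x_px * optical$pixel_size
    det$y <- det$y_px * optical$pixel_size
    trj <- link_trajectories(det, max_disp = tp$max_disp_nm,
                             memory_frames = tp$memory_frames,
                             min_length = tp$min_length)
    if (nrow(trj)) {
      cal <- iscat_calibration(c_max = tp$c_max,
                               direction_prior = tp$direction_prior)
      zs <- lapply(split(seq_len(nrow(trj)), trj$trajectory), function(ix) {
        tryCatch(as.numeric(contrast_to_dz(trj$contrast[ix], cal)),
                 error = function(e) rep(NA_real_, length(ix)))
      })
      trj$z_rel_nm <- unsplit(zs, trj$trajectory)
    }
    utils::write.csv(as.data.frame(trj),
                     file.path(cfg$output_dir, "trajectories.csv"),
                     row.names = FALSE)
    res$trajectories <- trj
    }
  })

  if ("maps" %in% steps) wrap("maps", {
    ts <- time_series()
    if (is.null(ts) && length(steps) > 1) {
      message("maps: no time-series input available; skipped")
    } else if (is.null(ts)) {
      stop("maps requires a time-series (t axis) input")
    } else {
    cm <- compute_contrast(ts, psf_fwhm = lateral_fwhm(optical),
                           kernel_fwhm_multiple =
                             cfg$contrast$kernel_fwhm_multiple)
    mp <- cfg$maps
    occ <- abs(cm$values) > 2 * stats::sd(cm$values)
    pm <- persistency_map(occ * 1, lag_s = mp$lag_s,
                          frame_interval_s = mp$frame_interval_s)
    om <- oscillation_map(cm$values, hysteresis = mp$hysteresis)
    write_stack(iscat_stack(array(pm$values, c(dim(pm$values), 1)),
                            axes = c("y", "x", "t"),
                            pixel_size = optical$pixel_size),
                file.path(cfg$output_dir, "persistency.tif"))
    write_stack(iscat_stack(array(om$counts + 0, c(dim(om$counts), 1)),
                            axes = c("y", "x", "t"),
                            pixel_size = optical$pixel_size),
                file.path(cfg$output_dir, "oscillation.tif"))
    idx <- which(pm$values >= 0, arr.ind = TRUE)
    utils::write.csv(
      data.frame(y_px = idx[, 1], x_px = idx[, 2],
                 persistency_s = as.numeric(pm$values),
                 inversions = as.integer(om$counts)),
      file.path(cfg$output_dir, "maps_summary.csv"), row.names = FALSE)
    res$persistency <- pm; res$oscillation <- om
    }
  })

  cfg_path <- file.path(cfg$output_dir, "config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  log$config_md5 <- unname(tools::md5sum(cfg_path))
  log$parameters <- unclass(cfg)
  jsonlite::write_json(log, file.path(cfg$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(res)
}
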