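#' Image stack container
#'
#' A thin wrapper around a numeric array holding detected intensity (or
#' contrast) with axis metadata. Axes are named from `"y"`, `"x"`, `"z"`,
#' `"t"` in storage order; `y` and `x` always come first.
#'
#' @param values Numeric array (2--4 dimensions).
#' @param axes Character vector naming each array dimension, e.g.
#'   `c("y", "x", "z")`.
#' @param pixel_size Lateral sampling, nm/px.
#' @param focus_nm Focus position(s) of the z planes (length = z extent, or
#'   length 1 for single-plane series).
#' @param frame_interval Frame interval in seconds (for a `t` axis).
#' @param meta Optional list of further metadata (seed, photon budget,
#'   model parameters ...).
#' @return An object of class `iscat_stack`.
#' @export
iscat_stack <- function(values, axes, pixel_size, focus_nm = 0,
                        frame_interval = NA_real_, meta = list()) {
  values <- as.array(values)
  if (length(dim(values)) != length(axes))
    stop("axes must name every array dimension")
  if (length(dim(values)) < 2 || length(dim(values)) > 4)
    stop("unsupported shape: stacks must have 2 to 4 dimensions")
  if (!identical(axes[1:2], c("y", "x")))
    stop("first two axes must be y, x")
  if (anyDuplicated(axes)) stop("duplicated axis names")
  structure(
    list(values = values, axes = axes, pixel_size = pixel_size,
         focus_nm = focus_nm, frame_interval = frame_interval, meta = meta),
    class = "iscat_stack"
  )
}

#' @export
print.iscat_stack <- function(x, ...) {
  cat("iSCAT image stack\n")
  cat(sprintf("  dimensions : %s  (%s)\n",
              paste(dim(x$values), collapse = " x "),
              paste(x$axes, collapse = ",")))
  cat(sprintf("  pixel size : %g nm\n", x$pixel_size))
  if (length(x$focus_nm) > 1)
    cat(sprintf("  focus      : %g .. %g nm (%d planes)\n",
                min(x$focus_nm), max(x$focus_nm), length(x$focus_nm)))
  else cat(sprintf("  focus      : %g nm\n", x$focus_nm))
  if (is.finite(x$frame_interval))
    cat(sprintf("  frame dt   : %g s\n", x$frame_interval))
  rng <- range(x$values)
  cat(sprintf("  values     : [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Extract one 2D frame from a stack
#'
#' @param stack An [iscat_stack()].
#' @param z,t Plane / frame index along the `z` / `t` axis (ignored when the
#'   stack lacks that axis).
#' @return A numeric matrix `[y, x]`.
#' @export
stack_frame <- function(stack, z = 1, t = 1) {
  a <- stack$axes
  v <- stack$values
  idx <- rep(list(quote(expr = )), length(a))
  if ("z" %in% a) idx[[which(a == "z")]] <- z
  if ("t" %in% a) idx[[which(a == "t")]] <- t
  out <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  dim(out) <- dim(v)[1:2]
  out
}

#' Write / read image stacks as multi-page TIFF with a JSON sidecar
#'
#' `write_stack()` stores the array as a multi-page TIFF (pages iterate the
#' trailing axes, last axis slowest) and a `<path>.json` sidecar recording
#' axes, dimensions, voxel sizes, frame interval, value scaling and any extra
#' metadata. Float data are min/max-scaled into \[0, 1\] for 32-bit float
#' storage with the scale and offset stated in the sidecar; `uint16` data
#' (integer arrays within \[0, 65535\]) round-trip bit-identically.
#' `read_stack()` reverses the process; the sidecar is required because TIFF
#' pages alone cannot disambiguate `z` from `t`.
#'
#' @param stack An [iscat_stack()].
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   an [iscat_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "iscat_stack"))
  v <- stack$values
  d <- dim(v)
  npage <- prod(d) / (d[1] * d[2])
  pv <- v
  dim(pv) <- c(d[1], d[2], npage)
  integerish <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
  if (integerish) {
    offset <- 0; scale <- 65535; bps <- 16L
  } else {
    offset <- min(v); scale <- max(v) - min(v)
    if (scale == 0) scale <- 1
    bps <- 32L
  }
  pages <- lapply(seq_len(npage), function(i) (pv[, , i] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none",
                  reduce = FALSE)
  side <- list(
    axes = stack$axes, dim = d, pixel_size_nm = stack$pixel_size,
    focus_nm = stack$focus_nm, frame_interval_s = stack$frame_interval,
    value_offset = offset, value_scale = scale,
    sample_format = if (bps == 16L) "uint16" else "float32",
    storage_mode = storage.mode(v),
    meta = stack$meta
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar metadata file '", side_path,
         "': axis order (z vs t) and voxel sizes cannot be inferred from the TIFF alone")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  d <- as.integer(side$dim)
  if (length(d) > 4) stop("unsupported shape: more than 4 dimensions")
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, dim = c(d[1], d[2], prod(d) / (d[1] * d[2])))
  for (i in seq_len(dim(v)[3])) v[, , i] <- pages[[i]]
  v <- v * side$value_scale + side$value_offset
  if (side$sample_format == "uint16") v <- round(v)
  if (identical(side$storage_mode, "integer")) storage.mode(v) <- "integer"
  dim(v) <- d
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  iscat_stack(v, axes = side$axes, pixel_size = side$pixel_size_nm,
              focus_nm = side$focus_nm,
              frame_interval = if (is.null(side$frame_interval_s)) NA_real_
                               else side$frame_interval_s,
              meta = meta)
}
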