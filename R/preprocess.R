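# Gaussian blur with mirror (reflective) boundary padding, wrapped around
# EBImage's FFT convolution. Mirror padding avoids the edge-contrast
# artifacts that circular wrap-around would introduce in background maps.
.gblur_mirror <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  pad_y <- min(ny - 1, ceiling(4 * sigma_px))
  pad_x <- min(nx - 1, ceiling(4 * sigma_px))
  iy <- c(pad_y:1, seq_len(ny), ny:(ny - pad_y + 1))
  ix <- c(pad_x:1, seq_len(nx), nx:(nx - pad_x + 1))
  padded <- img[iy, ix, drop = FALSE]
  radius <- min(floor((min(dim(padded)) - 1) / 2), ceiling(4 * sigma_px))
  ker <- EBImage::makeBrush(2 * radius + 1, shape = "Gaussian",
                            sigma = sigma_px)
  sm <- EBImage::filter2(padded, ker, boundary = "circular")
  sm[pad_y + seq_len(ny), pad_x + seq_len(nx)]
}

#' Estimate the iSCAT background by low-pass Gaussian filtering
#'
#' The background `I_bg` entering the contrast definition is obtained by
#' blurring the raw image with a Gaussian whose FWHM is a multiple of the
#' lateral PSF FWHM, large enough to average over the structures of interest
#' while following slow variations of the reference intensity. Appropriate
#' multiples lie between 16 and 32 PSF FWHM; values outside that range are
#' allowed but flagged with a warning. Stacks are filtered per plane.
#'
#' @param image Numeric matrix, 3D array, or [iscat_stack()] of strictly
#'   positive intensities.
#' @param psf_fwhm Lateral PSF FWHM in nm (see [lateral_fwhm()]).
#' @param kernel_fwhm_multiple Kernel FWHM as a multiple of `psf_fwhm`;
#'   default 24 (midpoint of the recommended 16--32 interval).
#' @param pixel_size nm per pixel (taken from the stack when given one).
#' @return Background of the same shape as the input (plain array for plain
#'   input, stack for stack input).
#' @export
estimate_background <- function(image, psf_fwhm, kernel_fwhm_multiple = 24,
                                pixel_size = NULL) {
  if (inherits(image, "iscat_stack")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    bg <- estimate_background(image$values, psf_fwhm, kernel_fwhm_multiple,
                              pixel_size)
    out <- image; out$values <- bg
    return(out)
  }
  if (is.null(pixel_size))
    stop("pixel_size is required for plain-array input")
  if (kernel_fwhm_multiple <= 0) stop("kernel_fwhm_multiple must be positive")
  if (any(image <= 0))
    stop("degenerate input: intensities must be strictly positive")
  if (kernel_fwhm_multiple < 16 || kernel_fwhm_multiple > 32)
    warning("kernel_fwhm_multiple ", kernel_fwhm_multiple,
            " lies outside the recommended range [16, 32] PSF FWHM")
  sigma_px <- kernel_fwhm_multiple * psf_fwhm / (2 * sqrt(2 * log(2))) /
    pixel_size
  if (is.matrix(image)) return(.gblur_mirror(image, sigma_px))
  out <- image
  for (k in seq_len(dim(image)[3]))
    out[, , k] <- .gblur_mirror(image[, , k], sigma_px)
  out
}

#' Contrast map
#'
#' Elementwise iSCAT contrast `(I - I_bg) / I_bg` with the background
#' retained for provenance.
#'
#' @param image Intensity matrix/array or [iscat_stack()].
#' @param background Background of the same shape (strictly positive), as
#'   from [estimate_background()].
#' @param kernel_fwhm_multiple Optional record of the kernel setting used.
#' @return An object of class `contrast_map` with elements `values`,
#'   `background`, `kernel_fwhm_multiple`; stack metadata is carried along
#'   when the input is a stack.
#' @export
contrast_map <- function(image, background, kernel_fwhm_multiple = NA_real_) {
  stk <- NULL
  if (inherits(image, "iscat_stack")) { stk <- image; image <- image$values }
  if (inherits(background, "iscat_stack")) background <- background$values
  if (!identical(dim(image), dim(background)) &&
      !(is.null(dim(image)) && is.null(dim(background)) &&
        length(image) == length(background)))
    stop("image and background shapes differ")
  if (any(background <= 0)) stop("degenerate background: must be positive")
  structure(
    list(values = (image - background) / background, background = background,
         kernel_fwhm_multiple = kernel_fwhm_multiple, stack = stk),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("iSCAT contrast map: %s, C in [%.4f, %.4f]\n",
              paste(dim(x$values), collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

# Pull a plain numeric array out of map-like inputs.
.values <- function(x) {
  if (inherits(x, "contrast_map")) x$values
  else if (inherits(x, "iscat_stack")) x$values
  else x
}

#' Background-correct a stack into a contrast stack
#'
#' Convenience composition of [estimate_background()] (per plane) and
#' [contrast_map()].
#'
#' @inheritParams estimate_background
#' @return A `contrast_map` whose `values` has the shape of the stack.
#' @export
compute_contrast <- function(image, psf_fwhm, kernel_fwhm_multiple = 24,
                             pixel_size = NULL) {
  bg <- estimate_background(image, psf_fwhm, kernel_fwhm_multiple, pixel_size)
  contrast_map(image, bg, kernel_fwhm_multiple)
}

#' Flat-field a wide-field image
#'
#' Divides by a smooth reference illumination profile and renormalizes the
#' result to mean 1.
#'
#' @param image Intensity matrix.
#' @param reference Strictly positive illumination reference of the same
#'   shape.
#' @return Flat-fielded image with mean exactly 1.
#' @export
flat_field <- function(image, reference) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference shapes differ")
  if (any(reference <= 0)) stop("reference contains non-positive pixels")
  out <- image / reference
  out / mean(out)
}
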