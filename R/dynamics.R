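# Pixelwise temporal summaries of network dynamics: persistency of
# occupancy and counting of contrast inversions.

#' Persistency map of network occupancy
#'
#' For each pixel of a binary occupancy movie, the duration (in seconds) of
#' the longest continuous occupancy, where interruptions shorter than the
#' lag period are tolerated: occupied runs separated by gaps of less than
#' `lag_s` merge into one run whose duration spans first to last occupied
#' frame. At `lag_s = frame_interval_s` this reduces to the plain maximal
#' run length. The alternative `mode = "total"` sums all occupied frames
#' regardless of contiguity.
#'
#' @param mask_stack Logical/0-1 array `[y, x, t]` (or [iscat_stack()]).
#' @param lag_s Lag period in s (>= `frame_interval_s`).
#' @param frame_interval_s Frame interval in s.
#' @param mode `"gap_tolerant"` (default) or `"total"`.
#' @return An object of class `persistency_map`: `values` (s), `lag`,
#'   `n_frames`, `frame_interval`, `mode`.
#' @export
persistency_map <- function(mask_stack, lag_s, frame_interval_s,
                            mode = c("gap_tolerant", "total")) {
  mode <- match.arg(mode)
  v <- .values(mask_stack)
  if (length(dim(v)) != 3 || prod(dim(v)) == 0)
    stop("a non-empty [y, x, t] mask stack is required")
  if (lag_s < frame_interval_s)
    stop("lag_s must be at least frame_interval_s")
  ny <- dim(v)[1]; nx <- dim(v)[2]; nt <- dim(v)[3]
  m <- matrix(v != 0, ny * nx, nt)
  if (mode == "total") {
    frames <- rowSums(m)
  } else {
    max_gap <- lag_s / frame_interval_s   # gaps strictly shorter than lag merge
    frames <- apply(m, 1, function(occ) {
      if (!any(occ)) return(0)
      r <- rle(occ)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      on <- which(r$values)
      best <- 0; run_start <- starts[on[1]]; run_end <- ends[on[1]]
      if (length(on) > 1) for (j in on[-1]) {
        gap <- starts[j] - run_end - 1
        if (gap * frame_interval_s < lag_s && gap <= max_gap) {
          run_end <- ends[j]
        } else {
          best <- max(best, run_end - run_start + 1)
          run_start <- starts[j]; run_end <- ends[j]
        }
      }
      max(best, run_end - run_start + 1)
    })
  }
  structure(
    list(values = matrix(frames * frame_interval_s, ny, nx), lag = lag_s,
         n_frames = nt, frame_interval = frame_interval_s, mode = mode),
    class = "persistency_map"
  )
}

#' @export
print.persistency_map <- function(x, ...) {
  cat(sprintf(
    "Persistency map (%s): %d x %d px, %d frames / %g s, lag %g s, max %g s\n",
    x$mode, nrow(x$values), ncol(x$values), x$n_frames,
    x$n_frames * x$frame_interval, x$lag, max(x$values)))
  invisible(x)
}

#' Contrast-inversion (oscillation) map
#'
#' Counts, per pixel, the sign changes of the mean-subtracted contrast time
#' course using Schmitt-trigger hysteresis: after the signal has exceeded
#' one threshold (`+hysteresis` or `-hysteresis`), a crossing is registered
#' only once it exceeds the opposite threshold. A pixel that starts inside
#' the hysteresis band and later leaves it registers its first excursion as
#' a crossing; a pixel already beyond a threshold at the first frame does
#' not. Constant pixels count 0; a noiseless sinusoid of f full cycles
#' counts 2f.
#'
#' @param contrast_stack `[y, x, t]` contrast array (or [iscat_stack()] /
#'   `contrast_map`).
#' @param hysteresis Trigger threshold in contrast units; scalar, matrix, or
#'   `NULL` for the default `0.25 *` per-pixel temporal standard deviation.
#' @return An object of class `oscillation_map`: integer `counts`,
#'   `hysteresis`, `n_frames`.
#' @export
oscillation_map <- function(contrast_stack, hysteresis = NULL) {
  v <- .values(contrast_stack)
  if (length(dim(v)) != 3 || dim(v)[3] < 2)
    stop("a [y, x, t] stack with at least 2 frames is required")
  ny <- dim(v)[1]; nx <- dim(v)[2]; nt <- dim(v)[3]
  m <- matrix(v, ny * nx, nt)
  m <- m - rowMeans(m)
  if (is.null(hysteresis)) {
    h <- 0.25 * apply(m, 1, stats::sd)
  } else h <- rep_len(as.numeric(hysteresis), ny * nx)
  state <- integer(ny * nx)
  counts <- integer(ny * nx)
  # frame 1 arms without counting where already beyond a threshold
  state[m[, 1] > h] <- 1L
  state[m[, 1] < -h] <- -1L
  for (t in 2:nt) {
    new_state <- state
    new_state[m[, t] > h] <- 1L
    new_state[m[, t] < -h] <- -1L
    counts <- counts + as.integer(new_state != state)
    state <- new_state
  }
  structure(
    list(counts = matrix(counts, ny, nx),
         hysteresis = matrix(h, ny, nx), n_frames = nt),
    class = "oscillation_map"
  )
}

#' @export
print.oscillation_map <- function(x, ...) {
  cat(sprintf(
    "Contrast-inversion map: %d x %d px over %d frames, counts 0..%d\n",
    nrow(x$counts), ncol(x$counts), x$n_frames, max(x$counts)))
  invisible(x)
}
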