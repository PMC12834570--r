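#' Frame timing of a dynamic acquisition
#'
#' A `frame_schedule` holds per-frame acquisition start times and durations in
#' seconds. Frames must begin at 0 s, be strictly ascending, have positive
#' durations, and must not overlap.
#'
#' @param start_s numeric vector of frame start times (s); first must be 0.
#' @param duration_s numeric vector of frame durations (s), same length.
#' @return An object of class `frame_schedule` with fields `start_s` and
#'   `duration_s`.
#' @examples
#' sch <- frame_schedule(c(0, 10, 20), c(10, 10, 60))
#' frame_mid_times(sch)
#' @export
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  stop_if(length(start_s) != length(duration_s),
          "start_s and duration_s must have equal length")
  stop_if(length(start_s) < 1L, "schedule must contain at least one frame")
  stop_if(any(!is.finite(start_s)) || any(!is.finite(duration_s)),
          "schedule times must be finite")
  stop_if(start_s[1] != 0, "first frame must start at 0 s")
  stop_if(any(diff(start_s) <= 0), "frame starts must be strictly ascending")
  stop_if(any(duration_s <= 0), "frame durations must be positive")
  n <- length(start_s)
  if (n > 1L) {
    stop_if(any(start_s[-n] + duration_s[-n] > start_s[-1] + 1e-9),
            "frames must not overlap")
  }
  structure(list(start_s = start_s, duration_s = duration_s),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' Mid-frame acquisition times
#'
#' @param schedule a [frame_schedule].
#' @return numeric vector of mid-frame times (s), `start + duration / 2`.
#' @export
frame_mid_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$start_s + schedule$duration_s / 2
}

#' Default dynamic acquisition schedule
#'
#' 12 x 10 s, 6 x 20 s, 6 x 60 s (24 frames, 600 s total): short early frames
#' to resolve the bolus, and more than two minutes of late frames from which
#' the alignment reference is summed.
#'
#' @return a [frame_schedule].
#' @export
default_schedule <- function() {
  dur <- c(rep(10, 12), rep(20, 6), rep(60, 6))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' A 4D dynamic PET series
#'
#' The central container: voxel intensities ordered `(x, y, z, frame)`, voxel
#' spacing in mm, and the frame timing. Intensities are arbitrary activity
#' units; negatives are permitted (reconstructed PET after noise).
#'
#' @param voxels 4D numeric array `(x, y, z, frame)`.
#' @param spacing_mm numeric length-3 voxel size (mm) along x, y, z.
#' @param schedule a [frame_schedule]; its length must equal the frame count.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, spacing_mm, schedule) {
  stop_if(length(dim(voxels)) != 4L, "voxels must be a 4D array (x, y, z, frame)")
  stop_if(!inherits(schedule, "frame_schedule"), "schedule must be a frame_schedule")
  stop_if(dim(voxels)[4] != length(schedule),
          "frame count (", dim(voxels)[4], ") does not match schedule length (",
          length(schedule), ")")
  spacing_mm <- as.numeric(spacing_mm)
  stop_if(length(spacing_mm) != 3L || any(spacing_mm <= 0),
          "spacing_mm must be 3 positive values")
  stop_if(any(!is.finite(voxels)), "voxel intensities must be finite")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, schedule = schedule),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_series> %d frames, %dx%dx%d voxels @ %.2gx%.2gx%.2g mm, %g s total\n",
              d[4], d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], max(x$schedule$start_s + x$schedule$duration_s)))
  invisible(x)
}

n_frames <- function(series) dim(series$voxels)[4]

get_frame <- function(series, i) series$voxels[, , , i]

# Per-frame total activity (sum of voxel values).
frame_totals <- function(series) {
  apply(series$voxels, 4, sum)
}

# Separable Gaussian blur with zero (constant) padding; the kernel is
# normalised to unit sum so interior intensity is conserved. sigma given in
# voxels per axis; sigma 0 disables the axis.
gauss_blur_3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      idx <- seq_len(n)
      src <- idx + o
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kern[o + half + 1]
    }
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    v <- aperm(vol, perm)
    dm <- dim(v)
    v <- matrix(K %*% matrix(v, dm[1], dm[2] * dm[3]), dm[1], dm[2] * dm[3])
    dim(v) <- dm
    inv <- order(perm)
    vol <- aperm(v, inv)
  }
  vol
}
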