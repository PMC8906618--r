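#' Construct a trial recording
#'
#' The central data object of the pipeline: per-frame 3D positions of the 25
#' canonical markers in the canonical laboratory frame (`x` cranial, `y`
#' left, `z` up; millimetres), together with the capture frame rate, the
#' treadmill belt speed, the measurement condition and subject metadata.
#' The animal is quasi-stationary in this frame while the belt moves under
#' it.
#'
#' Missing samples (marker dropouts) are carried as an explicit logical
#' mask; positions at masked frames are `NA` and are never silently
#' zero-filled.
#'
#' @param positions Numeric array `n_frames x 3 x 25` with dimnames
#'   `list(NULL, c("x","y","z"), canonical_markers())`, in mm.  A marker's
#'   missing frames are `NA` in all three components.
#' @param frame_rate Sampling frequency in Hz (> 0).
#' @param belt_speed Treadmill belt speed in m/s (read from the treadmill
#'   display), or `NA` if unknown.
#' @param condition Measurement condition label: `"reference"` (no
#'   harness), `"harness"`, or `"harness_leash"`.
#' @param subject Named list of subject metadata (e.g. `id`, `mass_kg`,
#'   `gait_pattern`); free-form.
#' @param mask Optional logical `n_frames x 25` matrix, `TRUE` where the
#'   sample is present.  Defaults to frames whose coordinates are all
#'   finite.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(positions, frame_rate, belt_speed = NA_real_,
                            condition = c("reference", "harness",
                                          "harness_leash"),
                            subject = list(), mask = NULL) {
  condition <- match.arg(condition)
  markers <- canonical_markers()
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[2] != 3L)
    stop("positions must be an n_frames x 3 x n_markers array")
  if (dim(positions)[3] != length(markers))
    stop("positions must cover all ", length(markers), " canonical markers")
  labs <- dimnames(positions)[[3]]
  if (is.null(labs))
    stop("positions must carry marker labels in dimnames")
  unknown <- setdiff(labs, markers)
  if (length(unknown))
    stop("unknown marker label(s): ", paste(unknown, collapse = ", "))
  # normalize marker order to canonical
  positions <- positions[, , markers, drop = FALSE]
  dimnames(positions)[[2]] <- c("x", "y", "z")
  n <- dim(positions)[1]
  if (n < 2L) stop("a recording needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      !is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be a single positive number (Hz)")
  if (is.null(mask)) {
    mask <- is.finite(positions[, 1, ]) & is.finite(positions[, 2, ]) &
      is.finite(positions[, 3, ])
  } else {
    if (!is.logical(mask) || !identical(dim(mask), c(n, length(markers))))
      stop("mask must be a logical n_frames x 25 matrix")
    if (!is.null(colnames(mask))) mask <- mask[, markers, drop = FALSE]
  }
  colnames(mask) <- markers
  # present samples must be finite
  for (ax in 1:3) {
    bad <- mask & !is.finite(positions[, ax, ])
    if (any(bad))
      stop("non-finite coordinates at unmasked samples (marker ",
           paste(unique(markers[ceiling(which(bad) / n)]),
                 collapse = ", "), ")")
  }
  structure(list(positions = positions, frame_rate = frame_rate,
                 belt_speed = belt_speed, condition = condition,
                 subject = subject, mask = mask),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- n_frames(x)
  cat("<trial_recording> ", n, " frames @ ", x$frame_rate, " Hz (",
      round(n / x$frame_rate, 2), " s), condition: ", x$condition, "\n",
      sep = "")
  if (is.finite(x$belt_speed))
    cat("  belt speed: ", x$belt_speed, " m/s\n", sep = "")
  if (length(x$subject))
    cat("  subject: ",
        paste(names(x$subject), unlist(x$subject), sep = "=",
              collapse = ", "), "\n", sep = "")
  miss <- 1 - mean(x$mask)
  cat("  markers: ", ncol(x$mask), ", missing samples: ",
      sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @rdname trial_recording
#' @param x A `trial_recording`.
#' @export
n_frames <- function(x) dim(x$positions)[1]

#' Time stamps of a recording
#'
#' @param x A `trial_recording`.
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1L) / x$frame_rate

# Maximum tolerated fraction of missing samples in an analysis window
# before a marker component is refused rather than interpolated.
MAX_MISSING_FRAC <- 0.2

# Linearly interpolate interior gaps of a series; extend the first/last
# observed value over leading/trailing gaps.  Assumes at least one finite
# value.
fill_gaps <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(is.finite(v))
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' Extract one marker coordinate component
#'
#' Returns a marker's `x`, `y` or `z` series with the package's missing-data
#' policy applied: if more than 20% of the samples in the requested window
#' are missing the marker is considered unusable and an error is raised;
#' otherwise interior gaps are linearly interpolated (leading/trailing gaps
#' take the nearest observed value).
#'
#' @param rec A `trial_recording`.
#' @param marker Marker label.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param frames Optional integer vector restricting the window (defaults to
#'   all frames).
#' @param fill If `FALSE`, return the raw series with `NA` at masked frames
#'   instead of applying the gap policy.
#' @return Numeric vector over `frames`.
#' @export
marker_series <- function(rec, marker, axis = c("x", "y", "z"),
                          frames = NULL, fill = TRUE) {
  axis <- match.arg(axis)
  if (!marker %in% canonical_markers())
    stop("unknown marker label: ", marker)
  if (is.null(frames)) frames <- seq_len(n_frames(rec))
  v <- rec$positions[frames, axis, marker]
  v[!rec$mask[frames, marker]] <- NA_real_
  if (!fill) return(v)
  frac <- mean(!is.finite(v))
  if (frac > MAX_MISSING_FRAC)
    stop(sprintf("marker %s is missing in %.0f%% of the window (policy limit %.0f%%)",
                 marker, 100 * frac, 100 * MAX_MISSING_FRAC))
  fill_gaps(v)
}

#' Extract a marker's 3D trajectory
#'
#' @inheritParams marker_series
#' @return An n x 3 matrix (columns `x`, `y`, `z`) with the gap policy of
#'   [marker_series()] applied per component (or raw `NA`s if `fill =
#'   FALSE`).
#' @export
marker_xyz <- function(rec, marker, frames = NULL, fill = TRUE) {
  cbind(x = marker_series(rec, marker, "x", frames, fill),
        y = marker_series(rec, marker, "y", frames, fill),
        z = marker_series(rec, marker, "z", frames, fill))
}

#' Mask a marker over a frame range (simulated dropout)
#'
#' Marks the given marker as missing over the given frames, as happens when
#' a marker is occluded on a real recording.  Downstream quantities that
#' need that marker become missing per the gap policy.
#'
#' @param rec A `trial_recording`.
#' @param marker Marker label to drop.
#' @param frames Integer vector of frames to mask (default: all).
#' @return The modified `trial_recording`.
#' @export
degrade <- function(rec, marker, frames = NULL) {
  stopifnot(inherits(rec, "trial_recording"))
  if (length(marker) != 1L || !marker %in% canonical_markers())
    stop("unknown marker label: ", marker)
  if (is.null(frames)) frames <- seq_len(n_frames(rec))
  if (length(frames) == 0L) return(rec)
  if (any(frames < 1L | frames > n_frames(rec)))
    stop("frames out of range")
  rec$mask[frames, marker] <- FALSE
  rec$positions[frames, , marker] <- NA_real_
  rec
}
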