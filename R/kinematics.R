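#' The 18 canonical joint-angle definitions
#'
#' Each angle is the interior angle at an apex marker between the vectors
#' to two peripheral markers, measured on a 2D projection: the sagittal
#' plane (canonical x-z) or the horizontal/dorsal plane (x-y).  The set
#' comprises the three spinal angles (apexes T1, T13, L7) in both planes
#' and, per side, the shoulder, elbow, carpus (forelimb) and hip, stifle,
#' tarsus (hindlimb) angles in the sagittal plane.  The caudal peripheral
#' marker of the sagittal L7 angle is the sacral apex S5, matching the
#' horizontal L7 definition.
#'
#' @return Data frame with columns `name`, `apex`, `a`, `b`, `plane`
#'   (18 rows, fixed order).
#' @export
joint_angle_definitions <- function() {
  spine <- function(plane) data.frame(
    name = paste0("spine_", c("T1", "T13", "L7"), "_",
                  substr(plane, 1, 3)),
    apex = c("T1", "T13", "L7"),
    a = c("S1", "T1", "T13"),
    b = c("T13", "L7", "S5"),
    plane = plane)
  limb <- function(side) {
    f <- paste0("F", side); b <- paste0("B", side)
    data.frame(
      name = paste0(c("shoulder", "elbow", "carpus", "hip", "stifle",
                      "tarsus"), "_", side),
      apex = c(paste0(f, c(2, 3, 4)), paste0(b, c(2, 3, 4))),
      a = c(paste0(f, c(1, 4, 5)), paste0(b, c(1, 4, 5))),
      b = c(paste0(f, c(3, 2, 3)), paste0(b, c(3, 2, 3))),
      plane = "sagittal")
  }
  defs <- rbind(spine("horizontal"), spine("sagittal"),
                limb("R")[1:3, ], limb("L")[1:3, ],
                limb("R")[4:6, ], limb("L")[4:6, ])
  rownames(defs) <- NULL
  defs
}

#' Names of the 18 joint angles
#' @return Character vector, in registry order.
#' @export
joint_angle_names <- function() joint_angle_definitions()$name

# Project n x 3 coordinates onto a named plane -> n x 2.
project_plane <- function(xyz, plane) {
  cols <- switch(plane, sagittal = c("x", "z"), horizontal = c("x", "y"),
                 stop("plane must be \"sagittal\" or \"horizontal\""))
  xyz[, cols, drop = FALSE]
}

#' Projected interior angle at an apex
#'
#' The angle between the vectors apex->a and apex->b after projecting all
#' three points onto the named plane; unsigned, in degrees, in \[0, 180\].
#' Invariant to in-plane rotation and uniform scaling, and symmetric in
#' `a` and `b`.
#'
#' @param a,apex,b Numeric length-3 vectors or n x 3 matrices (columns
#'   x, y, z).
#' @param plane `"sagittal"` (x-z) or `"horizontal"` (x-y).
#' @param on_degenerate What to do when projected points coincide:
#'   `"error"` (default, for scalar use) or `"na"` (propagate missingness,
#'   used frame-wise by [compute_joint_angles()]).
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' projected_angle(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), "sagittal")  # 90
projected_angle <- function(a, apex, b, plane = "sagittal",
                            on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  as_mat <- function(p) {
    if (!is.matrix(p)) p <- matrix(p, 1, 3)
    if (is.null(colnames(p))) colnames(p) <- c("x", "y", "z")
    p
  }
  a <- as_mat(a); apex <- as_mat(apex); b <- as_mat(b)
  u <- project_plane(a, plane) - project_plane(apex, plane)
  v <- project_plane(b, plane) - project_plane(apex, plane)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  degen <- !is.finite(nu) | !is.finite(nv) | nu < 1e-9 | nv < 1e-9
  if (any(degen, na.rm = TRUE) && on_degenerate == "error")
    stop("degenerate geometry: projected points coincide")
  cosang <- rowSums(u * v) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[degen] <- NA_real_
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Compute the 18 joint-angle series of a recording
#'
#' Evaluates every canonical angle definition at every frame.  Frames at
#' which any of the three defining markers is masked, or at which the
#' projected points coincide, carry `NA`.
#'
#' @param rec A (filtered) [trial_recording()].
#' @return Numeric matrix `n_frames x 18`, columns named per
#'   [joint_angle_names()], in degrees.
#' @export
compute_joint_angles <- function(rec) {
  stopifnot(inherits(rec, "trial_recording"))
  defs <- joint_angle_definitions()
  n <- n_frames(rec)
  out <- matrix(NA_real_, n, nrow(defs),
                dimnames = list(NULL, defs$name))
  P <- rec$positions
  if (!all(rec$mask)) {
    nah <- !rec$mask
    for (ax in 1:3) {
      tmp <- P[, ax, ]; tmp[nah] <- NA_real_; P[, ax, ] <- tmp
    }
  }
  raw <- function(m) P[, , m, drop = TRUE]
  for (j in seq_len(nrow(defs))) {
    out[, j] <- projected_angle(raw(defs$a[j]), raw(defs$apex[j]),
                                raw(defs$b[j]), defs$plane[j],
                                on_degenerate = "na")
  }
  out
}

#' Normalize an angle series over one gait cycle to 101 points
#'
#' Re-interpolates the series between the cycle's start and end frames onto
#' 101 equally spaced points, giving the value at each integer percent of
#' the gait cycle from 0 to 100%.  Missing frames inside the cycle are
#' bridged by the interpolation; if more than 20% of the cycle's frames are
#' missing the whole curve is returned missing.
#'
#' @param series Numeric per-frame series (e.g. one column of
#'   [compute_joint_angles()]).
#' @param cycle One element of a `gait_cycles` object (or any list with
#'   `start_frame` and `end_frame`).
#' @return Numeric vector of length 101.
#' @export
normalize_cycle <- function(series, cycle) {
  s <- cycle$start_frame; e <- cycle$end_frame
  if (is.null(s) || is.null(e) || e - s < 1L)
    stop("cycle must span at least 2 frames")
  if (e > length(series) || s < 1L) stop("cycle outside the series extent")
  frames <- s:e
  v <- series[frames]
  ok <- is.finite(v)
  if (mean(!ok) > MAX_MISSING_FRAC || sum(ok) < 2L)
    return(rep(NA_real_, 101L))
  stats::approx(frames[ok], v[ok], xout = seq(s, e, length.out = 101L),
                rule = 2)$y
}

#' Per-cycle 101-point curves for all 18 joint angles
#'
#' @param angles Matrix from [compute_joint_angles()].
#' @param cycles A `gait_cycles` object.
#' @return Numeric array `101 x 18 x n_cycles` (percent x angle x cycle).
#' @export
cycle_curves <- function(angles, cycles) {
  stopifnot(inherits(cycles, "gait_cycles"))
  out <- array(NA_real_, c(101L, ncol(angles), length(cycles)),
               dimnames = list(NULL, colnames(angles), NULL))
  for (k in seq_along(cycles))
    for (j in seq_len(ncol(angles)))
      out[, j, k] <- normalize_cycle(angles[, j], cycles[[k]])
  out
}

#' Pointwise mean curve with 95% band
#'
#' The default band is the pointwise 95% confidence interval of the mean,
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.  A prediction-style band
#' (`mean +/- 1.96 sd`) describing cycle-to-cycle spread is available via
#' `type = "prediction"`.
#'
#' @param curves Matrix of curves, one row per cycle, 101 columns (a
#'   `101 x n` matrix is transposed automatically).
#' @param type `"ci"` (default) or `"prediction"`.
#' @param level Band coverage (default 0.95).
#' @return List with `mean`, `lower`, `upper` (each length 101) and
#'   `n_cycles`.
#' @export
mean_band <- function(curves, type = c("ci", "prediction"), level = 0.95) {
  type <- match.arg(type)
  if (is.matrix(curves) && nrow(curves) == 101L && ncol(curves) != 101L)
    curves <- t(curves)
  if (!is.matrix(curves) || ncol(curves) != 101L)
    stop("curves must be an n x 101 matrix")
  curves <- curves[stats::complete.cases(curves), , drop = FALSE]
  n <- nrow(curves)
  if (n < 2L) stop("need at least 2 complete curves")
  m <- colMeans(curves)
  s <- apply(curves, 2, stats::sd)
  half <- switch(type,
                 ci = stats::qt(1 - (1 - level) / 2, n - 1L) * s / sqrt(n),
                 prediction = stats::qnorm(1 - (1 - level) / 2) * s)
  list(mean = m, lower = m - half, upper = m + half, n_cycles = n)
}

#' Range of motion of an angle over one cycle
#'
#' @param series Per-frame angle series (degrees).
#' @param cycle A cycle (as in [normalize_cycle()]).
#' @return `max - min` of the angle within the cycle, in degrees (`NA` if
#'   the cycle's data are missing beyond the gap policy).
#' @export
rom <- function(series, cycle) {
  v <- series[cycle$start_frame:cycle$end_frame]
  ok <- is.finite(v)
  if (mean(!ok) > MAX_MISSING_FRAC || sum(ok) < 2L) return(NA_real_)
  max(v[ok]) - min(v[ok])
}

#' Sagittal paw-path trace over one cycle
#'
#' The (x, z) positions of the limb's distal (5th) marker across the
#' cycle -- the standard visualization of the cyclic forward movement.
#'
#' @param rec A [trial_recording()].
#' @param limb `"FR"`, `"FL"`, `"BR"` or `"BL"`.
#' @param cycle A cycle (as in [normalize_cycle()]).
#' @return Data frame with columns `x` and `z` (mm), one row per frame of
#'   the cycle.
#' @export
paw_path <- function(rec, limb, cycle) {
  limb <- match.arg(limb, LIMBS)
  frames <- cycle$start_frame:cycle$end_frame
  m <- paste0(limb, PAW_IDX)
  data.frame(x = marker_series(rec, m, "x", frames),
             z = marker_series(rec, m, "z", frames))
}
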