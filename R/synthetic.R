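# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# cubic smoothstep: 0 -> 1 with zero slope at both ends
smoothstep <- function(s) 3 * s^2 - 2 * s^3

# per-limb phase offsets (fraction of stride; order FR, FL, BR, BL) and
# default duty factors of the supported footfall patterns
GAIT_PRESETS <- list(
  walk = list(offsets = c(FR = 0, FL = 0.5, BR = 0.75, BL = 0.25),
              duty = 0.65),
  amble = list(offsets = c(FR = 0, FL = 0.5, BR = 0.75, BL = 0.25),
               duty = 0.58),
  pace = list(offsets = c(FR = 0, FL = 0.5, BR = 0, BL = 0.5),
              duty = 0.55),
  trot = list(offsets = c(FR = 0, FL = 0.5, BR = 0.5, BL = 0),
              duty = 0.5)
)

#' Gait specification for the simulator
#'
#' Defines a steady treadmill gait: footfall pattern (which fixes the
#' per-limb phase offsets), stride time, duty factor (stance fraction of
#' the stride), belt speed, swing step height, walking base, body
#' geometry, marker noise and seed.  The defaults emulate a medium dog
#' ambling on a treadmill at 0.92 m/s, recorded at 120 Hz over 25 gait
#' cycles with sub-millimetre marker noise.  On a treadmill at steady
#' state the stride length is not free: it equals belt speed x stride
#' time, and is reported in the ground truth.
#'
#' @param pattern `"walk"`, `"amble"`, `"pace"` or `"trot"`.  Walk and
#'   amble share the lateral-sequence phase offsets (amble with a lower
#'   duty factor); pace has ipsilateral limbs in phase, trot diagonal
#'   limbs.
#' @param stride_time Stride duration in s.
#' @param duty_factor Stance fraction of the stride, in (0, 1); scalar or
#'   one value per limb (FR, FL, BR, BL).  `NULL` = pattern preset.
#' @param belt_speed Belt speed in m/s.
#' @param step_height Vertical paw lift during swing, mm.
#' @param walking_base Mediolateral separation of left and right paws, mm.
#' @param n_cycles Number of gait cycles to cover.
#' @param frame_rate Sampling frequency, Hz.
#' @param noise_sd White Gaussian marker noise SD per coordinate, mm.
#' @param seed RNG seed for the noise (reproducible).
#' @param flexion_amp Swing-phase distal-joint flexion amplitude, degrees.
#' @param spine_lateral_amp,spine_vertical_amp Spinal marker oscillation
#'   amplitudes, mm (0 = rigid, flat spine).
#' @param body Named list overriding body geometry defaults (mm):
#'   `girdle_height_front/back`, `girdle_x_front/back`,
#'   `segment_front/back` (two-segment leg lengths), `foot_len`,
#'   `paw_z0`.
#' @return A `gait_spec` object.
#' @export
gait_spec <- function(pattern = c("amble", "walk", "pace", "trot"),
                      stride_time = 0.8, duty_factor = NULL,
                      belt_speed = 0.92, step_height = 35,
                      walking_base = 80, n_cycles = 25, frame_rate = 120,
                      noise_sd = 0.5, seed = 1L, flexion_amp = 25,
                      spine_lateral_amp = 8, spine_vertical_amp = 4,
                      body = list()) {
  pattern <- match.arg(pattern)
  preset <- GAIT_PRESETS[[pattern]]
  if (is.null(duty_factor)) duty_factor <- preset$duty
  if (length(duty_factor) == 1L)
    duty_factor <- stats::setNames(rep(duty_factor, 4), LIMBS)
  stopifnot(all(duty_factor > 0 & duty_factor < 1),
            stride_time > 0, belt_speed > 0, step_height >= 0,
            walking_base > 0, n_cycles >= 2, frame_rate > 0,
            noise_sd >= 0)
  geom <- utils::modifyList(list(
    girdle_height_front = 380, girdle_height_back = 400,
    girdle_x_front = 250, girdle_x_back = -250,
    segment_front = c(260, 260), segment_back = c(270, 270),
    foot_len = 55, paw_z0 = 15), body)
  structure(list(pattern = pattern, offsets = preset$offsets,
                 stride_time = stride_time, duty_factor = duty_factor,
                 belt_speed = belt_speed, step_height = step_height,
                 walking_base = walking_base,
                 stride_length = belt_speed * stride_time,
                 n_cycles = n_cycles, frame_rate = frame_rate,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 flexion_amp = flexion_amp,
                 spine_lateral_amp = spine_lateral_amp,
                 spine_vertical_amp = spine_vertical_amp,
                 body = geom),
            class = "gait_spec")
}

# Paw trajectory of one limb: stance carried caudally by the belt, swing
# returning the paw cranially with a half-sine lift.
paw_traj <- function(phase, duty, R, x0, z0, H) {
  stance <- phase < duty
  x <- z <- numeric(length(phase))
  s <- phase[stance] / duty
  x[stance] <- x0 + R * (0.5 - s)
  z[stance] <- z0
  s <- (phase[!stance] - duty) / (1 - duty)
  x[!stance] <- x0 + R * (smoothstep(s) - 0.5)
  z[!stance] <- z0 + H * sin(pi * s)
  list(x = x, z = z, stance = stance)
}

# Two-link planar inverse kinematics in the x-z plane: joint position
# between a fixed proximal point G and distal point W, with segment
# lengths L1, L2 and bend direction `bend` (+1/-1).
two_link_joint <- function(gx, gz, wx, wz, L1, L2, bend) {
  dx <- wx - gx; dz <- wz - gz
  d <- sqrt(dx^2 + dz^2)
  if (any(d > L1 + L2 - 1e-6))
    stop("infeasible geometry: required limb reach ",
         sprintf("%.0f", max(d)), " mm exceeds leg length ", L1 + L2,
         " mm (stride too long for this body)")
  gamma <- acos(pmin(1, pmax(-1, (L1^2 + d^2 - L2^2) / (2 * L1 * d))))
  ux <- dx / d; uz <- dz / d
  th <- bend * gamma
  list(x = gx + L1 * (ux * cos(th) - uz * sin(th)),
       z = gz + L1 * (ux * sin(th) + uz * cos(th)))
}

#' Simulate a treadmill gait trial
#'
#' Generates a [trial_recording()] of the canonical 25-marker set for a
#' steady treadmill gait, with complete ground truth for every downstream
#' quantity.  Paw markers follow a stance phase carried caudally at belt
#' speed and a cubic-smoothstep swing return with a half-sine vertical
#' lift; intermediate limb markers are placed by two-segment leg inverse
#' kinematics (so joint-angle curves arise from a consistent geometry);
#' girdle and spinal markers oscillate weakly at stride frequency;
#' i.i.d. Gaussian noise of `noise_sd` mm is added to every coordinate.
#' Identical specs (including seed) yield bit-identical recordings.
#'
#' @param spec A [gait_spec()].
#' @param condition Condition label stored on the recording.
#' @return List with `recording` (a `trial_recording`) and `truth` (a
#'   `gait_truth` list: per-limb contact on/offset times and frames, the
#'   true value of each of the 35 spatio-temporal parameters, and the true
#'   18 joint ranges of motion).
#' @export
simulate_gait_trial <- function(spec, condition = "reference") {
  stopifnot(inherits(spec, "gait_spec"))
  period <- spec$stride_time; fr <- spec$frame_rate
  n <- ceiling((spec$n_cycles + 1.5) * period * fr)
  t0 <- 0.31 * period  # start mid-phase so the first events are interior
  t <- t0 + (seq_len(n) - 1L) / fr
  g <- spec$body
  markers <- canonical_markers()
  pos <- array(NA_real_, c(n, 3, length(markers)),
               dimnames = list(NULL, c("x", "y", "z"), markers))

  for (limb in LIMBS) {
    front <- substr(limb, 1, 1) == "F"
    side <- if (substr(limb, 2, 2) == "R") -1 else 1  # y is left-positive
    y <- side * spec$walking_base / 2
    gx <- if (front) g$girdle_x_front else g$girdle_x_back
    gz <- if (front) g$girdle_height_front else g$girdle_height_back
    seg <- if (front) g$segment_front else g$segment_back
    duty <- spec$duty_factor[[limb]]
    off <- spec$offsets[[limb]]
    phase <- (t / period - off) %% 1
    R <- spec$belt_speed * 1000 * duty * period
    paw <- paw_traj(phase, duty, R, gx + 20, g$paw_z0, spec$step_height)
    # girdle joint with small fore-aft and vertical oscillation
    Gx <- gx + 6 * sin(2 * pi * (t / period - off))
    Gz <- gz + 4 * sin(4 * pi * (t / period - off))
    # distal foot marker (4) above the paw, flexing during swing
    beta <- numeric(n)
    sw <- !paw$stance
    beta[sw] <- spec$flexion_amp * pi / 180 *
      sin(pi * ((phase[sw] - duty) / (1 - duty)))
    Wx <- paw$x - g$foot_len * sin(beta)
    Wz <- paw$z + g$foot_len * cos(beta)
    elbow <- two_link_joint(Gx, Gz, Wx, Wz, seg[1], seg[2],
                            bend = if (front) -1 else 1)
    # proximal marker (1): scapular spine / iliac crest
    off1 <- if (front) c(-40, 70) else c(30, 80)
    P1x <- Gx + off1[1] + 10 * sin(2 * pi * (t / period - off))
    P1z <- Gz + off1[2]
    coords <- list(cbind(P1x, y, P1z), cbind(Gx, y, Gz),
                   cbind(elbow$x, y, elbow$z), cbind(Wx, y, Wz),
                   cbind(paw$x, y, paw$z))
    for (i in 1:5) pos[, , paste0(limb, i)] <- coords[[i]]
  }

  spine_base <- list(S1 = c(480, 470), T1 = c(350, 450), T13 = c(0, 435),
                     L7 = c(-250, 425), S5 = c(-330, 415))
  for (m in names(spine_base)) {
    b <- spine_base[[m]]
    wavephase <- b[1] / 800  # travelling lateral wave along the trunk
    pos[, , m] <- cbind(b[1],
                        spec$spine_lateral_amp *
                          sin(2 * pi * (t / period - wavephase)),
                        b[2] + spec$spine_vertical_amp *
                          sin(4 * pi * t / period))
  }

  truth <- gait_truth(spec, t, fr)
  # true joint ROMs from the noise-free geometry over one representative
  # cycle (steady gait: all cycles are identical before noise)
  win <- truth$cycle_frames[1]:truth$cycle_frames[2]
  clean <- trial_recording(pos[win, , , drop = FALSE], fr,
                           belt_speed = spec$belt_speed,
                           condition = condition)
  angles <- compute_joint_angles(clean)
  cyc <- list(start_frame = 1L, end_frame = length(win))
  truth$rom <- vapply(joint_angle_names(), function(j)
    rom(angles[, j], cyc), numeric(1))
  names(truth$rom) <- paste0("rom_", joint_angle_names())

  if (spec$noise_sd > 0)
    pos <- with_seed(spec$seed,
                     pos + stats::rnorm(length(pos), 0, spec$noise_sd))
  rec <- trial_recording(pos, fr, belt_speed = spec$belt_speed,
                         condition = condition,
                         subject = list(gait_pattern = spec$pattern))
  list(recording = rec, truth = truth)
}

# Ground-truth events and per-cycle parameter values implied by a spec.
gait_truth <- function(spec, t, fr) {
  period <- spec$stride_time
  t_min <- t[1]; t_max <- t[length(t)]
  events <- lapply(stats::setNames(LIMBS, LIMBS), function(limb) {
    off <- spec$offsets[[limb]]; duty <- spec$duty_factor[[limb]]
    k <- seq(floor(t_min / period) - 1, ceiling(t_max / period) + 1)
    hs <- (k + off) * period
    hs <- hs[hs >= t_min & hs <= t_max]
    to <- hs + duty * period
    list(heel_strike_times = hs, toe_off_times = to[to <= t_max],
         heel_strike_frames = round((hs - t_min) * fr) + 1L)
  })
  br <- events$BR$heel_strike_frames
  contra <- c(FR = "FL", FL = "FR", BR = "BL", BL = "BR")
  params <- c(
    stride_time = period, cadence = 240 / period, speed = spec$belt_speed,
    stride_distance_front = spec$belt_speed * period,
    stride_distance_back = spec$belt_speed * period,
    walking_base_front = spec$walking_base,
    walking_base_back = spec$walking_base)
  for (limb in LIMBS) {
    duty <- spec$duty_factor[[limb]]
    dphi <- (spec$offsets[[limb]] - spec$offsets[[contra[[limb]]]]) %% 1
    params[paste0("step_distance_", limb)] <- spec$belt_speed * dphi * period
    params[paste0("step_height_", limb)] <- spec$step_height
    params[paste0("swing_time_", limb)] <- (1 - duty) * period
    params[paste0("swing_ratio_", limb)] <- 100 * (1 - duty)
    params[paste0("stance_time_", limb)] <- duty * period
    params[paste0("stance_ratio_", limb)] <- 100 * duty
    params[paste0("paw_travel_distance_", limb)] <-
      spec$belt_speed * duty * period
  }
  structure(list(events = events, parameters = params,
                 n_cycles = as.integer(spec$n_cycles),
                 stride_length = spec$stride_length,
                 cycle_frames = br[c(1, 2)]),
            class = "gait_truth")
}
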