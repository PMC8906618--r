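#' The 53-parameter registry
#'
#' Names of the scalar parameters computed for every gait cycle: 35
#' spatio-temporal parameters (stride time, cadence, speed, front/back
#' stride distance, front/back walking base, and per limb step distance,
#' step height, swing time/ratio, stance time/ratio, paw travel distance)
#' plus the 18 joint-angle ranges of motion.
#'
#' @return Character vector of the 53 parameter names.  Attributes
#'   `"spatiotemporal"` and `"rom"` hold the two sub-registries.
#' @export
parameter_registry <- function() {
  st <- c("stride_time", "cadence", "speed",
          "stride_distance_front", "stride_distance_back",
          "walking_base_front", "walking_base_back",
          unlist(lapply(LIMBS, function(l)
            paste0(c("step_distance", "step_height", "swing_time",
                     "swing_ratio", "stance_time", "stance_ratio",
                     "paw_travel_distance"), "_", l))))
  romn <- paste0("rom_", joint_angle_names())
  structure(c(st, romn), spatiotemporal = st, rom = romn)
}

#' Cadence from stride time
#'
#' Steps per minute for a quadruped: `4 * 60 / stride_time` (four steps per
#' stride).
#'
#' @param stride_time Stride (cycle) time in seconds, > 0.
#' @return Cadence in steps/min.
#' @export
cadence <- function(stride_time) {
  if (any(!is.finite(stride_time) | stride_time <= 0))
    stop("stride_time must be positive")
  4 * 60 / stride_time
}

#' Stride time of a cycle
#'
#' @param cycle One element of a `gait_cycles` object.
#' @param frame_rate Sampling frequency in Hz.
#' @return Cycle duration `(end_frame - start_frame) / frame_rate` in s.
#' @export
stride_time <- function(cycle, frame_rate) {
  if (cycle$end_frame <= cycle$start_frame)
    stop("cycle end must lie after its start")
  (cycle$end_frame - cycle$start_frame) / frame_rate
}

# Gap-filled paw trajectories per limb; NULL where the marker violates the
# missing-data policy.
paw_trajectories <- function(rec) {
  lapply(stats::setNames(LIMBS, LIMBS), function(l)
    tryCatch(marker_xyz(rec, paste0(l, PAW_IDX)), error = function(e) NULL))
}

# Single in-cycle event of a limb, or NA if not exactly one.
one_event <- function(v) if (length(v) == 1L) v else NA_integer_

# Next heel strike / toe-off of the limb strictly after frame h (full
# event list).
next_hs <- function(events, limb, h) {
  later <- events[[limb]]$heel_strikes
  later <- later[later > h]
  if (length(later)) later[1] else NA_integer_
}

next_to <- function(events, limb, h) {
  later <- events[[limb]]$toe_offs
  later <- later[later > h]
  if (length(later)) later[1] else NA_integer_
}

# Latest contralateral heel strike at or before frame h.
prev_contra_hs <- function(events, limb, h) {
  contra <- c(FR = "FL", FL = "FR", BR = "BL", BL = "BR")[[limb]]
  earlier <- events[[contra]]$heel_strikes
  earlier <- earlier[earlier <= h]
  if (length(earlier)) earlier[length(earlier)] else NA_integer_
}

#' Compute the 53 scalar parameters of one gait cycle
#'
#' All distance parameters are belt-compensated: over-ground-equivalent
#' distance = laboratory-frame fore-aft displacement + belt speed x elapsed
#' time, since on a treadmill the animal is quasi-stationary while the belt
#' travels under it.  Swing and stance are computed as signed durations
#' from the detected events; negative values (out-of-order events) are
#' preserved and flagged anomalous, never clamped.  Swing/stance ratios are
#' relative to the limb's own heel-strike-to-heel-strike interval, so
#' `swing + stance = stride` and `swing_ratio + stance_ratio = 100` hold
#' exactly whenever the cycle is unflagged.
#'
#' @param rec A (filtered) [trial_recording()].
#' @param cycle One element of a `gait_cycles` object.
#' @param events The full `gait_events` of the recording (events beyond the
#'   cycle end are needed for the next ipsilateral heel strike).
#' @param belt_speed Belt speed in m/s (defaults to the recording's).
#' @param angles Optional precomputed [compute_joint_angles()] matrix.
#' @param paws Optional precomputed `paw_trajectories()` (internal reuse).
#' @return List with `values` (named numeric, the 53 parameters), `flags`
#'   (character vector of anomaly flags) and `anomaly` (logical).
#' @export
compute_cycle_parameters <- function(rec, cycle, events,
                                     belt_speed = rec$belt_speed,
                                     angles = NULL, paws = NULL) {
  fr <- rec$frame_rate
  if (is.null(angles)) angles <- compute_joint_angles(rec)
  if (is.null(paws)) paws <- paw_trajectories(rec)
  reg <- parameter_registry()
  vals <- stats::setNames(rep(NA_real_, length(reg)), reg)
  flags <- character(0)
  win <- cycle$start_frame:cycle$end_frame

  st <- stride_time(cycle, fr)
  vals["stride_time"] <- st
  vals["cadence"] <- cadence(st)

  # per-limb stride distance (belt-compensated), averaged left/right
  limb_stride_dist <- function(limb) {
    h <- one_event(cycle$events[[limb]]$heel_strikes)
    if (is.na(h)) return(NA_real_)
    h2 <- next_hs(events, limb, h)
    p <- paws[[limb]]
    if (is.na(h2) || is.null(p)) return(NA_real_)
    (p[h2, "x"] - p[h, "x"]) / 1000 + belt_speed * (h2 - h) / fr
  }
  sd_pair <- function(l1, l2) {
    d <- c(limb_stride_dist(l1), limb_stride_dist(l2))
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }
  vals["stride_distance_front"] <- sd_pair("FR", "FL")
  vals["stride_distance_back"] <- sd_pair("BR", "BL")
  vals["speed"] <- (vals[["stride_distance_front"]] +
                      vals[["stride_distance_back"]]) / 2 / st

  # walking base: mediolateral paw separation at the heel strikes
  wb <- function(l_left, l_right) {
    hl <- one_event(cycle$events[[l_left]]$heel_strikes)
    hr <- one_event(cycle$events[[l_right]]$heel_strikes)
    pl <- paws[[l_left]]; pr <- paws[[l_right]]
    if (is.na(hl) || is.na(hr) || is.null(pl) || is.null(pr))
      return(NA_real_)
    abs(pl[hl, "y"] - pr[hr, "y"])
  }
  vals["walking_base_front"] <- wb("FL", "FR")
  vals["walking_base_back"] <- wb("BL", "BR")

  for (limb in LIMBS) {
    p <- paws[[limb]]
    h <- one_event(cycle$events[[limb]]$heel_strikes)

    # step distance from the preceding contralateral heel strike
    if (!is.na(h) && !is.null(p)) {
      pc <- prev_contra_hs(events, limb, h)
      contra <- c(FR = "FL", FL = "FR", BR = "BL", BL = "BR")[[limb]]
      pcp <- paws[[contra]]
      if (!is.na(pc) && !is.null(pcp))
        vals[paste0("step_distance_", limb)] <-
          (p[h, "x"] - pcp[pc, "x"]) / 1000 + belt_speed * (h - pc) / fr
    }

    if (!is.null(p)) {
      z <- p[win, "z"]
      vals[paste0("step_height_", limb)] <- max(z) - min(z)
      x <- p[win, "x"]
      vals[paste0("paw_travel_distance_", limb)] <- (max(x) - min(x)) / 1000
    }

    # timing: stance runs from the limb's heel strike to its following
    # toe-off, swing from that toe-off to the limb's next heel strike.
    # If the next heel strike arrives early -- before the toe-off, the
    # out-of-order case seen on irregular gaits -- swing comes out
    # negative; it is preserved and flagged, never clamped.
    if (!is.na(h)) {
      h2 <- next_hs(events, limb, h)
      to_next <- next_to(events, limb, h)
      if (!is.na(h2) && !is.na(to_next)) {
        limb_stride <- (h2 - h) / fr
        stance <- (to_next - h) / fr
        swing <- (h2 - to_next) / fr
        vals[paste0("stance_time_", limb)] <- stance
        vals[paste0("swing_time_", limb)] <- swing
        vals[paste0("stance_ratio_", limb)] <- 100 * stance / limb_stride
        vals[paste0("swing_ratio_", limb)] <- 100 * swing / limb_stride
        if (stance < 0 || swing < 0)
          flags <- c(flags, paste0("negative_swing_stance_", limb))
      }
    }
  }

  # ranges of motion
  for (nm in joint_angle_names())
    vals[paste0("rom_", nm)] <- rom(angles[, nm], cycle)

  if (!cycle$complete) flags <- c(flags, "incomplete_events")
  list(values = vals, flags = flags, anomaly = length(flags) > 0L)
}

#' Per-cycle parameter table of a recording
#'
#' Runs [compute_cycle_parameters()] for every segmented cycle and
#' assembles the tabular result: one row per cycle with cycle metadata,
#' anomaly flags and the 53 named scalar columns.
#'
#' @param rec A (filtered) [trial_recording()].
#' @param cycles A `gait_cycles` object.
#' @param events The full `gait_events` of the recording.
#' @param belt_speed Belt speed in m/s.
#' @param angles Optional precomputed angle matrix.
#' @return Data frame with columns `cycle`, `start_frame`, `end_frame`,
#'   `condition`, `anomaly`, `flags`, then the 53 parameters.
#' @export
cycle_parameter_table <- function(rec, cycles, events,
                                  belt_speed = rec$belt_speed,
                                  angles = NULL) {
  stopifnot(inherits(cycles, "gait_cycles"))
  if (is.null(angles)) angles <- compute_joint_angles(rec)
  paws <- paw_trajectories(rec)
  rows <- lapply(seq_along(cycles), function(k) {
    cp <- compute_cycle_parameters(rec, cycles[[k]], events, belt_speed,
                                   angles, paws)
    data.frame(cycle = k, start_frame = cycles[[k]]$start_frame,
               end_frame = cycles[[k]]$end_frame,
               condition = rec$condition,
               anomaly = cp$anomaly,
               flags = paste(cp$flags, collapse = ";"),
               t(cp$values), check.names = FALSE)
  })
  do.call(rbind, rows)
}
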