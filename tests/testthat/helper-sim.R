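# Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# A short default amble trial (8 cycles) plus its processed analysis.
cached_sim <- function(key = "default", ...) {
  if (is.null(.fixture_cache[[key]])) {
    spec <- gait_spec(n_cycles = 8, ...)
    out <- simulate_gait_trial(spec)
    out$spec <- spec
    .fixture_cache[[key]] <- out
  }
  .fixture_cache[[key]]
}

cached_analysis <- function(key = "default", ...) {
  akey <- paste0(key, "_analysis")
  if (is.null(.fixture_cache[[akey]]))
    .fixture_cache[[akey]] <- process_trial(cached_sim(key, ...)$recording)
  .fixture_cache[[akey]]
}

# A static recording: every marker constant over `n` frames, posed as a
# standing dog with straight vertical legs (limb markers 2..5 collinear).
static_recording <- function(n = 12, frame_rate = 120, belt_speed = 0.9) {
  markers <- canonical_markers()
  pos <- array(NA_real_, c(n, 3, length(markers)),
               dimnames = list(NULL, c("x", "y", "z"), markers))
  put <- function(m, x, y, z) pos[, , m] <<- rep(c(x, y, z), each = n)
  for (limb in c("FR", "FL", "BR", "BL")) {
    front <- substr(limb, 1, 1) == "F"
    y <- if (substr(limb, 2, 2) == "R") -40 else 40
    x <- if (front) 250 else -250
    z5 <- c(380, 290, 200, 110, 20)  # straight vertical leg
    put(paste0(limb, 1), x - 40, y, 450)
    for (i in 2:5) put(paste0(limb, i), x, y, z5[i])
  }
  put("S1", 480, 0, 470); put("T1", 350, 0, 450); put("T13", 0, 0, 435)
  put("L7", -250, 0, 425); put("S5", -330, 0, 415)
  trial_recording(pos, frame_rate, belt_speed = belt_speed)
}

# Hand-built gait_events / gait_cycles for timing arithmetic tests.
# `hs`/`to` are named lists of frame-index vectors per limb.
manual_events <- function(hs, to, frame_rate = 120) {
  ev <- lapply(stats::setNames(c("FR", "FL", "BR", "BL"),
                               c("FR", "FL", "BR", "BL")), function(l)
    list(heel_strikes = as.integer(hs[[l]]), toe_offs = as.integer(to[[l]])))
  structure(ev, frame_rate = frame_rate, class = "gait_events")
}
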