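test_that("the registry holds exactly 35 spatio-temporal + 18 ROM = 53 names", {
  reg <- parameter_registry()
  expect_length(reg, 53L)
  expect_length(attr(reg, "spatiotemporal"), 35L)
  expect_length(attr(reg, "rom"), 18L)
  expect_false(anyDuplicated(reg) > 0)
  expect_identical(attr(reg, "rom"), paste0("rom_", joint_angle_names()))
})

test_that("stride time and cadence follow their definitions", {
  cyc <- list(start_frame = 1L, end_frame = 97L)
  expect_equal(stride_time(cyc, 120), 0.8)
  expect_error(stride_time(list(start_frame = 10L, end_frame = 10L), 120),
               "after its start")
  expect_equal(cadence(1.0), 240)
  expect_equal(cadence(0.8), 300)
  expect_error(cadence(0), "positive")
})

test_that("timing arithmetic: stance to toe-off, swing to next heel strike", {
  rec <- static_recording(n = 250)
  # HS at frame 1, TO at 0.3 s (frame 37), next HS at 0.8 s (frame 97)
  hs <- list(FR = c(1L, 97L), FL = 49L, BR = c(1L, 97L), BL = 49L)
  to <- list(FR = 37L, FL = 85L, BR = 37L, BL = 85L)
  ev <- manual_events(hs, to)
  cyc <- segment_cycles(ev, 120)[[1]]
  cp <- compute_cycle_parameters(rec, cyc, ev, belt_speed = 0.9)
  v <- cp$values
  expect_equal(v[["stance_time_FR"]], 0.3)
  expect_equal(v[["swing_time_FR"]], 0.5)
  expect_equal(v[["stance_ratio_FR"]], 37.5)
  expect_equal(v[["swing_ratio_FR"]], 62.5)
  expect_false("negative_swing_stance_FR" %in% cp$flags)
  # stationary-in-lab paw, belt 0.9 m/s, stride 0.8 s -> 0.72 m
  expect_equal(v[["stride_distance_front"]], 0.9 * 0.8)
  expect_equal(v[["speed"]], 0.9)
  # static paws: walking base is the configured 80 mm separation
  expect_equal(v[["walking_base_front"]], 80)
  expect_equal(v[["walking_base_back"]], 80)
  expect_equal(v[["step_height_FL"]], 0)
  expect_equal(v[["paw_travel_distance_BR"]], 0)
  # zero time offset between contralateral heel strikes -> step distance 0
  ev0 <- manual_events(list(FR = c(1L, 97L), FL = c(1L, 97L),
                            BR = c(1L, 97L), BL = c(1L, 97L)), to)
  cyc0 <- segment_cycles(ev0, 120)[[1]]
  v0 <- compute_cycle_parameters(rec, cyc0, ev0, belt_speed = 0.9)$values
  expect_equal(v0[["step_distance_FR"]], 0)
})

test_that("out-of-order events give negative, flagged, never clamped swing", {
  rec <- static_recording(n = 250)
  # FR's next heel strike (frame 65) arrives before its toe-off (frame 70)
  hs <- list(FR = c(30L, 65L), FL = 20L, BR = c(1L, 60L), BL = 20L)
  to <- list(FR = 70L, FL = 40L, BR = 35L, BL = 40L)
  ev <- manual_events(hs, to)
  cyc <- segment_cycles(ev, 120)[[1]]
  cp <- compute_cycle_parameters(rec, cyc, ev, belt_speed = 0.9)
  expect_lt(cp$values[["swing_time_FR"]], 0)
  expect_true(any(grepl("negative_swing_stance_FR", cp$flags)))
  expect_true(cp$anomaly)
  # identities hold even for the flagged limb
  limb_stride <- (65 - 30) / 120
  expect_equal(cp$values[["swing_time_FR"]] + cp$values[["stance_time_FR"]],
               limb_stride)
  expect_equal(cp$values[["swing_ratio_FR"]] + cp$values[["stance_ratio_FR"]],
               100)
})

test_that("swing + stance = stride and ratios sum to 100 over random event sets", {
  rec <- static_recording(n = 2000)
  set.seed(123)
  for (i in 1:20) {
    start <- sample(1:200, 1)
    stride <- sample(60:140, 1)
    mk <- function() {
      h1 <- start + sample(0:30, 1)
      list(h = c(h1, h1 + stride), t = h1 + sample(-20:50, 1))
    }
    limbs <- replicate(4, mk(), simplify = FALSE)
    names(limbs) <- c("FR", "FL", "BR", "BL")
    limbs$BR$h <- c(start, start + stride)
    ev <- manual_events(lapply(limbs, function(l) sort(unique(l$h))),
                        lapply(limbs, `[[`, "t"))
    cyc <- segment_cycles(ev, 120)[[1]]
    cp <- compute_cycle_parameters(rec, cyc, ev, belt_speed = 1)
    for (l in c("FR", "FL", "BR", "BL")) {
      sw <- cp$values[[paste0("swing_time_", l)]]
      stn <- cp$values[[paste0("stance_time_", l)]]
      if (is.na(sw)) next
      h1 <- sort(unique(limbs[[l]]$h))
      expect_equal(sw + stn, diff(h1[1:2]) / 120, tolerance = 1e-12)
      expect_equal(cp$values[[paste0("swing_ratio_", l)]] +
                     cp$values[[paste0("stance_ratio_", l)]], 100,
                   tolerance = 1e-9)
      if (!cp$anomaly) expect_gte(min(sw, stn), 0)
    }
  }
})

test_that("simulated steady gait recovers the configured parameters", {
  sim <- cached_sim()
  an <- cached_analysis()
  p <- an$parameters
  tv <- sim$truth$parameters
  fr <- sim$recording$frame_rate
  expect_lt(abs(mean(p$stride_time) - tv[["stride_time"]]), 1 / fr)
  expect_equal(mean(p$cadence), 240 / mean(p$stride_time), tolerance = 1e-9)
  expect_lt(abs(mean(p$speed) - tv[["speed"]]) / tv[["speed"]], 0.02)
  noise_tol <- 2 * sim$spec$noise_sd + 1
  for (l in c("FR", "FL", "BR", "BL")) {
    expect_lt(abs(mean(p[[paste0("stance_ratio_", l)]]) -
                    tv[[paste0("stance_ratio_", l)]]), 3)
    expect_lt(abs(mean(p[[paste0("step_height_", l)]]) -
                    tv[[paste0("step_height_", l)]]), noise_tol)
    expect_lt(abs(mean(p[[paste0("step_distance_", l)]], na.rm = TRUE) -
                    tv[[paste0("step_distance_", l)]]), 0.02)
    expect_lt(abs(mean(p[[paste0("paw_travel_distance_", l)]],
                       na.rm = TRUE) -
                    tv[[paste0("paw_travel_distance_", l)]]), 0.02)
  }
  expect_lt(abs(mean(p$walking_base_front) - tv[["walking_base_front"]]),
            noise_tol)
  expect_lt(abs(mean(p$stride_distance_back) -
                  tv[["stride_distance_back"]]), 0.01)
})

test_that("a dropped toe-off blanks exactly that limb's timing scalars", {
  an <- cached_analysis()
  ev <- an$events
  k <- 4
  cyc <- an$cycles[[k]]
  # remove every FL toe-off after this cycle's FL heel strike
  h <- cyc$events$FL$heel_strikes[1]
  ev$FL$toe_offs <- ev$FL$toe_offs[ev$FL$toe_offs <= h]
  cp <- compute_cycle_parameters(an$recording, cyc, ev)
  for (nm in paste0(c("swing_time_", "swing_ratio_", "stance_time_",
                      "stance_ratio_"), "FL"))
    expect_true(is.na(cp$values[[nm]]))
  for (nm in paste0(c("swing_time_", "stance_time_"), c("FR", "BR")))
    expect_false(is.na(cp$values[[nm]]))
  expect_false(is.na(cp$values[["step_height_FL"]]))
})

test_that("identical cycles give identical parameter records", {
  an <- cached_analysis()
  cp1 <- compute_cycle_parameters(an$recording, an$cycles[[2]], an$events)
  cp2 <- compute_cycle_parameters(an$recording, an$cycles[[2]], an$events)
  expect_identical(cp1, cp2)
})
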