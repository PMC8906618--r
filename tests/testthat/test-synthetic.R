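test_that("simulated recordings have the requested extent and cycle count", {
  sim <- cached_sim()
  spec <- sim$spec
  n_exp <- (spec$n_cycles + 1.5) * spec$stride_time * spec$frame_rate
  expect_equal(n_frames(sim$recording), ceiling(n_exp))
  expect_equal(sim$truth$n_cycles, spec$n_cycles)
  # the recording really contains that many BR-anchored cycles
  expect_gte(length(sim$truth$events$BR$heel_strike_frames) - 1L,
             spec$n_cycles)
  expect_equal(sim$truth$stride_length,
               spec$belt_speed * spec$stride_time)
})

test_that("generation is deterministic in the seed", {
  a <- simulate_gait_trial(gait_spec(n_cycles = 3, seed = 42))
  b <- simulate_gait_trial(gait_spec(n_cycles = 3, seed = 42))
  expect_identical(a$recording$positions, b$recording$positions)
  c_ <- simulate_gait_trial(gait_spec(n_cycles = 3, seed = 43))
  expect_false(identical(a$recording$positions, c_$recording$positions))
  # the global RNG stream is left untouched
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); simulate_gait_trial(gait_spec(n_cycles = 3, seed = 99))
  expect_identical(stats::rnorm(1), before)
})

test_that("a noise-free flat spine yields constant sagittal spinal angles", {
  sim <- simulate_gait_trial(gait_spec(n_cycles = 3, noise_sd = 0,
                                       spine_lateral_amp = 0,
                                       spine_vertical_amp = 0))
  ang <- compute_joint_angles(sim$recording)
  for (j in c("spine_T1_sag", "spine_T13_sag", "spine_L7_sag"))
    expect_lt(diff(range(ang[, j])), 1e-6)
})

test_that("footfall presets reproduce their limb-phase relationships", {
  near <- function(a, b, tol = 1e-9) min(abs(outer(a, b, `-`))) < tol
  pace <- simulate_gait_trial(gait_spec("pace", n_cycles = 3,
                                        noise_sd = 0))$truth$events
  # ipsilateral limbs strike together
  expect_true(all(vapply(pace$FR$heel_strike_times[2:3], function(h)
    near(h, pace$BR$heel_strike_times), logical(1))))
  trot <- simulate_gait_trial(gait_spec("trot", n_cycles = 3,
                                        noise_sd = 0))$truth$events
  # diagonal limbs strike together
  expect_true(all(vapply(trot$FR$heel_strike_times[2:3], function(h)
    near(h, trot$BL$heel_strike_times), logical(1))))
  walk <- simulate_gait_trial(gait_spec("walk", n_cycles = 3,
                                        noise_sd = 0))$truth
  # lateral sequence: BR -> FR -> BL -> FL at quarter-stride spacing
  hs1 <- vapply(walk$events[c("BR", "FR", "BL", "FL")], function(e)
    e$heel_strike_times[e$heel_strike_times > 0.5][1], numeric(1))
  expect_equal(unname(diff(hs1)), rep(0.2, 3), tolerance = 1e-9)
})

test_that("ground truth is internally consistent", {
  sim <- cached_sim()
  tv <- sim$truth$parameters
  spec <- sim$spec
  for (l in c("FR", "FL", "BR", "BL")) {
    expect_equal(tv[[paste0("stance_time_", l)]],
                 spec$duty_factor[[l]] * spec$stride_time)
    expect_equal(tv[[paste0("swing_time_", l)]] +
                   tv[[paste0("stance_time_", l)]], tv[["stride_time"]])
    expect_equal(tv[[paste0("stance_ratio_", l)]] +
                   tv[[paste0("swing_ratio_", l)]], 100)
  }
  expect_equal(tv[["cadence"]], 240 / tv[["stride_time"]])
  expect_equal(tv[["speed"]], spec$belt_speed)
})

test_that("infeasible stride geometry is refused", {
  expect_error(simulate_gait_trial(gait_spec(stride_time = 3, n_cycles = 2)),
               "infeasible geometry")
})

test_that("dropouts mask markers and propagate to missing results", {
  sim <- cached_sim()
  rec <- degrade(sim$recording, "L7")
  expect_false(any(rec$mask[, "L7"]))
  an <- process_trial(rec)
  # every angle built on L7 is missing; the rest survive
  expect_true(all(is.na(an$parameters$rom_spine_L7_hor)))
  expect_true(all(is.na(an$parameters$rom_spine_L7_sag)))
  expect_true(all(is.na(an$parameters$rom_spine_T13_hor)))
  expect_false(anyNA(an$parameters$rom_spine_T1_hor))
  expect_false(anyNA(an$parameters$stride_time))
  # partial dropout below the 20% policy is bridged
  rec2 <- degrade(sim$recording, "FR5", frames = 101:110)
  expect_silent(marker_series(rec2, "FR5", "x"))
  expect_error(degrade(sim$recording, "NOPE"), "unknown marker")
  expect_identical(degrade(sim$recording, "L7", integer(0)),
                   sim$recording)
})
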