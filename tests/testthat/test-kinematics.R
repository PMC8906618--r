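test_that("projected angles reproduce closed-form cases", {
  expect_equal(projected_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               "horizontal"), 180)
  expect_equal(projected_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                               "horizontal"), 90)
  # arccos of normalized dot product: 45 degrees
  expect_equal(projected_angle(c(2, 0, 0), c(0, 0, 0), c(1, 1, 0),
                               "horizontal"), 45)
  # projection matters: y is ignored in the sagittal plane
  expect_equal(projected_angle(c(0, 99, 1), c(0, -5, 0), c(1, 17, 0),
                               "sagittal"), 90)
  expect_error(projected_angle(c(1, 1, 1), c(1, 1, 1), c(2, 0, 0)),
               "degenerate")
})

test_that("projected angles are symmetric, rotation- and scale-invariant", {
  set.seed(42)
  rot2 <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                            sin(th) * p[1] + cos(th) * p[2], p[3])
  for (i in 1:25) {
    a <- c(stats::rnorm(2), 0); apex <- c(stats::rnorm(2), 0)
    b <- c(stats::rnorm(2), 0)
    ang <- projected_angle(a, apex, b, "horizontal")
    expect_equal(projected_angle(b, apex, a, "horizontal"), ang)
    th <- stats::runif(1, 0, 2 * pi); s <- stats::runif(1, 0.1, 10)
    expect_equal(projected_angle(s * rot2(a, th), s * rot2(apex, th),
                                 s * rot2(b, th), "horizontal"),
                 ang, tolerance = 1e-9)
  }
})

test_that("a recording yields 18 angle series; straight legs read 180 degrees", {
  rec <- static_recording()
  ang <- compute_joint_angles(rec)
  expect_identical(dim(ang), c(n_frames(rec), 18L))
  expect_identical(colnames(ang), joint_angle_names())
  for (j in c("elbow_R", "elbow_L", "carpus_R", "carpus_L",
              "stifle_R", "stifle_L", "tarsus_R", "tarsus_L"))
    expect_equal(unname(ang[, j]), rep(180, n_frames(rec)))
  # straight spine: horizontal spinal angles are 180
  expect_equal(unname(ang[, "spine_T13_hor"]), rep(180, n_frames(rec)))
})

test_that("coincident markers propagate as missing values, not errors", {
  rec <- static_recording()
  rec$positions[3, , "FR1"] <- rec$positions[3, , "FR2"]
  ang <- compute_joint_angles(rec)
  expect_true(is.na(ang[3, "shoulder_R"]))
  expect_false(anyNA(ang[-3, "shoulder_R"]))
  expect_false(anyNA(ang[, "elbow_R"]))
})

test_that("prescribed flexion is recovered as range of motion", {
  sim <- cached_sim()
  an <- cached_analysis()
  romdet <- colMeans(an$parameters[, names(sim$truth$rom)], na.rm = TRUE)
  expect_lt(max(abs(romdet - sim$truth$rom)), 2)
  # larger flexion amplitude yields larger distal-joint ROM
  hi <- simulate_gait_trial(gait_spec(n_cycles = 4, flexion_amp = 40,
                                      noise_sd = 0))
  lo <- simulate_gait_trial(gait_spec(n_cycles = 4, flexion_amp = 10,
                                      noise_sd = 0))
  expect_gt(hi$truth$rom[["rom_carpus_R"]], lo$truth$rom[["rom_carpus_R"]])
})

test_that("cycle normalization yields exactly 101 samples with exact endpoints", {
  cyc <- list(start_frame = 11L, end_frame = 107L)
  expect_equal(normalize_cycle(rep(4.2, 120), cyc), rep(4.2, 101L))
  ramp <- seq(0, 119) * 0.5
  expect_equal(normalize_cycle(ramp, cyc),
               seq(ramp[11], ramp[107], length.out = 101))
  # one full period per cycle: first and last sample agree
  s <- sin(2 * pi * (0:119 - 10) / 96)
  curve <- normalize_cycle(s, cyc)
  expect_length(curve, 101L)
  expect_equal(curve[1], curve[101], tolerance = 1e-6)
  expect_equal(curve[1], s[11], tolerance = 1e-9)
  expect_error(normalize_cycle(ramp, list(start_frame = 5L, end_frame = 5L)),
               "at least 2 frames")
  expect_error(normalize_cycle(ramp, list(start_frame = 100L,
                                          end_frame = 130L)), "extent")
})

test_that("every cycle yields 18 curves of 101 samples", {
  an <- cached_analysis()
  expect_identical(dim(an$curves),
                   c(101L, 18L, length(an$cycles)))
  expect_false(anyNA(an$curves))
})

test_that("mean curve bands behave like pointwise confidence intervals", {
  tpl <- sin(2 * pi * (0:100) / 100) * 10 + 120
  same <- rbind(tpl, tpl, tpl)
  mb <- mean_band(same)
  expect_equal(mb$mean, unname(tpl))
  expect_lt(max(mb$upper - mb$lower), 1e-9)
  opp <- rbind(tpl, -tpl)
  expect_equal(mean_band(opp)$mean, rep(0, 101))
  expect_error(mean_band(same[1, , drop = FALSE]), "at least 2")
  # ~95% pointwise coverage of the true mean under Gaussian noise
  set.seed(7)
  hits <- replicate(300, {
    cs <- matrix(rep(tpl, each = 12) + stats::rnorm(12 * 101, 0, 3),
                 12, 101)
    mb <- mean_band(cs)
    mean(tpl >= mb$lower & tpl <= mb$upper)
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
  # invariant: lower <= mean <= upper pointwise
  expect_true(all(mb$lower <= mb$mean & mb$mean <= mb$upper))
})

test_that("range of motion matches closed forms and the normalized curves", {
  cyc <- list(start_frame = 1L, end_frame = 120L)
  expect_equal(rom(rep(3, 150), cyc), 0)
  s <- 7 * sin(2 * pi * (0:149) / 60)
  expect_equal(rom(s, cyc), 14, tolerance = 1e-3)
  an <- cached_analysis()
  k <- 3
  for (j in c("stifle_R", "spine_T1_hor")) {
    curve_rom <- max(an$curves[, j, k]) - min(an$curves[, j, k])
    expect_equal(rom(an$angles[, j], an$cycles[[k]]), curve_rom,
                 tolerance = 0.15)
  }
})

test_that("paw paths trace the swing loop", {
  rec <- static_recording(n = 50)
  cyc <- list(start_frame = 1L, end_frame = 50L)
  pp <- paw_path(rec, "FR", cyc)
  expect_identical(nrow(pp), 50L)
  expect_equal(diff(range(pp$x)), 0)
  expect_equal(diff(range(pp$z)), 0)
  sim <- cached_sim()
  an <- cached_analysis()
  pp <- paw_path(an$recording, "BL", an$cycles[[3]])
  expect_equal(diff(range(pp$z)), sim$spec$step_height, tolerance = 2)
  expect_error(paw_path(degrade(an$recording, "BL5"), "BL",
                        an$cycles[[3]]), "missing")
})
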