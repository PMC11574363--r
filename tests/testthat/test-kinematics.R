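test_that("sagittal angles follow the clinical conventions", {
  n <- 3
  pt <- function(x, z) cbind(rep(x, n), 0, rep(z, n))
  # straight leg: collinear hip-knee-ankle
  expect_equal(sagittal_angle(pt(0, 1), pt(0, 0.55), pt(0, 0.1), "knee"),
               rep(0, n), tolerance = 1e-12)
  # shank rotated 30 degrees backward (flexion) from the thigh line
  th <- 30 * pi / 180
  knee <- pt(0, 0.55)
  ank <- cbind(knee[, 1] - 0.45 * sin(th), 0, knee[, 3] - 0.45 * cos(th))
  expect_equal(sagittal_angle(pt(0, 1), knee, ank, "knee"), rep(30, n),
               tolerance = 1e-9)
  # hip flexion positive when the thigh swings forward (+x)
  hip <- pt(0, 0.95)
  knee_fwd <- cbind(hip[, 1] + 0.42 * sin(th), 0, hip[, 3] - 0.42 * cos(th))
  expect_equal(sagittal_angle(pt(0, 1.4), hip, knee_fwd, "hip"), rep(30, n),
               tolerance = 1e-9)
  # ankle: horizontal foot under vertical shank reads 0 (neutral)
  a <- sagittal_angle(pt(0, 0.55), pt(0, 0.1), pt(0.2, 0.1), "ankle")
  expect_equal(a, rep(0, n), tolerance = 1e-9)
  # zero-length segment -> NA
  bad <- sagittal_angle(pt(0, 1), pt(0, 1), pt(0.2, 0.1), "knee")
  expect_true(all(is.na(bad)))
})

test_that("cycle normalisation is exact where it should be", {
  tt <- seq(0, 2, by = 1 / 200)
  stride <- list(start = 0.25, end = 1.75)
  # linear ramp stays linear with preserved endpoints
  ramp <- normalize_cycle(tt, 3 * tt - 1, stride)
  expect_equal(ramp, seq(3 * 0.25 - 1, 3 * 1.75 - 1, length.out = 101),
               tolerance = 1e-9)
  # constant stays constant
  expect_equal(normalize_cycle(tt, rep(2.5, length(tt)), stride),
               rep(2.5, 101))
  # cubic polynomial: machine precision
  f <- function(t) 1 - 2 * t + 0.3 * t^2 + 0.11 * t^3
  expect_equal(normalize_cycle(tt, f(tt), stride),
               f(seq(0.25, 1.75, length.out = 101)), tolerance = 1e-12)
  # sine: < 1e-4 absolute error
  s <- normalize_cycle(tt, sin(2 * pi * tt), list(start = 0.3, end = 1.3))
  expect_lt(max(abs(s - sin(2 * pi * seq(0.3, 1.3, length.out = 101)))),
            1e-4)
  expect_error(normalize_cycle(tt, tt, list(start = -1, end = 1)),
               "bounds")
})

test_that("ROM is max minus min and offset invariant", {
  expect_equal(rom_per_trial(list(hip = rep(5, 10)))$rom, 0)
  expect_equal(rom_per_trial(list(knee = c(-10, 3, 25)))$rom, 35)
  a <- runif(50, -20, 40)
  expect_equal(rom_per_trial(list(j = a))$rom,
               rom_per_trial(list(j = a + 13.7))$rom, tolerance = 1e-12)
  expect_true(is.na(rom_per_trial(list(j = rep(NA_real_, 5)))$rom))
})

test_that("generator angle templates are recovered by the pipeline", {
  # uniform cycle times: the stride phase is exactly linear in time, so
  # every normalised stride curve equals the joint template
  cfg <- gait_sim_config(n_participants = 2, trials_per_substrate = 1,
                         marker_noise_sd = 0, cycle_stride_sd = 0,
                         seed = 17)
  st <- simulate_study(cfg, emg = FALSE)
  proc <- process_study(st$trials, emg = FALSE)
  j <- dplyr::inner_join(proc$roms, st$truth$roms,
                         by = c("trial_id", "side", "joint"),
                         suffix = c("", ".gt"))
  expect_gt(nrow(j), 0)
  expect_lt(max(abs(j$rom - j$rom.gt)), 1)
  # reconstruct each hard-floor trial's expected template curve and compare
  tpl <- sandgait:::default_joint_templates()
  p <- 0:100 / 100
  crv <- proc$angle_curves[proc$angle_curves$substrate_id == "hard_floor", ]
  gt_rom <- st$truth$roms
  for (j_ in c("hip", "knee", "ankle")) {
    tj <- tpl[[j_]]
    base <- tj$mean + tj$amp1 * cos(2 * pi * p - tj$phase1) +
      tj$amp2 * cos(4 * pi * p - tj$phase2)
    for (id in unique(crv$trial_id)) {
      # per-trial amplitude jitter: recover the scale from the GT ROM
      scale <- gt_rom$rom[gt_rom$trial_id == id & gt_rom$joint == j_ &
                            gt_rom$side == "L"][1] / (max(base) - min(base))
      expected <- tj$mean + scale * (base - tj$mean)
      got <- crv$angle_deg[crv$trial_id == id & crv$joint == j_ &
                             crv$side == "L" & crv$stride == 2]
      rms <- sqrt(mean((got - expected)^2))
      expect_lt(rms, 0.5)
    }
  }
})

test_that("deeper substrates show the configured extra peak flexion", {
  cfg <- gait_sim_config(n_participants = 3, trials_per_substrate = 1,
                         marker_noise_sd = 0, seed = 18)
  st <- simulate_study(cfg, emg = FALSE)
  proc <- process_study(st$trials, emg = FALSE)
  mean_hip <- proc$angle_curves |>
    dplyr::filter(joint == "hip") |>
    dplyr::group_by(substrate_id, node) |>
    dplyr::summarise(m = mean(angle_deg), .groups = "drop")
  peak <- mean_hip |>
    dplyr::group_by(substrate_id) |>
    dplyr::summarise(pk = max(m), .groups = "drop")
  pk <- setNames(peak$pk, peak$substrate_id)
  expect_gt(pk[["play_sand"]], pk[["hard_floor"]])
  expect_gt(pk[["dry_building_sand"]], pk[["wet_building_sand"]])
})
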