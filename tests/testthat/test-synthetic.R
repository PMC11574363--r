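small_cfg <- function(seed = 42, ...) {
  gait_sim_config(n_participants = 2, trials_per_substrate = 1,
                  marker_noise_sd = 0, seed = seed, ...)
}

test_that("simulation is bit-reproducible given a seed and varies across seeds", {
  a <- simulate_study(small_cfg(), emg = FALSE)
  b <- simulate_study(small_cfg(), emg = FALSE)
  expect_identical(a$trials[[1]]$markers, b$trials[[1]]$markers)
  expect_identical(a$truth$strides, b$truth$strides)
  c <- simulate_study(small_cfg(seed = 43), emg = FALSE)
  expect_false(identical(a$trials[[1]]$markers, c$trials[[1]]$markers))
  # EMG generation must not perturb marker draws
  d <- simulate_study(small_cfg(), emg = TRUE)
  expect_identical(a$trials[[1]]$markers, d$trials[[1]]$markers)
})

test_that("study shape follows the configured trial counts", {
  st <- simulate_study(gait_sim_config(n_participants = 3,
                                       marker_noise_sd = 0, seed = 2),
                       emg = FALSE)
  # 3 participants x (3 floor + 3 sands x 5) = 54 trials
  expect_length(st$trials, 3 * (3 + 3 * 5))
  empty <- simulate_study(gait_sim_config(trials_per_substrate = 0,
                                          seed = 2), emg = FALSE)
  expect_length(empty$trials, 0)
})

test_that("hard-floor ground-truth sink depths are exactly zero", {
  st <- simulate_study(small_cfg(), emg = FALSE)
  gt <- st$truth$strides
  floor <- gt[gt$substrate_id == "hard_floor", ]
  expect_true(all(floor$heel_sink_depth == 0))
  expect_true(all(floor$hallux_sink_depth == 0))
})

test_that("ground-truth event times are strictly increasing and consistent", {
  st <- simulate_study(small_cfg(), emg = FALSE)
  gt <- st$truth$strides
  for (id in unique(gt$trial_id)) {
    for (sd_ in c("L", "R")) {
      g <- gt[gt$trial_id == id & gt$side == sd_, ]
      expect_true(all(diff(g$start) > 0))
      expect_true(all(g$start < g$toe_off & g$toe_off < g$end))
      expect_equal(g$stance_time + g$swing_time, g$cycle_time,
                   tolerance = 1e-12)
    }
  }
})

test_that("configured depth means are recovered within 3 standard errors", {
  cfg <- gait_sim_config(n_participants = 8, trials_per_substrate = 2,
                         marker_noise_sd = 0, seed = 7)
  st <- simulate_study(cfg, emg = FALSE)
  gt <- st$truth$strides
  for (sub in cfg$substrates[-1]) {
    d <- gt$heel_sink_depth[gt$substrate_id == sub$substrate_id]
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - sub$heel_depth_mean), 3 * se + 0.05)
  }
})

test_that("within-substrate depth-speed coupling has the configured sign", {
  subs <- list(deep = substrate_spec("deep", heel_depth_mean = 4,
                                     hallux_depth_mean = 5,
                                     heel_depth_sd = 0.5,
                                     hallux_depth_sd = 0.5,
                                     depth_speed_slope = 0.8,
                                     speed_mean = 1.2, speed_sd = 0.3))
  cfg <- gait_sim_config(n_participants = 8, trials_per_substrate = 3,
                         substrates = subs, marker_noise_sd = 0, seed = 5,
                         participant_speed_sd = 0)
  gt <- simulate_study(cfg, emg = FALSE)$truth$strides
  tm <- dplyr::summarise(dplyr::group_by(gt, .data$trial_id),
                         speed = mean(speed),
                         depth = mean(heel_sink_depth), .groups = "drop")
  expect_gt(cor(tm$speed, tm$depth, method = "spearman"), 0)
})

test_that("the exchange oracle reproduces the analytic pendulum limits", {
  t <- seq(0, 1, length.out = 2001)
  anti <- oracle_exchange(10 * sin(2 * pi * t), -10 * sin(2 * pi * t) + 20)
  expect_equal(anti$r_pct, 100, tolerance = 1e-9)
  expect_equal(anti$ra, 1, tolerance = 1e-9)
  expect_equal(anti$co_pct, 0, tolerance = 1e-9)
  inph <- oracle_exchange(10 * sin(2 * pi * t), 10 * sin(2 * pi * t) + 5)
  expect_equal(inph$r_pct, 0, tolerance = 1e-9)
  expect_equal(inph$co_pct, 100, tolerance = 1e-9)
  quarter <- oracle_exchange(sin(2 * pi * t), cos(2 * pi * t))
  expect_equal(quarter$co_pct, 50, tolerance = 0.5)
  expect_error(oracle_exchange(sin(t), rep(1, length(t))), "RA undefined")
})

test_that("an ideal-pendulum configuration yields oracle R of 100%", {
  subs <- list(hard_floor = substrate_spec(
    "hard_floor", surface_z = 0, speed_mean = 1.25, speed_sd = 0,
    cycle_time_mean = 1.05, cycle_time_sd = 0))
  cfg <- gait_sim_config(
    n_participants = 1, trials_per_substrate = 1, substrates = subs,
    ep_ek_phase = 180, com_speed_amplitude = 9.81 * 0.025 / 1.25,
    marker_noise_sd = 0, participant_speed_sd = 0, cycle_stride_sd = 0,
    seed = 3)
  gt <- simulate_study(cfg, emg = FALSE)$truth$strides
  expect_true(all(abs(gt$r_pct - 100) < 0.1))
  expect_true(all(gt$co_pct < 1))
})

test_that("oracle R increases monotonically as the energy phase sweeps to 180", {
  subs <- list(hard_floor = substrate_spec(
    "hard_floor", surface_z = 0, speed_mean = 1.25, speed_sd = 0,
    cycle_time_mean = 1.05, cycle_time_sd = 0))
  rs <- vapply(c(90, 120, 150, 180), function(ph) {
    cfg <- gait_sim_config(
      n_participants = 1, trials_per_substrate = 1, substrates = subs,
      ep_ek_phase = ph, marker_noise_sd = 0, participant_speed_sd = 0,
      cycle_stride_sd = 0, seed = 3)
    mean(simulate_study(cfg, emg = FALSE)$truth$strides$r_pct)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("config invariants are enforced", {
  expect_error(gait_sim_config(duty_factor = 1.2), "duty_factor")
  expect_error(gait_sim_config(strides_per_trial = 2), "strides_per_trial")
  expect_error(gait_sim_config(ep_ek_phase = 400), "ep_ek_phase")
  expect_error(substrate_spec("x", heel_depth_mean = -1), "depths")
})
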