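# constructed trial with known stride timing and constant-speed pelvis
constructed_trial <- function(speed = 1.2, rate = 200, duration = 6,
                              surface_z = 0.10, heel_min_z = 0.06) {
  tt <- seq(0, duration, by = 1 / rate)
  n <- length(tt)
  relx <- 0.3 * sin(2 * pi * tt)
  x <- speed * tt
  zheel <- surface_z + 0.04 + 0.02 * sin(2 * pi * tt) # min 2 cm above surface
  mk <- list(
    SACR = cbind(x, 0, rep(1, n)),
    LHEE = cbind(x + relx, rep(-0.06, n), zheel),
    RHEE = cbind(x - relx, rep(0.06, n), zheel),
    LHALL = cbind(x + relx, rep(-0.06, n),
                  surface_z + (heel_min_z - surface_z) +
                    0.04 * (1 + sin(2 * pi * tt))),
    RHALL = cbind(x - relx, rep(0.06, n), zheel))
  gait_trial(mk, marker_rate = rate, substrate_surface_z = surface_z,
             trial_id = "constructed")
}

test_that("spatiotemporal definitions hold on a constructed trial", {
  tr <- constructed_trial()
  ev <- detect_events(tr)
  st <- build_strides(ev, tr)
  out <- compute_spatiotemporal(tr, st, ev)
  expect_true(all(abs(out$speed - 1.2) < 1e-6))
  expect_true(all(abs(out$cycle_time - 1) < 0.006))
  # stance = toe_off - start; duty strictly in (0, 1)
  expect_true(all(out$duty_factor > 0 & out$duty_factor < 1))
  expect_equal(out$stance_time + out$swing_time, out$cycle_time,
               tolerance = 1e-12)
  expect_true(all(abs(out$stride_width - 0.12) < 1e-9))
  # pelvis at constant speed: stride length = speed x cycle
  expect_equal(out$stride_length, out$speed * out$cycle_time,
               tolerance = 1e-3)
})

test_that("duty factor follows its definition", {
  st <- tibble::tibble(side = "L", stride = 1L, start = 0, toe_off = 0.7,
                       end = 1, valid = TRUE, reason = NA_character_)
  ev <- tibble::tibble(side = c("L", "L", "L"),
                       event = c("heel_strike", "toe_off", "heel_strike"),
                       time = c(0, 0.7, 1), frame = c(1L, 141L, 201L))
  tr <- constructed_trial()
  out <- compute_spatiotemporal(tr, st, ev)
  expect_equal(out$duty_factor, 0.7)
  expect_equal(out$stance_time, 0.7)
})

test_that("noise-free study recovers every ground-truth parameter within 1%", {
  cfg <- gait_sim_config(n_participants = 3, trials_per_substrate = 1,
                         marker_noise_sd = 0, seed = 14)
  st <- simulate_study(cfg, emg = FALSE)
  proc <- process_study(st$trials, emg = FALSE)
  j <- dplyr::inner_join(proc$stride_table, st$truth$strides,
                         by = c("trial_id", "side", "stride"),
                         suffix = c("", ".gt"))
  expect_equal(nrow(j), nrow(st$truth$strides))
  for (v in c("speed", "cycle_time", "stance_time", "swing_time",
              "duty_factor", "stride_length", "stride_width")) {
    rel <- abs(j[[v]] - j[[paste0(v, ".gt")]]) /
      pmax(abs(j[[paste0(v, ".gt")]]), 1e-9)
    expect_lt(max(rel, na.rm = TRUE), 0.01)
  }
  expect_lt(max(abs(j$double_support_time - j$double_support_time.gt),
                na.rm = TRUE), 1e-9)
})

test_that("symmetric gait satisfies the double-support identity to a frame", {
  cfg <- gait_sim_config(n_participants = 3, trials_per_substrate = 1,
                         marker_noise_sd = 0, cycle_stride_sd = 0,
                         seed = 15)
  st <- simulate_study(cfg, emg = FALSE)
  proc <- process_study(st$trials, emg = FALSE)
  tab <- proc$stride_table
  err <- abs(tab$double_support_time -
               tab$cycle_time * (2 * tab$duty_factor - 1))
  expect_lte(max(err, na.rm = TRUE), 1 / 200 + 1e-9)
})

test_that("sinkage depth follows the surface-minus-minimum definition", {
  tr <- constructed_trial(surface_z = 0.10, heel_min_z = 0.06)
  ev <- detect_events(tr)
  st <- build_strides(ev, tr)
  snk <- compute_sinkage(tr, st)
  # LHALL min z = 0.06 -> 4 cm; LHEE min z = 0.12 -> -2 cm, flagged not clipped
  lhall <- snk$hallux_sink_depth[snk$side == "L"]
  expect_true(all(abs(lhall - 4) < 0.05))
  lheel <- snk$heel_sink_depth[snk$side == "L"]
  expect_true(all(lheel < 0))
  expect_true(all(snk$flagged[snk$side == "L"]))
})

test_that("sinkage is invariant to rigid x/y translation of the trial", {
  tr <- constructed_trial()
  ev <- detect_events(tr)
  st <- build_strides(ev, tr)
  s1 <- compute_sinkage(tr, st)
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m) {
    m[, 1] <- m[, 1] + 3.7; m[, 2] <- m[, 2] - 1.1; m
  })
  s2 <- compute_sinkage(tr2, build_strides(detect_events(tr2), tr2))
  expect_equal(s1$hallux_sink_depth, s2$hallux_sink_depth,
               tolerance = 1e-9)
})

test_that("CV matches hand computation and is scale invariant", {
  d <- tibble::tibble(g = "a", v = c(1, 2, 3))
  cv <- coefficient_of_variation(d, "v", group = "g")
  expect_equal(cv$cv, 0.5)
  expect_equal(coefficient_of_variation(
    tibble::tibble(g = "a", v = rep(4, 5)), "v", group = "g")$cv, 0)
  k <- 7.3
  cvk <- coefficient_of_variation(dplyr::mutate(d, v = v * k), "v",
                                  group = "g")
  expect_equal(cvk$cv, cv$cv, tolerance = 1e-12)
  expect_error(coefficient_of_variation(
    tibble::tibble(g = "a", v = c(-1, 1)), "v", group = "g"), "zero")
  expect_error(coefficient_of_variation(
    tibble::tibble(g = "a", v = 1), "v", group = "g"), "at least 2")
})

test_that("relative CV change uses the reference substrate", {
  cv <- tibble::tibble(variable = "duty_factor",
                       substrate_id = c("hard_floor", "play_sand"),
                       n = c(10, 10), mean = c(1, 1), sd = c(1, 1),
                       cv = c(0.10, 0.129))
  out <- cv_relative_change(cv)
  expect_equal(out$cv_change_pct[out$substrate_id == "play_sand"], 29,
               tolerance = 1e-9)
  expect_true(is.na(out$cv_change_pct[out$substrate_id == "hard_floor"]))
})
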