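test_that("segmental CoM follows the weighted-endpoint model", {
  n <- 4
  one <- function(a, b, c) cbind(rep(a, n), rep(b, n), rep(c, n))
  tab1 <- tibble::tibble(segment = "s", proximal_role = "A",
                         distal_role = "B", mass_fraction = 1,
                         com_fraction = 0.5)
  tr <- gait_trial(list(A = one(0, 0, 0), B = one(1, 0, 0)))
  sch <- structure(c(A = "A", B = "B"), class = "marker_schema")
  com <- body_com(tr, sch, tab1, use_direct = FALSE)
  expect_equal(unname(com[1, ]), c(0.5, 0, 0))
  # coincident endpoints: CoM = that point
  tr2 <- gait_trial(list(A = one(2, 3, 4), B = one(2, 3, 4)))
  expect_equal(unname(body_com(tr2, sch, tab1, use_direct = FALSE)[1, ]),
               c(2, 3, 4))
})

test_that("full-body CoM equals an explicit-loop weighted-mean oracle", {
  set.seed(6)
  st <- simulate_study(gait_sim_config(n_participants = 1,
                                       trials_per_substrate = 1,
                                       marker_noise_sd = 0, seed = 6),
                       emg = FALSE)
  tr <- st$trials[[1]]
  tab <- default_anthropometric_table()
  sch <- default_marker_schema()
  com <- body_com(tr, sch, tab, use_direct = FALSE)
  # oracle on a subsample of frames (loop implementation)
  frames <- seq(1, nrow(com), by = 37)
  sub <- tr
  sub$markers <- lapply(tr$markers, function(m) m[frames, , drop = FALSE])
  oracle <- com_loop_oracle(sub, sch, tab)
  expect_lt(max(abs(com[frames, ] - oracle)), 1e-12)
})

test_that("missing endpoint roles are reported by segment", {
  tr <- sinusoid_trial()
  expect_error(body_com(tr, default_marker_schema(), use_direct = FALSE),
               "missing endpoint role")
})

test_that("energies match closed forms for stationary and uniform motion", {
  n <- 600
  still <- cbind(rep(0, n), 0, rep(1, n))
  es <- com_energies(still, body_mass = 70, rate = 200)
  expect_equal(es$e_pot, rep(70 * 9.81 * 1, n), tolerance = 1e-12)
  expect_equal(max(abs(es$e_kin)), 0, tolerance = 1e-9)
  expect_equal(es$e_tot, es$e_pot + es$e_kin)
  tt <- (seq_len(n) - 1) / 200
  moving <- cbind(1.2 * tt, 0, rep(1, n))
  es2 <- com_energies(moving, body_mass = 70, rate = 200)
  expect_equal(es2$e_kin, rep(0.5 * 70 * 1.2^2, n), tolerance = 1e-6)
})

test_that("kinetic energy is constant on a circular path at constant speed", {
  rate <- 400
  tt <- seq(0, 3, by = 1 / rate)
  com <- cbind(cos(2 * pi * tt), sin(2 * pi * tt), 1)
  es <- com_energies(com, body_mass = 70, rate = rate, lowpass_hz = NULL)
  ek <- es$e_kin[50:(length(tt) - 50)]
  expect_lt((max(ek) - min(ek)) / mean(ek), 1e-6)
})

test_that("exchange metrics reproduce the pendulum limits", {
  t <- seq(0, 1, length.out = 2001)
  anti <- exchange_metrics(tibble::tibble(
    e_pot = 10 * sin(2 * pi * t), e_kin = -10 * sin(2 * pi * t) + 20))
  expect_equal(anti$r_pct, 100, tolerance = 1e-9)
  expect_equal(anti$ra, 1, tolerance = 1e-9)
  expect_equal(anti$co_pct, 0, tolerance = 1e-9)
  inph <- exchange_metrics(tibble::tibble(
    e_pot = 10 * sin(2 * pi * t), e_kin = 10 * sin(2 * pi * t)))
  expect_equal(inph$r_pct, 0, tolerance = 1e-9)
  expect_equal(inph$co_pct, 100, tolerance = 1e-9)
  quarter <- exchange_metrics(tibble::tibble(
    e_pot = sin(2 * pi * t), e_kin = cos(2 * pi * t)))
  expect_equal(quarter$co_pct, 50, tolerance = 1)
  o <- oracle_exchange(sin(2 * pi * t), cos(2 * pi * t))
  expect_lt(abs(quarter$r_pct - o$r_pct), 0.1)
  # degenerate inputs
  expect_error(exchange_metrics(tibble::tibble(e_pot = rep(1, 10),
                                               e_kin = rep(2, 10))),
               "R undefined")
})

test_that("R, RA and CO are invariant to energy offsets", {
  set.seed(8)
  t <- seq(0, 1, length.out = 400)
  ep <- 5 * sin(2 * pi * t) + 2 * sin(4 * pi * t + 1)
  ek <- 4 * sin(2 * pi * t + 2.5) + sin(4 * pi * t)
  a <- exchange_metrics(tibble::tibble(e_pot = ep, e_kin = ek))
  b <- exchange_metrics(tibble::tibble(e_pot = ep + 300, e_kin = ek + 55))
  expect_equal(a$r_pct, b$r_pct, tolerance = 1e-9)
  expect_equal(a$ra, b$ra, tolerance = 1e-9)
  expect_equal(a$co_pct, b$co_pct, tolerance = 1e-9)
})

test_that("metrics are stable under 2x resampling and stay in bounds", {
  t1 <- seq(0, 1, length.out = 201)
  t2 <- seq(0, 1, length.out = 401)
  f_ep <- function(t) 5 * sin(2 * pi * t) + sin(4 * pi * t + 0.7)
  f_ek <- function(t) 4 * sin(2 * pi * t + 2.9) + 0.5 * sin(4 * pi * t)
  a <- exchange_metrics(tibble::tibble(e_pot = f_ep(t1), e_kin = f_ek(t1)))
  b <- exchange_metrics(tibble::tibble(e_pot = f_ep(t2), e_kin = f_ek(t2)))
  expect_lt(abs(a$r_pct - b$r_pct), 0.5)
  expect_lt(abs(a$ra - b$ra), 0.5)
  expect_lt(abs(a$co_pct - b$co_pct), 0.5)
  # bounds over random smooth inputs
  set.seed(9)
  for (i in 1:20) {
    tt <- seq(0, 1, length.out = 300)
    ep <- cumsum(rnorm(300)); ek <- cumsum(rnorm(300))
    m <- exchange_metrics(tibble::tibble(e_pot = ep, e_kin = ek))
    expect_gte(m$r_pct, 0); expect_lte(m$r_pct, 100)
    expect_gte(m$co_pct, 0); expect_lte(m$co_pct, 100)
    expect_gt(m$ra, 0)
  }
})

test_that("pipeline exchange metrics track the brute-force oracle per stride", {
  cfg <- gait_sim_config(n_participants = 3, trials_per_substrate = 1,
                         marker_noise_sd = 0, seed = 16)
  st <- simulate_study(cfg, emg = FALSE)
  proc <- process_study(st$trials, emg = FALSE)
  j <- dplyr::inner_join(proc$exchange, st$truth$strides,
                         by = c("trial_id", "side", "stride"),
                         suffix = c("", ".gt"))
  expect_gt(nrow(j), 50)
  expect_lt(max(abs(j$r_pct - j$r_pct.gt)), 0.5)
  expect_lt(max(abs(j$co_pct - j$co_pct.gt)), 1)
})
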