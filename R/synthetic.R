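#' Describe a walking substrate
#'
#' A substrate spec carries the surface height and the foot-sinkage regime
#' the generator should reproduce. Default depth parameters (see
#' [default_substrates()]) place the three sand conditions at heel
#' (calcaneus) means of 2.08, 2.68 and 4.09 cm and hallux means of 3.43,
#' 4.26 and 5.23 cm for wet building, dry building and play sand; the hard
#' floor has all depths equal to zero. `depth_speed_slope` couples stride
#' depth to trial speed within a substrate (cm per m/s, positive: faster
#' trials sink deeper).
#'
#' @param substrate_id Identifier.
#' @param surface_z Walking-surface height above the lab floor, m.
#' @param heel_depth_mean,hallux_depth_mean Mean sinkage depths, cm.
#' @param heel_depth_sd,hallux_depth_sd Between-stride depth s.d., cm.
#' @param depth_speed_slope Within-substrate depth-speed coupling, cm/(m/s).
#' @param speed_mean,speed_sd Trial walking-speed distribution, m/s.
#' @param cycle_time_mean,cycle_time_sd Trial stride-cycle time, s.
#' @return A list of class `substrate_spec`.
#' @export
substrate_spec <- function(substrate_id, surface_z = 0.10,
                           heel_depth_mean = 0, hallux_depth_mean = 0,
                           heel_depth_sd = 0, hallux_depth_sd = 0,
                           depth_speed_slope = 0,
                           speed_mean = 1.25, speed_sd = 0.08,
                           cycle_time_mean = 1.06, cycle_time_sd = 0.03) {
  assert_that(heel_depth_mean >= 0 && hallux_depth_mean >= 0,
              "substrate depths must be >= 0")
  assert_that(surface_z >= 0, "surface_z must be >= 0")
  structure(list(substrate_id = substrate_id, surface_z = surface_z,
                 heel_depth_mean = heel_depth_mean,
                 hallux_depth_mean = hallux_depth_mean,
                 heel_depth_sd = heel_depth_sd,
                 hallux_depth_sd = hallux_depth_sd,
                 depth_speed_slope = depth_speed_slope,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 cycle_time_mean = cycle_time_mean,
                 cycle_time_sd = cycle_time_sd),
            class = "substrate_spec")
}

#' Default study substrates
#'
#' Hard floor plus the three sand conditions, with depth means/s.d. at the
#' observed study scale, slower mean speeds and longer cycle times on deeper
#' substrates, and a positive within-substrate depth-speed slope.
#' @return Named list of [substrate_spec()]s.
#' @export
default_substrates <- function() {
  list(
    hard_floor = substrate_spec("hard_floor", surface_z = 0,
      speed_mean = 1.35, cycle_time_mean = 1.02),
    wet_building_sand = substrate_spec("wet_building_sand",
      heel_depth_mean = 2.08, hallux_depth_mean = 3.43,
      heel_depth_sd = 0.85, hallux_depth_sd = 0.88,
      depth_speed_slope = 0.8,
      speed_mean = 1.25, cycle_time_mean = 1.06),
    dry_building_sand = substrate_spec("dry_building_sand",
      heel_depth_mean = 2.68, hallux_depth_mean = 4.26,
      heel_depth_sd = 1.00, hallux_depth_sd = 1.37,
      depth_speed_slope = 0.8,
      speed_mean = 1.15, cycle_time_mean = 1.10),
    play_sand = substrate_spec("play_sand",
      heel_depth_mean = 4.09, hallux_depth_mean = 5.23,
      heel_depth_sd = 0.93, hallux_depth_sd = 1.24,
      depth_speed_slope = 0.8,
      speed_mean = 1.10, cycle_time_mean = 1.14))
}

default_joint_templates <- function() {
  # angle(p) = mean + amp1*cos(2*pi*p - phase1) + amp2*cos(4*pi*p - phase2)
  list(
    hip   = list(mean = 10, amp1 = 19, phase1 = 0.0,        amp2 = 3, phase2 = 1.0),
    knee  = list(mean = 30, amp1 = 26, phase1 = 2 * pi * 0.72, amp2 = 6, phase2 = 2 * pi * 0.2),
    ankle = list(mean = 0,  amp1 = 8,  phase1 = 2 * pi * 0.35, amp2 = 6, phase2 = 2 * pi * 0.8))
}

default_emg_bursts <- function() {
  # per muscle: list of c(onset %cycle, offset %cycle, relative amplitude);
  # textbook activation phases (cycle starts at ipsilateral heel-strike)
  list(
    BFL = list(c(0.80, 1.00, 1.0), c(0.00, 0.10, 0.7)),
    RF  = list(c(0.00, 0.15, 1.0), c(0.88, 1.00, 0.6)),
    VL  = list(c(0.00, 0.18, 1.0), c(0.90, 1.00, 0.5)),
    VM  = list(c(0.00, 0.18, 1.0), c(0.90, 1.00, 0.5)),
    TA  = list(c(0.00, 0.12, 1.0), c(0.60, 1.00, 0.8)),
    LG  = list(c(0.10, 0.55, 1.0)),
    MG  = list(c(0.10, 0.55, 1.0)),
    SOL = list(c(0.12, 0.58, 1.0)))
}

#' Configure the synthetic gait study
#'
#' Defaults emulate the study conditions: 21 participants, 3 hard-floor and
#' 5 sand trials per participant per substrate, 200 Hz markers and 1110 Hz
#' EMG, self-selected speeds near 1.1-1.35 m/s declining with sinkage depth,
#' a CoM that oscillates vertically twice per stride with a kinetic-energy
#' fluctuation whose phase against potential energy is configurable
#' (`ep_ek_phase`, degrees; 180 is the ideal out-of-phase pendulum).
#'
#' @param n_participants Number of participants.
#' @param trials_per_substrate Either `NULL` (study shape: 3 on the hard
#'   floor, 5 on each sand) or a single count applied to every substrate.
#' @param strides_per_trial Number of full right-side strides per trial
#'   (left side yields one more); must be >= 3.
#' @param substrates Named list of [substrate_spec()]s.
#' @param duty_factor Stance fraction of the gait cycle (0-1).
#' @param com_height Mean CoM height, m.
#' @param com_vertical_amplitude CoM vertical oscillation amplitude, m.
#' @param com_speed_amplitude Amplitude of the CoM speed fluctuation, m/s
#'   (sets the kinetic-energy oscillation amplitude).
#' @param ep_ek_phase Phase of the kinetic-energy oscillation relative to
#'   potential energy, degrees in `[0, 360)`; 180 = ideal pendulum.
#' @param stride_width Lateral heel separation, m.
#' @param joint_angle_templates Per-joint two-harmonic templates (see
#'   `default_joint_templates`-style lists).
#' @param joint_offset_by_substrate Named numeric: constant flexion offset
#'   (deg) added to hip/knee/ankle curves per substrate (deeper substrates
#'   default to larger peak flexion).
#' @param emg_bursts Per-muscle burst windows (onset, offset, amplitude in
#'   fraction of cycle / relative units).
#' @param emg_amplitude Envelope scale, volts.
#' @param emg_noise_scale Multiplicative band-limited noise scale (0 gives
#'   pure envelopes, the generator's noise-free envelope mode).
#' @param emg_drift_amplitude,emg_drift_freq Additive baseline drift, volts
#'   and Hz.
#' @param marker_rate,emg_rate Sampling rates, Hz.
#' @param marker_noise_sd Isotropic marker noise s.d., m.
#' @param participant_speed_sd Between-participant random-intercept s.d. on
#'   speed, m/s.
#' @param cycle_stride_sd Within-trial stride-to-stride cycle-time s.d., s.
#' @param seed Integer seed; the study is bit-reproducible given the seed.
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_participants = 21,
                            trials_per_substrate = NULL,
                            strides_per_trial = 4,
                            substrates = default_substrates(),
                            duty_factor = 0.62,
                            com_height = 0.97,
                            com_vertical_amplitude = 0.025,
                            com_speed_amplitude = 0.08,
                            ep_ek_phase = 170,
                            stride_width = 0.12,
                            joint_angle_templates = default_joint_templates(),
                            joint_offset_by_substrate = NULL,
                            emg_bursts = default_emg_bursts(),
                            emg_amplitude = 3e-4,
                            emg_noise_scale = 1,
                            emg_drift_amplitude = 2e-5,
                            emg_drift_freq = 0.4,
                            marker_rate = 200,
                            emg_rate = 1110,
                            marker_noise_sd = 0.001,
                            participant_speed_sd = 0.10,
                            cycle_stride_sd = 0.02,
                            seed = 1L) {
  assert_that(duty_factor > 0 && duty_factor < 1,
              "duty_factor must lie strictly between 0 and 1")
  assert_that(strides_per_trial >= 3, "strides_per_trial must be >= 3")
  assert_that(ep_ek_phase >= 0 && ep_ek_phase < 360,
              "ep_ek_phase must lie in [0, 360) degrees")
  sds <- c(marker_noise_sd, participant_speed_sd, cycle_stride_sd,
           vapply(substrates, function(s)
             max(s$speed_sd, s$cycle_time_sd, s$heel_depth_sd,
                 s$hallux_depth_sd), numeric(1)))
  assert_that(all(sds >= 0), "all standard deviations must be >= 0")
  if (is.null(joint_offset_by_substrate)) {
    ids <- vapply(substrates, `[[`, character(1), "substrate_id")
    depth <- vapply(substrates, `[[`, numeric(1), "heel_depth_mean")
    joint_offset_by_substrate <- setNames(rank(depth, ties.method = "first") - 1,
                                          ids) * 1.6
  }
  structure(
    list(n_participants = n_participants,
         trials_per_substrate = trials_per_substrate,
         strides_per_trial = strides_per_trial,
         substrates = substrates, duty_factor = duty_factor,
         com_height = com_height,
         com_vertical_amplitude = com_vertical_amplitude,
         com_speed_amplitude = com_speed_amplitude,
         ep_ek_phase = ep_ek_phase, stride_width = stride_width,
         joint_angle_templates = joint_angle_templates,
         joint_offset_by_substrate = joint_offset_by_substrate,
         emg_bursts = emg_bursts, emg_amplitude = emg_amplitude,
         emg_noise_scale = emg_noise_scale,
         emg_drift_amplitude = emg_drift_amplitude,
         emg_drift_freq = emg_drift_freq,
         marker_rate = marker_rate, emg_rate = emg_rate,
         marker_noise_sd = marker_noise_sd,
         participant_speed_sd = participant_speed_sd,
         cycle_stride_sd = cycle_stride_sd, seed = as.integer(seed)),
    class = "gait_sim_config")
}

#' Brute-force pendular exchange oracle
#'
#' Reference implementation of the energy-recovery statistics, kept as an
#' independent code path (dense incremental sums in an explicit loop) from
#' the pipeline's [exchange_metrics()]. Used for ground truth and
#' cross-validation only.
#'
#' @param e_pot,e_kin Equal-length energy series, J (>= 3 samples).
#' @return A list with `r_pct`, `ra`, `co_pct`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 400)
#' oracle_exchange(10 * sin(2 * pi * t), -10 * sin(2 * pi * t) + 20)$r_pct
oracle_exchange <- function(e_pot, e_kin) {
  assert_that(length(e_pot) == length(e_kin), "series lengths differ")
  assert_that(length(e_pot) >= 3L, "need at least 3 samples")
  tol <- 1e-12
  wv <- 0; wf <- 0; wext <- 0
  n_same <- 0L; n_move <- 0L
  for (i in 2:length(e_pot)) {
    dp <- e_pot[i] - e_pot[i - 1L]
    dk <- e_kin[i] - e_kin[i - 1L]
    dt <- dp + dk
    if (dp > 0) wv <- wv + dp
    if (dk > 0) wf <- wf + dk
    if (dt > 0) wext <- wext + dt
    if (abs(dp) > tol && abs(dk) > tol) {
      n_move <- n_move + 1L
      if (sign(dp) == sign(dk)) n_same <- n_same + 1L
    }
  }
  if (max(e_kin) - min(e_kin) <= tol)
    abort("RA undefined: kinetic energy is constant")
  if (wv + wf <= tol)
    abort("R undefined: both energy series are constant")
  list(r_pct = 100 * (wv + wf - wext) / (wv + wf),
       ra = (max(e_pot) - min(e_pot)) / (max(e_kin) - min(e_kin)),
       co_pct = if (n_move > 0L) 100 * n_same / n_move else NA_real_)
}

# stride phase: 0 at knots[1], increasing by 2*pi per knot, C^2 cubic
# spline between knots (strike spacing is near-uniform, so the interpolant
# stays monotone and the phase rate is smooth — kinks at strikes would
# leak broadband content into the CoM velocities); linearly extrapolated
# beyond the first/last knot
stride_phase <- function(t, knots) {
  vals <- 2 * pi * (seq_along(knots) - 1)
  ph <- if (length(knots) >= 3) {
    stats::splinefun(knots, vals, method = "fmm")(pmin(
      pmax(t, knots[1]), knots[length(knots)]))
  } else {
    stats::approx(knots, vals, xout = t, rule = 2)$y
  }
  lo <- t < knots[1]
  hi <- t > knots[length(knots)]
  if (any(lo)) {
    slope <- 2 * pi / (knots[2] - knots[1])
    ph[lo] <- (t[lo] - knots[1]) * slope
  }
  if (any(hi)) {
    k <- length(knots)
    slope <- 2 * pi / (knots[k] - knots[k - 1])
    ph[hi] <- 2 * pi * (k - 1) + (t[hi] - knots[k]) * slope
  }
  ph
}

eval_joint_template <- function(tpl, p, offset = 0, scale = 1) {
  offset + tpl$mean + scale * (
    tpl$amp1 * cos(2 * pi * p - tpl$phase1) +
    tpl$amp2 * cos(4 * pi * p - tpl$phase2))
}

burst_envelope <- function(bursts, p) {
  env <- numeric(length(p))
  pm <- p %% 1
  for (b in bursts) {
    on <- b[1]; off <- b[2]; amp <- b[3]
    width <- (off - on) %% 1
    if (width == 0) next
    w <- ((pm - on) %% 1) / width
    inside <- w >= 0 & w <= 1
    env[inside] <- env[inside] + amp * 0.5 * (1 - cos(2 * pi * w[inside]))
  }
  env
}

#' Simulate one walking trial with ground truth
#'
#' Builds a full synthetic trial: a CoM with prescribed potential/kinetic
#' phase relation (emitted both as a direct `COM` channel and implied by the
#' skeleton), pelvis and foot markers arranged so the coordinate-based event
#' rule recovers the scheduled (frame-snapped) heel-strikes and toe-offs,
#' stance-phase heel/hallux dips below the substrate surface by half-sines of
#' the drawn depths, leg joint centres consistent with the joint-angle
#' templates, and EMG burst envelopes modulating band-limited noise.
#'
#' @param cfg A [gait_sim_config()].
#' @param participant List with `id`, `sex`, `body_mass`, `height`,
#'   `speed_intercept` (or an integer index, in which case deterministic
#'   defaults are derived).
#' @param substrate A [substrate_spec()].
#' @param seed Integer seed for this trial's draws.
#' @param trial_id Identifier.
#' @param emg Generate EMG channels? (Marker draws are unaffected by this
#'   switch.)
#' @return List with elements `trial` (a [gait_trial()]) and `truth` (list of
#'   tibbles: `strides`, `roms`, `emg`).
#' @export
simulate_trial <- function(cfg, participant, substrate, seed = cfg$seed,
                           trial_id = NULL, emg = TRUE) {
  if (is.numeric(participant)) {
    idx <- as.integer(participant)
    participant <- list(id = sprintf("P%02d", idx),
                        sex = if (idx %% 2L == 1L) "female" else "male",
                        body_mass = 68.5, height = 1.73,
                        speed_intercept = 0)
  }
  trial_id <- trial_id %||%
    paste(participant$id, substrate$substrate_id, "T1", sep = "_")
  with_seed(seed, simulate_trial_impl(cfg, participant, substrate,
                                      trial_id, emg))
}

simulate_trial_impl <- function(cfg, prt, sub, trial_id, emg_on) {
  rate <- cfg$marker_rate
  dt <- 1 / rate
  duty <- cfg$duty_factor
  K <- cfg$strides_per_trial          # right strides; left has K + 1

  ## -- schedule: left heel strikes, frame-snapped ---------------------------
  speed <- max(0.4, sub$speed_mean + prt$speed_intercept +
                 rnorm(1, 0, sub$speed_sd))
  cycle_trial <- max(0.6, sub$cycle_time_mean + rnorm(1, 0, sub$cycle_time_sd))
  n_strike <- K + 2L
  cycles <- pmax(0.6, cycle_trial + rnorm(n_strike - 1L, 0, cfg$cycle_stride_sd))
  t_pad <- 0.45 * cycle_trial
  tau_raw <- t_pad + c(0, cumsum(cycles))
  tau_l <- round(tau_raw / dt) * dt                 # left strikes, on-grid
  tau_r <- round((tau_l[-n_strike] + tau_l[-1]) / 2 / dt) * dt
  t_end <- tau_l[n_strike] + t_pad
  tt <- seq(0, round(t_end / dt) * dt, by = dt)
  nf <- length(tt)

  # one toe-off per strike (virtual continuation cycle closes the last stance)
  toes_from <- function(tau) {
    tau_ext <- c(tau, tau[length(tau)] + diff(tau)[length(tau) - 1L])
    round((tau_ext[-length(tau_ext)] + duty * diff(tau_ext)) / dt) * dt
  }
  toe_l <- toes_from(tau_l)
  toe_r <- toes_from(tau_r)

  ## -- CoM with prescribed E_pot/E_kin phase relation -----------------------
  m <- prt$body_mass
  g <- 9.81
  phi_l <- stride_phase(tt, tau_l)                  # 0..2pi per left stride
  alpha <- 2 * phi_l                                # 2 oscillations / stride
  az <- cfg$com_vertical_amplitude
  z_com <- cfg$com_height + az * sin(alpha)
  dalpha <- c(diff(alpha) / dt, NA)
  dalpha[nf] <- dalpha[nf - 1L]
  vz <- az * cos(alpha) * dalpha
  phase_rad <- cfg$ep_ek_phase * pi / 180
  ak <- m * speed * cfg$com_speed_amplitude         # E_kin oscillation, J
  k0 <- 0.5 * m * speed^2
  e_kin_target <- pmax(k0 + ak * sin(alpha + phase_rad), 1)
  vx_sq <- pmax(2 * e_kin_target / m - vz^2, 0.01)
  vx <- sqrt(vx_sq)
  x_com <- cumsum(c(0, (vx[-1] + vx[-nf]) / 2 * dt))
  s <- 1                                            # travel direction
  e_pot_true <- m * g * z_com
  e_kin_true <- 0.5 * m * (vx^2 + vz^2)             # == e_kin_target

  ## -- pelvis, trunk, head, arms -------------------------------------------
  com <- cbind(x = s * x_com, y = 0, z = z_com)
  sacr <- sweep(com, 2, c(-0.03, 0, 0.02), `+`)
  mk <- list(COM = com, SACR = sacr)
  fixed_offset <- function(dx, dy, dz)
    sweep(sacr, 2, c(dx, dy, dz), `+`)
  mk$NECK <- fixed_offset(0.00, 0, 0.45)
  mk$HEAD <- fixed_offset(0.00, 0, 0.70)
  mk$LSHO <- fixed_offset(0.00, -0.18, 0.42)
  mk$RSHO <- fixed_offset(0.00, 0.18, 0.42)
  mk$LELB <- fixed_offset(-0.02, -0.20, 0.12)
  mk$RELB <- fixed_offset(-0.02, 0.20, 0.12)
  mk$LWRI <- fixed_offset(0.02, -0.21, -0.13)
  mk$RWRI <- fixed_offset(0.02, 0.21, -0.13)

  ## -- legs from joint-angle templates --------------------------------------
  off_sub <- unname(cfg$joint_offset_by_substrate[sub$substrate_id])
  if (is.na(off_sub) || is.null(off_sub)) off_sub <- 0
  amp_scale <- 1 + rnorm(1, 0, 0.03)
  phi_r <- stride_phase(tt, tau_r)
  l1 <- 0.245 * prt$height; l2 <- 0.250 * prt$height; l3 <- 0.12 * prt$height
  legs <- list(L = list(phase = phi_l / (2 * pi), ysign = -1),
               R = list(phase = phi_r / (2 * pi), ysign = +1))
  roms <- list()
  for (side in names(legs)) {
    p <- legs[[side]]$phase
    ys <- legs[[side]]$ysign
    hip_a <- eval_joint_template(cfg$joint_angle_templates$hip, p,
                                 off_sub, amp_scale)
    knee_a <- eval_joint_template(cfg$joint_angle_templates$knee, p,
                                  off_sub, amp_scale)
    ankle_a <- eval_joint_template(cfg$joint_angle_templates$ankle, p,
                                   off_sub, amp_scale)
    th_t <- hip_a * pi / 180
    th_s <- (hip_a - knee_a) * pi / 180
    th_f <- th_s + ankle_a * pi / 180
    hip <- sweep(sacr, 2, c(0.00, ys * 0.09, -0.05), `+`)
    knee <- hip + l1 * cbind(s * sin(th_t), 0, -cos(th_t))
    ank <- knee + l2 * cbind(s * sin(th_s), 0, -cos(th_s))
    toe <- ank + l3 * cbind(s * cos(th_f), 0, sin(th_f))
    mk[[paste0(side, "HIP")]] <- hip
    mk[[paste0(side, "KNEE")]] <- knee
    mk[[paste0(side, "ANK")]] <- ank
    mk[[paste0(side, "TOE")]] <- toe
    roms[[side]] <- tibble(
      side = side, joint = c("hip", "knee", "ankle"),
      rom = c(max(hip_a) - min(hip_a), max(knee_a) - min(knee_a),
              max(ankle_a) - min(ankle_a)))
  }

  ## -- heel / hallux markers: events + sinkage ------------------------------
  surf <- sub$surface_z
  rel_amp <- 0.40 * speed * cycle_trial
  strike_list <- list(L = tau_l, R = tau_r)
  toe_list <- list(L = toe_l, R = toe_r)
  depth_draw <- function(n, mean_cm, sd_cm) {
    if (mean_cm <= 0) return(rep(0, n))
    pmax(0, mean_cm + sub$depth_speed_slope * (speed - sub$speed_mean) +
           rnorm(n, 0, sd_cm))
  }
  heel_depths <- list(); hall_depths <- list()
  for (side in c("L", "R")) {
    tau <- strike_list[[side]]
    ns <- length(tau) - 1L
    heel_depths[[side]] <- depth_draw(ns, sub$heel_depth_mean,
                                      sub$heel_depth_sd)
    hall_depths[[side]] <- depth_draw(ns, sub$hallux_depth_mean,
                                      sub$hallux_depth_sd)
    phi <- stride_phase(tt, tau)
    ysign <- if (side == "L") -1 else 1
    rel_x <- rel_amp * cos(phi)
    # hallux relative x: minima exactly at the (frame-snapped) toe-offs
    psi <- stride_phase(tt, toe_list[[side]]) + pi
    rel_x_hall <- rel_amp * cos(psi)
    # vertical: stance dip (half-sine of drawn depth), swing lift
    z_heel <- rep(surf, nf); z_hall <- rep(surf, nf)
    for (k in seq_len(ns)) {
      stance <- duty * (tau[k + 1L] - tau[k])
      in_st <- tt >= tau[k] & tt <= tau[k] + stance
      ph_st <- (tt[in_st] - tau[k]) / stance
      z_heel[in_st] <- surf - heel_depths[[side]][k] / 100 * sin(pi * ph_st)
      z_hall[in_st] <- surf - hall_depths[[side]][k] / 100 * sin(pi * ph_st)
      in_sw <- tt > tau[k] + stance & tt < tau[k + 1L]
      ph_sw <- (tt[in_sw] - tau[k] - stance) / ((1 - duty) * (tau[k + 1L] - tau[k]))
      z_heel[in_sw] <- surf + 0.06 * sin(pi * ph_sw)
      z_hall[in_sw] <- surf + 0.04 * sin(pi * ph_sw)
    }
    x_base <- s * x_com
    mk[[paste0(side, "HEE")]] <-
      cbind(x = x_base + s * rel_x, y = ysign * cfg$stride_width / 2,
            z = z_heel)
    mk[[paste0(side, "HALL")]] <-
      cbind(x = x_base + s * rel_x_hall + s * 0.15,
            y = ysign * cfg$stride_width / 2, z = z_hall)
  }

  ## -- marker noise (after all structural draws) ----------------------------
  if (cfg$marker_noise_sd > 0) {
    for (lab in names(mk)) {
      if (lab == "COM") next   # direct CoM channel stays noise-free
      mk[[lab]] <- mk[[lab]] + matrix(rnorm(3L * nf, 0, cfg$marker_noise_sd),
                                      nf, 3L)
    }
  }

  ## -- ground truth ---------------------------------------------------------
  gt <- list()
  for (side in c("L", "R")) {
    tau <- strike_list[[side]]
    toes <- toe_list[[side]]
    other <- if (side == "L") "R" else "L"
    ns <- length(tau) - 1L
    for (k in seq_len(ns)) {
      t0 <- tau[k]; t1 <- tau[k + 1L]
      cyc <- t1 - t0
      st <- toes[k] - t0
      # double support via direct interval intersection with the other side
      o_tau <- strike_list[[other]]
      o_toe <- toe_list[[other]]
      # both-in-stance time: own stance is [t0, toe_off] within the stride;
      # indeterminate when no contralateral strike precedes the stride start
      if (min(o_tau) > t0) {
        ds <- NA_real_
      } else {
        ds <- 0
        for (j in seq_along(o_toe)) {
          lo <- max(t0, o_tau[j]); hi <- min(toes[k], o_toe[j])
          if (hi > lo) ds <- ds + (hi - lo)
        }
      }
      i0 <- as.integer(round(t0 / dt)) + 1L
      i1 <- as.integer(round(t1 / dt)) + 1L
      seg <- i0:i1
      ex <- oracle_exchange(e_pot_true[seg], e_kin_true[seg])
      gt[[paste(side, k)]] <- tibble(
        trial_id = trial_id, participant_id = prt$id, sex = prt$sex,
        substrate_id = sub$substrate_id, side = side, stride = k,
        start = t0, toe_off = toes[k], end = t1,
        cycle_time = cyc, stance_time = st, swing_time = cyc - st,
        double_support_time = ds, duty_factor = st / cyc,
        speed = (x_com[i1] - x_com[i0]) / (tt[i1] - tt[i0]),
        stride_length = abs(mk[[paste0(side, "HEE")]][i1, 1] -
                              mk[[paste0(side, "HEE")]][i0, 1]),
        stride_width = cfg$stride_width,
        heel_sink_depth = heel_depths[[side]][k],
        hallux_sink_depth = hall_depths[[side]][k],
        r_pct = ex$r_pct, ra = ex$ra, co_pct = ex$co_pct)
    }
  }
  truth_strides <- dplyr::bind_rows(gt)
  truth_roms <- dplyr::bind_rows(roms) |>
    mutate(trial_id = trial_id, participant_id = prt$id,
           substrate_id = sub$substrate_id, .before = 1)

  ## -- EMG -------------------------------------------------------------------
  emg_list <- list()
  truth_emg <- tibble()
  if (emg_on) {
    te <- seq(0, tt[nf], by = 1 / cfg$emg_rate)
    pe <- stride_phase(te, tau_l) / (2 * pi)
    rows <- list()
    for (mu in names(cfg$emg_bursts)) {
      env <- cfg$emg_amplitude * burst_envelope(cfg$emg_bursts[[mu]], pe)
      sigd <- env
      if (cfg$emg_noise_scale > 0) {
        noise <- rnorm(length(te))
        bf <- signal::butter(2, 20 / (cfg$emg_rate / 2), type = "high")
        noise <- as.numeric(signal::filter(bf, noise))
        noise <- noise / max(sd(noise), 1e-12)
        sigd <- env * (cfg$emg_noise_scale * noise)
      }
      drift <- cfg$emg_drift_amplitude *
        sin(2 * pi * cfg$emg_drift_freq * te + runif(1, 0, 2 * pi))
      emg_list[[mu]] <- sigd + drift
      for (k in seq_len(length(tau_l) - 1L)) {
        inseg <- te >= tau_l[k] & te <= tau_l[k + 1L]
        rows[[paste(mu, k)]] <- tibble(
          trial_id = trial_id, participant_id = prt$id,
          substrate_id = sub$substrate_id, muscle = mu, side = "L",
          stride = k, envelope_integral = trapz(te[inseg], env[inseg]))
      }
    }
    truth_emg <- dplyr::bind_rows(rows)
  }

  trial <- gait_trial(
    markers = mk, marker_rate = rate, emg = emg_list, emg_rate = cfg$emg_rate,
    trial_id = trial_id, participant_id = prt$id, sex = prt$sex,
    body_mass = prt$body_mass, height = prt$height,
    substrate_id = sub$substrate_id, substrate_surface_z = surf,
    travel_direction = s, t0 = 0)
  list(trial = trial,
       truth = list(strides = truth_strides, roms = truth_roms,
                    emg = truth_emg))
}

#' Simulate a multi-participant, multi-substrate study
#'
#' Draws participant attributes once (alternating sexes, body mass and
#' stature near the study cohort, a participant-level random intercept on
#' speed so mixed-model recovery is testable), then simulates every trial.
#' Deterministic given `cfg$seed`; per-trial seeds are derived so omitting
#' EMG does not perturb marker draws.
#'
#' @param cfg A [gait_sim_config()].
#' @param emg Generate EMG channels?
#' @return List with `trials` (list of [gait_trial()]), `truth` (list of
#'   bound tibbles `strides`, `roms`, `emg`) and `participants` (tibble).
#' @export
#' @examples
#' st <- simulate_study(gait_sim_config(n_participants = 2,
#'   trials_per_substrate = 1, seed = 7), emg = FALSE)
#' length(st$trials)
simulate_study <- function(cfg, emg = TRUE) {
  participants <- with_seed(cfg$seed, {
    n <- cfg$n_participants
    tibble(
      id = sprintf("P%02d", seq_len(n)),
      sex = ifelse(seq_len(n) %% 2L == 1L, "female", "male"),
      body_mass = pmax(45, rnorm(n, 68.5, 9.2)),
      height = pmax(1.5, rnorm(n, 1.73, 0.10)),
      speed_intercept = rnorm(n, 0, cfg$participant_speed_sd))
  })
  trials <- list()
  truth_s <- list(); truth_r <- list(); truth_e <- list()
  for (p in seq_len(cfg$n_participants)) {
    prt <- as.list(participants[p, ])
    for (si in seq_along(cfg$substrates)) {
      sub <- cfg$substrates[[si]]
      n_tr <- cfg$trials_per_substrate %||%
        (if (sub$heel_depth_mean > 0) 5L else 3L)
      if (n_tr < 1L) next
      for (tr in seq_len(n_tr)) {
        trial_id <- sprintf("%s_%s_T%d", prt$id, sub$substrate_id, tr)
        seed_tr <- (abs(cfg$seed) %% 65000L) * 32749L +
          p * 617L + si * 127L + tr
        seed_tr <- seed_tr %% 2147483647L
        out <- simulate_trial(cfg, prt, sub, seed = seed_tr,
                              trial_id = trial_id, emg = emg)
        trials[[trial_id]] <- out$trial
        truth_s[[trial_id]] <- out$truth$strides
        truth_r[[trial_id]] <- out$truth$roms
        truth_e[[trial_id]] <- out$truth$emg
      }
    }
  }
  list(trials = trials,
       truth = list(strides = dplyr::bind_rows(truth_s),
                    roms = dplyr::bind_rows(truth_r),
                    emg = dplyr::bind_rows(truth_e)),
       participants = participants)
}
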