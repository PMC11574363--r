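# Shared fixtures and independent oracles, built in code at test time.

# memoised heavy fixtures (per test run)
.sg_cache <- new.env(parent = emptyenv())
sg_cached <- function(key, expr) {
  if (!exists(key, envir = .sg_cache))
    assign(key, force(expr), envir = .sg_cache)
  get(key, envir = .sg_cache)
}

# the noise-free study at default conditions (21 participants, 3 floor + 5
# per sand trials); shared by events / spatiotemporal / sinkage /
# energetics checks
default_noisefree_study <- function() {
  sg_cached("study_nf", {
    cfg <- gait_sim_config(seed = 20240901, marker_noise_sd = 0)
    simulate_study(cfg, emg = FALSE)
  })
}

default_noisefree_processed <- function() {
  sg_cached("proc_nf", {
    st <- default_noisefree_study()
    process_study(st$trials, emg = FALSE)
  })
}

# unit-variance smooth Gaussian 1D fields (kernel normalised so the
# marginal variance is exactly 1)
smooth_gaussian_fields <- function(n, n_nodes, fwhm) {
  sk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sk)
  kern <- dnorm(seq(-pad, pad), sd = sk)
  kern <- kern / sqrt(sum(kern^2))
  t(vapply(seq_len(n), function(i) {
    stats::convolve(rnorm(n_nodes + 2 * pad), kern, type = "filter")
  }, numeric(n_nodes)))
}

# fraction of ground-truth events matched by a detected event within tol
event_accuracy <- function(trials, truth_strides, tol = 0.005) {
  hits <- 0L; tot <- 0L
  for (id in names(trials)) {
    ev <- detect_events(trials[[id]])
    g <- truth_strides[truth_strides$trial_id == id, ]
    for (sd_ in c("L", "R")) {
      det_hs <- ev$time[ev$side == sd_ & ev$event == "heel_strike"]
      det_to <- ev$time[ev$side == sd_ & ev$event == "toe_off"]
      gt_hs <- unique(c(g$start[g$side == sd_], g$end[g$side == sd_]))
      gt_to <- g$toe_off[g$side == sd_]
      tot <- tot + length(gt_hs) + length(gt_to)
      hits <- hits +
        sum(vapply(gt_hs, function(x)
          any(abs(det_hs - x) <= tol + 1e-9), logical(1))) +
        sum(vapply(gt_to, function(x)
          any(abs(det_to - x) <= tol + 1e-9), logical(1)))
    }
  }
  hits / tot
}

# a hand-built trial: SACR fixed at origin, heel/hallux relative x a
# sinusoid, flat z; enough structure for the event rule
sinusoid_trial <- function(duration = 5, rate = 200, amp = 0.3,
                           shift = 0) {
  tt <- seq(0, duration, by = 1 / rate)
  n <- length(tt)
  relx <- amp * sin(2 * pi * tt)
  zero <- rep(0, n)
  mk <- list(
    SACR = cbind(zero + shift, zero, zero + 1),
    LHEE = cbind(relx + shift, zero - 0.06, zero + 0.05),
    RHEE = cbind(-relx + shift, zero + 0.06, zero + 0.05),
    LHALL = cbind(relx + shift, zero - 0.06, zero + 0.03),
    RHALL = cbind(-relx + shift, zero + 0.06, zero + 0.03))
  gait_trial(mk, marker_rate = rate, trial_id = "sine",
             substrate_surface_z = 0)
}

# independent brute-force weighted-mean CoM (explicit loops)
com_loop_oracle <- function(trial, schema, table) {
  nf <- nrow(trial$markers[[1]])
  out <- matrix(0, nf, 3)
  for (fr in seq_len(nf)) {
    acc <- c(0, 0, 0)
    for (i in seq_len(nrow(table))) {
      pp <- trial$markers[[unname(schema[table$proximal_role[i]])]][fr, ]
      pd <- trial$markers[[unname(schema[table$distal_role[i]])]][fr, ]
      ci <- pp + table$com_fraction[i] * (pd - pp)
      acc <- acc + table$mass_fraction[i] * ci
    }
    out[fr, ] <- acc
  }
  out
}

# power-iteration leading eigenvector (independent of base eigen)
power_iter_ev <- function(m, iters = 2000) {
  v <- rep(1, ncol(m)) / sqrt(ncol(m))
  for (i in seq_len(iters)) {
    # shift to make the leading eigenvalue of the shifted matrix dominant
    v2 <- (m + diag(ncol(m)) * ncol(m)) %*% v
    v <- as.numeric(v2) / sqrt(sum(v2^2))
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}
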