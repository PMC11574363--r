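#' Whole-body centre of mass from the 13-segment model
#'
#' Each segment's CoM is `p_prox + f * (p_dist - p_prox)` with `f` the
#' segment's `com_fraction`; the body CoM is the mass-fraction-weighted sum
#' over segments. When the schema maps a `COM` role to a precomputed
#' whole-body CoM channel (e.g. exported by modelling software or by the
#' synthetic generator), that channel is returned directly (`use_direct =
#' TRUE`, the documented bypass).
#'
#' @param trial A [gait_trial()].
#' @param schema A [marker_schema()].
#' @param table An anthropometric table
#'   ([default_anthropometric_table()]).
#' @param use_direct Use a mapped `COM` channel when present?
#' @return A frames x 3 matrix (x, y, z in metres).
#' @export
body_com <- function(trial, schema = default_marker_schema(),
                     table = default_anthropometric_table(),
                     use_direct = TRUE) {
  if (use_direct) {
    direct <- schema_marker(trial, schema, "COM", required = FALSE)
    if (!is.null(direct)) return(direct)
  }
  validate_anthropometric_table(table)
  need <- unique(c(table$proximal_role, table$distal_role))
  have <- vapply(need, function(r)
    !is.null(schema_marker(trial, schema, r, required = FALSE)), logical(1))
  if (!all(have)) {
    missing_segs <- table$segment[
      !(table$proximal_role %in% need[have]) |
        !(table$distal_role %in% need[have])]
    abort(paste0("cannot compute segmental CoM; missing endpoint role(s) ",
                 paste(need[!have], collapse = ", "),
                 " for segment(s): ", paste(missing_segs, collapse = ", ")))
  }
  nf <- nrow(trial$markers[[1]])
  com <- matrix(0, nf, 3L)
  for (i in seq_len(nrow(table))) {
    pp <- schema_marker(trial, schema, table$proximal_role[i])
    pd <- schema_marker(trial, schema, table$distal_role[i])
    seg_com <- pp + table$com_fraction[i] * (pd - pp)
    com <- com + table$mass_fraction[i] * seg_com
  }
  colnames(com) <- c("x", "y", "z")
  com
}

#' Potential, kinetic and total CoM energy series
#'
#' `E_pot = m g z` (g = 9.81 m/s^2); CoM velocity by central differences
#' (one-sided at the ends) on the low-pass-filtered CoM trajectory
#' (zero-phase linear-phase FIR with a flat passband);
#' `E_kin = m |v|^2 / 2` over all three velocity components (set
#' `components = c("x", "z")` for sagittal-only); `E_tot = E_pot + E_kin`
#' exactly.
#'
#' @param com Frames x 3 CoM matrix (m).
#' @param body_mass Mass, kg.
#' @param rate Sampling rate, Hz.
#' @param lowpass_hz Zero-phase low-pass cutoff before differentiation
#'   (default 10 Hz; `NULL`/0 disables).
#' @param components Velocity components entering `E_kin`.
#' @return A tibble of class `energy_series`: `time`, `e_pot`, `e_kin`,
#'   `e_tot` (J).
#' @export
com_energies <- function(com, body_mass, rate, lowpass_hz = 10,
                         components = c("x", "y", "z")) {
  assert_that(nrow(com) >= 5L, "need at least 5 CoM samples")
  assert_that(rate > 0, "rate must be > 0")
  g <- 9.81
  # linear-phase FIR: flat passband so stride-frequency velocity content
  # is preserved (the exchange statistics are sensitive to the kinetic
  # amplitude and to the sample-level sign of its increments)
  comf <- apply(com, 2, fir_lowpass_zero_phase, rate = rate,
                cutoff_hz = lowpass_hz)
  vel <- apply(comf, 2, central_diff, dt = 1 / rate)
  colnames(vel) <- c("x", "y", "z")
  idx <- match(components, colnames(vel))
  e_pot <- body_mass * g * com[, 3]
  e_kin <- 0.5 * body_mass * rowSums(vel[, idx, drop = FALSE]^2)
  out <- tibble(time = (seq_len(nrow(com)) - 1) / rate,
                e_pot = e_pot, e_kin = e_kin, e_tot = e_pot + e_kin)
  class(out) <- c("energy_series", class(out))
  out
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Pendular energy-exchange statistics for one stride
#'
#' With sample-to-sample increments: `W_v` = sum of positive potential
#' increments, `W_f` = sum of positive kinetic increments, `W_ext` = sum of
#' positive total-energy increments (the external-work convention), then
#' recovery `R = 100 (W_v + W_f - W_ext) / (W_v + W_f)` (%), relative
#' amplitude `RA` = peak-to-peak `E_pot` / peak-to-peak `E_kin`, and
#' congruity `CO` = percentage of samples where the two energies move in the
#' same direction, among samples where both move (increments with magnitude
#' below 1e-12 J are treated as zero).
#'
#' @param es An [com_energies()] tibble (or any tibble with `e_pot`,
#'   `e_kin`), cropped to one stride.
#' @return A one-row tibble: `r_pct`, `ra`, `co_pct`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 400)
#' es <- tibble::tibble(e_pot = 10 * sin(2 * pi * t),
#'                      e_kin = -10 * sin(2 * pi * t) + 20)
#' exchange_metrics(es) # R = 100, RA = 1, CO = 0
exchange_metrics <- function(es) {
  tol <- 1e-12
  dp <- diff(es$e_pot)
  dk <- diff(es$e_kin)
  dtot <- dp + dk
  wv <- sum(dp[dp > 0])
  wf <- sum(dk[dk > 0])
  wext <- sum(dtot[dtot > 0])
  if (wv + wf <= tol)
    abort("R undefined: both energy series are constant over the stride")
  if (max(es$e_kin) - min(es$e_kin) <= tol)
    abort("RA undefined: kinetic energy is constant over the stride")
  moving <- abs(dp) > tol & abs(dk) > tol
  co <- if (any(moving))
    100 * mean(sign(dp[moving]) == sign(dk[moving])) else NA_real_
  tibble(r_pct = 100 * (wv + wf - wext) / (wv + wf),
         ra = (max(es$e_pot) - min(es$e_pot)) /
              (max(es$e_kin) - min(es$e_kin)),
         co_pct = co)
}

#' Per-stride CoM energetics for a trial
#'
#' Computes the CoM (13-segment model or direct channel), the energy series,
#' and the exchange statistics for every valid stride; optionally also the
#' per-stride energy curves normalised to 101 gait-cycle nodes for plotting
#' group means.
#'
#' @param trial A [gait_trial()].
#' @param strides A [build_strides()] result.
#' @param schema,table,lowpass_hz,use_direct See [body_com()] and
#'   [com_energies()].
#' @param keep_curves Also return 101-node energy curves?
#' @return A tibble of per-stride metrics (identifiers + `r_pct`, `ra`,
#'   `co_pct`); when `keep_curves`, a list with `metrics` and `curves`.
#' @export
stride_energetics <- function(trial, strides,
                              schema = default_marker_schema(),
                              table = default_anthropometric_table(),
                              lowpass_hz = 10, use_direct = TRUE,
                              keep_curves = FALSE) {
  com <- body_com(trial, schema, table, use_direct = use_direct)
  es <- com_energies(com, trial$body_mass, trial$marker_rate,
                     lowpass_hz = lowpass_hz)
  es$time <- marker_times(trial)
  rows <- list(); curves <- list()
  for (i in seq_len(nrow(strides))) {
    st <- strides[i, ]
    if (!isTRUE(st$valid)) next
    seg <- es[es$time >= st$start - 1e-9 & es$time <= st$end + 1e-9, ]
    met <- exchange_metrics(seg)
    rows[[i]] <- tibble(trial_id = trial$trial_id,
                        participant_id = trial$participant_id,
                        substrate_id = trial$substrate_id,
                        side = st$side, stride = st$stride) |>
      dplyr::bind_cols(met)
    if (keep_curves) {
      st_row <- st
      curves[[i]] <- purrr::map_dfr(c("e_pot", "e_kin", "e_tot"), function(v) {
        tibble(trial_id = trial$trial_id, side = st$side,
               stride = st$stride, substrate_id = trial$substrate_id,
               variable = v, node = 0:100,
               value = normalize_cycle(seg$time, seg[[v]], st_row))
      })
    }
  }
  metrics <- bind_rows(rows)
  if (keep_curves) list(metrics = metrics, curves = bind_rows(curves))
  else metrics
}
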