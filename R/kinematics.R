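#' Signed sagittal-plane joint angle
#'
#' Angle between the proximal->joint and joint->distal segment vectors after
#' projection on the plane of progression (lab x-z), mapped to the clinical
#' convention: hip and knee flexion positive, ankle dorsiflexion positive
#' with the shank-foot angle offset by 90 degrees so anatomical neutral
#' reads 0. Frames where either projected segment is shorter than 1 mm
#' yield `NA`.
#'
#' @param proximal,joint,distal Frames x 3 point series (m).
#' @param convention `"hip"`, `"knee"` or `"ankle"`.
#' @param travel_direction +1 or -1 (sign of progression along lab x).
#' @return Numeric vector of angles, degrees.
#' @export
#' @examples
#' # straight leg: collinear hip-knee-ankle -> knee angle 0
#' n <- 5
#' hip <- cbind(0, 0, rep(1, n)); knee <- cbind(0, 0, rep(0.55, n))
#' ank <- cbind(0, 0, rep(0.1, n))
#' sagittal_angle(hip, knee, ank, "knee")
sagittal_angle <- function(proximal, joint, distal,
                           convention = c("hip", "knee", "ankle"),
                           travel_direction = 1) {
  convention <- match.arg(convention)
  s <- travel_direction
  ux <- joint[, 1] - proximal[, 1]; uz <- joint[, 3] - proximal[, 3]
  vx <- distal[, 1] - joint[, 1];   vz <- distal[, 3] - joint[, 3]
  lu <- sqrt(ux^2 + uz^2); lv <- sqrt(vx^2 + vz^2)
  bad <- lu < 1e-3 | lv < 1e-3
  raw <- atan2(s * (uz * vx - ux * vz), ux * vx + uz * vz) * 180 / pi
  ang <- switch(convention,
                hip = -raw,
                knee = raw,
                ankle = -(raw + 90))
  # keep ankle in (-180, 180]
  if (convention == "ankle") ang <- ((ang + 180) %% 360) - 180
  ang[bad] <- NA_real_
  ang
}

#' Normalise a per-stride series to 101 gait-cycle nodes
#'
#' Cubic-spline interpolation onto nodes 0, 1, ..., 100 % of the cycle
#' (node 0 at the ipsilateral heel-strike); endpoints on the sampling grid
#' are preserved exactly, and the interpolant is exact on cubic
#' polynomials.
#'
#' @param time Sample times, s (must cover the stride).
#' @param values Sample values.
#' @param stride One-row stride (with `start` and `end`), or a list with
#'   those fields.
#' @return Numeric vector of length 101.
#' @export
normalize_cycle <- function(time, values, stride) {
  t0 <- stride$start; t1 <- stride$end
  assert_that(t0 >= min(time) - 1e-9 && t1 <= max(time) + 1e-9,
              "stride extends beyond the series (bounds error)")
  nodes <- seq(t0, t1, length.out = 101L)
  ok <- is.finite(values)
  assert_that(sum(ok) >= 4L, "need at least 4 finite samples to interpolate")
  stats::spline(time[ok], values[ok], xout = nodes, method = "fmm")$y
}

#' Joint range of motion per trial
#'
#' ROM = maximum minus minimum joint angle over the whole trial (not per
#' stride), per joint.
#'
#' @param angles Named list (or tibble columns) of angle series, degrees.
#' @return A tibble: `joint`, `rom` (deg), `n_missing`.
#' @export
rom_per_trial <- function(angles) {
  purrr::imap_dfr(angles, function(a, j) {
    fin <- a[is.finite(a)]
    tibble(joint = j,
           rom = if (length(fin)) max(fin) - min(fin) else NA_real_,
           n_missing = sum(!is.finite(a)))
  })
}

#' Sagittal hip/knee/ankle curves and ROMs for a trial
#'
#' Computes the three sagittal joint-angle series per side from joint-centre
#' markers, crops each valid stride and normalises it to 101 nodes, and
#' derives per-trial ROMs.
#'
#' @param trial A [gait_trial()].
#' @param strides A [build_strides()] result.
#' @param schema A [marker_schema()] mapping `NECK`, per-side `HIP`,
#'   `KNEE`, `ANK`, `TOE`.
#' @return List with `curves` (long tibble: identifiers, `side`, `stride`,
#'   `joint`, `node`, `angle_deg`) and `roms` (per trial, side and joint).
#' @export
joint_angle_curves <- function(trial, strides,
                               schema = default_marker_schema()) {
  tt <- marker_times(trial)
  s <- trial$travel_direction
  neck <- schema_marker(trial, schema, "NECK")
  curves <- list(); roms <- list()
  for (sd_ in c("L", "R")) {
    hip <- schema_marker(trial, schema, paste0(sd_, "HIP"))
    knee <- schema_marker(trial, schema, paste0(sd_, "KNEE"))
    ank <- schema_marker(trial, schema, paste0(sd_, "ANK"))
    toe <- schema_marker(trial, schema, paste0(sd_, "TOE"))
    ang <- list(
      hip = sagittal_angle(neck, hip, knee, "hip", s),
      knee = sagittal_angle(hip, knee, ank, "knee", s),
      ankle = sagittal_angle(knee, ank, toe, "ankle", s))
    roms[[sd_]] <- rom_per_trial(ang) |>
      mutate(trial_id = trial$trial_id,
             participant_id = trial$participant_id,
             substrate_id = trial$substrate_id, side = sd_, .before = 1)
    sstr <- strides[strides$side == sd_ & strides$valid, ]
    for (i in seq_len(nrow(sstr))) {
      st <- sstr[i, ]
      for (j in names(ang)) {
        curves[[paste(sd_, st$stride, j)]] <- tibble(
          trial_id = trial$trial_id,
          participant_id = trial$participant_id,
          substrate_id = trial$substrate_id,
          side = sd_, stride = st$stride, joint = j, node = 0:100,
          angle_deg = normalize_cycle(tt, ang[[j]], st))
      }
    }
  }
  list(curves = bind_rows(curves), roms = bind_rows(roms))
}
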