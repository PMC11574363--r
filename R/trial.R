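#' Construct a walking-trial recording
#'
#' A `gait_trial` bundles the synchronised streams of one walking pass:
#' motion-capture marker trajectories (lab frame, metres, z up, z = 0 at the
#' hard lab floor), surface EMG channels (volts), and trial metadata. All
#' internal positions are metres, times seconds, angles degrees, masses kg.
#'
#' @param markers Named list of numeric matrices (frames x 3, columns
#'   x/y/z in metres), all with the same number of frames; or a long tibble
#'   with columns `time`, `label`, `x`, `y`, `z`.
#' @param marker_rate Marker sampling rate in Hz (default 200).
#' @param emg Named list of numeric vectors (volts), all equal length. May be
#'   empty.
#' @param emg_rate EMG sampling rate in Hz (default 1110).
#' @param trial_id,participant_id Identifiers.
#' @param sex `"male"` or `"female"`.
#' @param body_mass Body mass, kg (> 0).
#' @param height Stature, m.
#' @param substrate_id Substrate identifier, conventionally one of
#'   `"hard_floor"`, `"wet_building_sand"`, `"dry_building_sand"`,
#'   `"play_sand"`, or user-defined.
#' @param substrate_surface_z Height of the walking surface above the lab
#'   floor (z = 0), metres, non-negative.
#' @param travel_direction `+1` or `-1`: sign of progression along lab x.
#' @param t0 Shared clock origin (s) for both streams.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(markers,
                       marker_rate = 200,
                       emg = list(),
                       emg_rate = 1110,
                       trial_id = "trial",
                       participant_id = "P01",
                       sex = c("female", "male"),
                       body_mass = 70,
                       height = 1.73,
                       substrate_id = "hard_floor",
                       substrate_surface_z = 0,
                       travel_direction = 1,
                       t0 = 0) {
  sex <- match.arg(sex)
  if (is.data.frame(markers)) markers <- markers_long_to_list(markers)
  assert_that(length(markers) > 0L, "at least one marker series is required")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    assert_that(ncol(m) == 3L, "marker series must have 3 columns (x, y, z)")
    colnames(m) <- c("x", "y", "z")
    storage.mode(m) <- "double"
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  assert_that(length(unique(nf)) == 1L,
              "all marker series must have identical length")
  if (length(emg)) {
    ne <- vapply(emg, length, integer(1))
    assert_that(length(unique(ne)) == 1L,
                "all EMG series must have identical length")
  }
  assert_that(marker_rate > 0 && emg_rate > 0, "sampling rates must be > 0")
  assert_that(substrate_surface_z >= 0, "substrate_surface_z must be >= 0")
  assert_that(body_mass > 0, "body_mass must be > 0")
  assert_that(travel_direction %in% c(-1, 1),
              "travel_direction must be +1 or -1")
  structure(
    list(markers = markers, marker_rate = marker_rate,
         emg = emg, emg_rate = emg_rate,
         trial_id = trial_id, participant_id = participant_id, sex = sex,
         body_mass = body_mass, height = height,
         substrate_id = substrate_id,
         substrate_surface_z = substrate_surface_z,
         travel_direction = travel_direction, t0 = t0),
    class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial %s> participant %s (%s) on %s\n",
              x$trial_id, x$participant_id, x$sex, x$substrate_id))
  cat(sprintf("  %d markers x %d frames @ %g Hz; %d EMG channels @ %g Hz\n",
              length(x$markers), nrow(x$markers[[1]]), x$marker_rate,
              length(x$emg), x$emg_rate))
  cat(sprintf("  surface z = %g m, travel %+d, mass %g kg\n",
              x$substrate_surface_z, x$travel_direction, x$body_mass))
  invisible(x)
}

#' Marker frame times of a trial
#' @param trial A [gait_trial()].
#' @return Numeric vector of times (s) for the marker stream.
#' @export
marker_times <- function(trial) {
  trial$t0 + (seq_len(nrow(trial$markers[[1]])) - 1L) / trial$marker_rate
}

#' EMG sample times of a trial
#' @param trial A [gait_trial()].
#' @return Numeric vector of times (s) for the EMG stream (length 0 when the
#'   trial carries no EMG).
#' @export
emg_times <- function(trial) {
  if (!length(trial$emg)) return(numeric(0))
  trial$t0 + (seq_len(length(trial$emg[[1]])) - 1L) / trial$emg_rate
}

#' Tidy view of a trial's marker trajectories
#' @param x A [gait_trial()].
#' @param ... Unused.
#' @return A long tibble with columns `time`, `label`, `x`, `y`, `z`.
#' @export
as_tibble.gait_trial <- function(x, ...) {
  tt <- marker_times(x)
  purrr::imap_dfr(x$markers, function(m, lab) {
    tibble(time = tt, label = lab, x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

markers_long_to_list <- function(df) {
  need <- c("time", "label", "x", "y", "z")
  assert_that(all(need %in% names(df)),
              "long marker table needs columns time, label, x, y, z")
  split(df[c("time", "x", "y", "z")], df$label) |>
    lapply(function(d) {
      d <- d[order(d$time), ]
      as.matrix(d[c("x", "y", "z")])
    })
}

#' Define a marker schema
#'
#' Maps the semantic roles the pipeline needs onto the labels present in a
#' trial. Required roles: `SACR` (pelvis origin), `LHEE`/`RHEE` (calcaneus)
#' and `LHALL`/`RHALL` (hallux). Optional roles add per-side joint centres
#' (`LHIP`, `LKNEE`, `LANK`, `LTOE`, ... and right-side counterparts) plus
#' `NECK`, `HEAD`, shoulders/elbows/wrists for the 13-segment model, and an
#' optional `COM` role naming a precomputed whole-body CoM channel.
#'
#' @param ... Named role = label pairs, e.g. `SACR = "SACR"`,
#'   `LHEE = "LHeel"`.
#' @param .roles Alternatively, a named character vector of role = label.
#' @return A named character vector of class `marker_schema`.
#' @export
#' @examples
#' sch <- marker_schema(SACR = "SACR", LHEE = "LHEE", RHEE = "RHEE",
#'                      LHALL = "LHALL", RHALL = "RHALL")
marker_schema <- function(..., .roles = NULL) {
  roles <- .roles %||% unlist(list(...))
  assert_that(length(roles) > 0L && !is.null(names(roles)),
              "marker_schema needs named role = label pairs")
  required <- c("SACR", "LHEE", "RHEE", "LHALL", "RHALL")
  missing_roles <- setdiff(required, names(roles))
  assert_that(length(missing_roles) == 0L,
              paste0("marker schema missing required role(s): ",
                     paste(missing_roles, collapse = ", ")))
  dup <- roles[duplicated(roles)]
  assert_that(length(dup) == 0L,
              paste0("label mapped to two roles: ",
                     paste(unique(dup), collapse = ", ")))
  structure(roles, class = "marker_schema")
}

#' Default marker schema for synthetic trials
#'
#' Identity mapping for the labels emitted by [simulate_trial()]: sinkage and
#' event roles, per-side joint centres, trunk/head/arm endpoints for the
#' 13-segment model, and the generator's direct `COM` channel.
#' @return A `marker_schema`.
#' @export
default_marker_schema <- function() {
  labs <- c("SACR", "LHEE", "RHEE", "LHALL", "RHALL",
            "LHIP", "RHIP", "LKNEE", "RKNEE", "LANK", "RANK", "LTOE", "RTOE",
            "NECK", "HEAD", "LSHO", "RSHO", "LELB", "RELB", "LWRI", "RWRI",
            "COM")
  marker_schema(.roles = setNames(labs, labs))
}

# Resolve a role to a marker matrix; errors name the role and label.
schema_marker <- function(trial, schema, role, required = TRUE) {
  lab <- unname(schema[role])
  if (is.na(lab) || is.null(lab)) {
    if (required) abort(sprintf("schema does not map required role '%s'", role))
    return(NULL)
  }
  m <- trial$markers[[lab]]
  if (is.null(m)) {
    if (required)
      abort(sprintf("trial has no marker '%s' (schema role '%s')", lab, role))
    return(NULL)
  }
  m
}

#' Read a walking trial from long-format text tables
#'
#' Markers come from a CSV with columns `time`, `label`, `x`, `y`, `z`
#' (metres); EMG, when given, from a CSV with columns `time`, `muscle`,
#' `value` (volts). Sampling must be uniform within 1e-6 s jitter; rates are
#' inferred from the time stamps.
#'
#' @param markers_path Path to the marker CSV.
#' @param emg_path Optional path to the EMG CSV (`NULL` for none).
#' @param ... Trial metadata passed on to [gait_trial()] (`participant_id`,
#'   `body_mass`, `substrate_id`, `substrate_surface_z`, ...).
#' @return A [gait_trial()].
#' @export
read_tabular_trial <- function(markers_path, emg_path = NULL, ...) {
  mk <- readr::read_csv(markers_path, comment = "#", show_col_types = FALSE)
  need <- c("time", "label", "x", "y", "z")
  assert_that(all(need %in% names(mk)),
              "marker table needs columns time, label, x, y, z")
  assert_that(!anyDuplicated(mk[c("time", "label")]),
              "duplicate (time, label) rows in marker table")
  times <- sort(unique(mk$time))
  rate <- uniform_rate(times, what = "marker")
  markers <- markers_long_to_list(mk)
  nf <- vapply(markers, nrow, integer(1))
  assert_that(length(unique(nf)) == 1L && unique(nf) == length(times),
              "every marker label must be sampled at every time stamp")
  emg <- list()
  emg_rate <- 1110
  if (!is.null(emg_path)) {
    ed <- readr::read_csv(emg_path, comment = "#", show_col_types = FALSE)
    assert_that(all(c("time", "muscle", "value") %in% names(ed)),
                "EMG table needs columns time, muscle, value")
    assert_that(!anyDuplicated(ed[c("time", "muscle")]),
                "duplicate (time, muscle) rows in EMG table")
    etimes <- sort(unique(ed$time))
    emg_rate <- uniform_rate(etimes, what = "EMG")
    emg <- split(ed[c("time", "value")], ed$muscle) |>
      lapply(function(d) d$value[order(d$time)])
  }
  gait_trial(markers = markers, marker_rate = rate,
             emg = emg, emg_rate = emg_rate, t0 = times[1], ...)
}

uniform_rate <- function(times, what = "marker", jitter = 1e-6) {
  assert_that(length(times) >= 2L,
              sprintf("%s stream needs at least 2 time stamps", what))
  dt <- diff(times)
  med <- median(dt)
  if (any(abs(dt - med) > jitter))
    abort(sprintf("%s sampling is not uniform (max jitter %.3g s > %.0e s)",
                  what, max(abs(dt - med)), jitter))
  1 / med
}

#' Write a trial to the long-format text tables
#'
#' Inverse of [read_tabular_trial()]: marker samples round-trip to 1e-9 m.
#'
#' @param trial A [gait_trial()].
#' @param markers_path Destination CSV for markers.
#' @param emg_path Optional destination CSV for EMG channels.
#' @return `trial`, invisibly.
#' @export
write_tabular_trial <- function(trial, markers_path, emg_path = NULL) {
  readr::write_csv(as_tibble.gait_trial(trial), markers_path)
  if (!is.null(emg_path) && length(trial$emg)) {
    tt <- emg_times(trial)
    ed <- purrr::imap_dfr(trial$emg, function(v, mu)
      tibble(time = tt, muscle = mu, value = v))
    readr::write_csv(ed, emg_path)
  }
  invisible(trial)
}
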