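#' Detect heel-strikes and toe-offs from marker coordinates
#'
#' Implements the coordinate-based event rule: a heel-strike is a local
#' maximum of the heel's progression-axis position relative to the sacral
#' marker (signed by travel direction), and a toe-off is a local minimum of
#' the hallux's relative position. The relative-position signals are
#' low-pass filtered (zero-phase) before peak-picking; candidate peaks must
#' be separated by at least `min_separation` seconds (default: half the
#' dominant period of the signal). Toe-offs outside the span of detected
#' heel-strikes (partial cycles) are discarded.
#'
#' @param trial A [gait_trial()].
#' @param schema A [marker_schema()] mapping `SACR`, `LHEE`/`RHEE`,
#'   `LHALL`/`RHALL`.
#' @param min_separation Minimum event separation, s (`NULL`: estimated from
#'   the signal's dominant frequency).
#' @param lowpass_hz Zero-phase low-pass cutoff applied to the relative
#'   signals before peak-picking (default 10 Hz).
#' @return A tibble of class `gait_events` with columns `side`, `event`
#'   (`"heel_strike"`/`"toe_off"`), `time` (s) and `frame`.
#' @export
detect_events <- function(trial, schema = default_marker_schema(),
                          min_separation = NULL, lowpass_hz = 10) {
  rate <- trial$marker_rate
  tt <- marker_times(trial)
  assert_that(length(tt) >= 2 * rate, "need at least 2 s of marker data")
  s <- trial$travel_direction
  sacr <- schema_marker(trial, schema, "SACR")
  out <- list()
  for (side in c("L", "R")) {
    heel <- schema_marker(trial, schema, paste0(side, "HEE"))
    hall <- schema_marker(trial, schema, paste0(side, "HALL"))
    rel_heel <- s * (heel[, 1] - sacr[, 1])
    rel_hall <- s * (hall[, 1] - sacr[, 1])
    rel_heel_f <- lowpass_zero_phase(rel_heel, rate, lowpass_hz)
    rel_hall_f <- lowpass_zero_phase(rel_hall, rate, lowpass_hz)
    sep_s <- min_separation %||% (0.5 / dominant_freq(rel_heel_f, rate))
    sep <- max(3L, as.integer(round(sep_s * rate)))
    guard <- max(2L, as.integer(round(0.25 * sep)))
    hs <- find_peaks(rel_heel_f, min_sep = sep)
    hs <- hs[hs > guard & hs <= length(tt) - guard]
    if (length(hs) < 2L)
      abort(sprintf("no strides: fewer than 2 heel-strikes detected on side %s",
                    side))
    to <- find_peaks(-rel_hall_f, min_sep = sep)
    to <- to[to > guard & to <= length(tt) - guard]
    to <- to[to > min(hs) & to < max(hs)]
    out[[side]] <- bind_rows(
      tibble(side = side, event = "heel_strike", frame = hs, time = tt[hs]),
      tibble(side = side, event = "toe_off", frame = to, time = tt[to]))
  }
  ev <- bind_rows(out) |> arrange(.data$side, .data$time)
  attr(ev, "marker_rate") <- rate
  class(ev) <- c("gait_events", class(ev))
  ev
}

# dominant frequency (Hz) of a detrended signal by FFT argmax in (0.2, 5] Hz
dominant_freq <- function(x, rate) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  fr <- (seq_len(n %/% 2) - 1) * rate / n
  band <- fr > 0.2 & fr <= 5
  if (!any(band)) return(1)
  fr[band][which.max(sp[band])]
}

#' Per-trial event quality-control report
#'
#' Summarises event counts per side and flags cycle-time outliers (beyond 3
#' median absolute deviations of the side's median cycle time), standing in
#' for the manual event checks used in lab practice.
#'
#' @param events A [detect_events()] result.
#' @return A tibble with one row per side: event counts, median cycle time
#'   and the number of flagged cycles.
#' @export
event_qc <- function(events) {
  purrr::map_dfr(unique(events$side), function(sd_) {
    hs <- sort(events$time[events$side == sd_ &
                             events$event == "heel_strike"])
    nto <- sum(events$side == sd_ & events$event == "toe_off")
    ct <- diff(hs)
    md <- median(ct)
    madv <- median(abs(ct - md))
    tibble(side = sd_, n_heel_strikes = length(hs), n_toe_offs = nto,
           median_cycle_s = md,
           n_cycle_outliers = if (madv == 0) 0L
                              else sum(abs(ct - md) > 3 * madv))
  })
}

#' Build strides from detected gait events
#'
#' One stride per consecutive ipsilateral heel-strike pair. A stride is
#' marked invalid (with a reason) when it lacks exactly one interior toe-off
#' or when a required marker has missing samples inside the window.
#'
#' @param events A [detect_events()] result (or a tibble with the same
#'   columns).
#' @param trial The [gait_trial()] the events came from (used for gap
#'   checks); may be `NULL` to skip them.
#' @param schema Schema used for gap checks.
#' @return A tibble of class `stride_set`: `side`, `stride`, `start`,
#'   `toe_off`, `end` (s), `valid`, `reason`.
#' @export
build_strides <- function(events, trial = NULL,
                          schema = default_marker_schema()) {
  res <- list()
  for (sd_ in unique(events$side)) {
    hs <- sort(events$time[events$side == sd_ &
                             events$event == "heel_strike"])
    to <- sort(events$time[events$side == sd_ & events$event == "toe_off"])
    if (length(hs) < 2L) next
    for (k in seq_len(length(hs) - 1L)) {
      t0 <- hs[k]; t1 <- hs[k + 1L]
      inner <- to[to > t0 & to < t1]
      valid <- TRUE; reason <- NA_character_; toff <- NA_real_
      if (length(inner) != 1L) {
        valid <- FALSE
        reason <- if (length(inner) == 0L) "no interior toe-off"
                  else "multiple interior toe-offs"
      } else toff <- inner
      if (valid && !is.null(trial)) {
        tt <- marker_times(trial)
        win <- tt >= t0 & tt <= t1
        for (role in c("SACR", paste0(sd_, "HEE"), paste0(sd_, "HALL"))) {
          m <- schema_marker(trial, schema, role, required = FALSE)
          if (!is.null(m) && anyNA(m[win, ])) {
            valid <- FALSE; reason <- sprintf("marker gap in %s", role)
            break
          }
        }
      }
      res[[paste(sd_, k)]] <- tibble(side = sd_, stride = k, start = t0,
                                     toe_off = toff, end = t1,
                                     valid = valid, reason = reason)
    }
  }
  out <- bind_rows(res)
  if (nrow(out)) class(out) <- c("stride_set", class(out))
  out
}
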