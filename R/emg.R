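#' High-pass filter and rectify a raw EMG channel
#'
#' Second-order Butterworth high-pass at 12 Hz, applied forward-backward
#' (zero phase; effective 4th order) by default, then full-wave rectified.
#' A single forward pass is available for strict phase-preserving
#' comparisons with single-pass chains.
#'
#' @param raw Raw EMG samples, volts.
#' @param rate Sampling rate, Hz (> 2 x cutoff).
#' @param cutoff_hz High-pass cutoff (default 12 Hz).
#' @param zero_phase Forward-backward application (default `TRUE`).
#' @return Rectified series, volts.
#' @export
filter_rectify <- function(raw, rate, cutoff_hz = 12, zero_phase = TRUE) {
  assert_that(rate > 2 * cutoff_hz,
              "sampling rate must exceed twice the high-pass cutoff")
  assert_that(length(raw) >= rate,
              "need at least 1 s of EMG data to filter")
  settle <- ceiling(3 * rate / cutoff_hz)
  assert_that(length(raw) >= settle,
              "series shorter than 3 filter settling lengths")
  filt <- if (zero_phase) {
    butter_zero_phase(raw, rate, cutoff_hz, 2L, "high")
  } else {
    bf <- signal::butter(2, cutoff_hz / (rate / 2), type = "high")
    as.numeric(signal::filter(bf, raw))
  }
  abs(filt)
}

#' Normalise rectified EMG to a participant's maximum
#'
#' Every sample of every trial is divided by the single maximum rectified
#' amplitude observed across all of that participant's trials for the same
#' muscle, so the participant-level maximum of the normalised signal (nEMG)
#' is exactly 1. Idempotent.
#'
#' @param rectified_trials List (one element per trial) of rectified series
#'   for one muscle of one participant.
#' @return List of normalised series (same shape).
#' @export
normalize_participant <- function(rectified_trials) {
  mx <- max(vapply(rectified_trials, function(v) max(abs(v)), numeric(1)))
  if (mx <= 0) abort("normalization undefined: channel is all zero")
  lapply(rectified_trials, function(v) v / mx)
}

#' Integrated EMG over one stride
#'
#' Trapezoidal integral of the normalised envelope over the stride's real
#' time span; units are normalised amplitude x seconds. Set
#' `cycle_normalized = TRUE` to divide by stride duration instead
#' (unitless mean activation).
#'
#' @param nemg Normalised EMG series.
#' @param times Sample times, s (same length), or `NULL` with `rate`.
#' @param stride One-row stride (fields `start`, `end`).
#' @param rate Sampling rate, used when `times` is `NULL` (t = 0 at the
#'   first sample).
#' @param cycle_normalized Divide the integral by stride duration?
#' @return Scalar iEMG.
#' @export
iemg_per_stride <- function(nemg, stride, times = NULL, rate = NULL,
                            cycle_normalized = FALSE) {
  if (is.null(times)) {
    assert_that(!is.null(rate), "supply either times or rate")
    times <- (seq_along(nemg) - 1) / rate
  }
  assert_that(stride$start >= times[1] - 1e-9 &&
                stride$end <= times[length(times)] + 1e-9,
              "stride lies outside the EMG series (bounds error)")
  sel <- times >= stride$start - 1e-9 & times <= stride$end + 1e-9
  val <- trapz(times[sel], nemg[sel])
  if (cycle_normalized) val / (stride$end - stride$start) else val
}

#' Per-stride EMG processing for a set of trials
#'
#' Runs the full chain for each participant and muscle: high-pass filter +
#' rectify each trial, normalise to the participant's maximum across all
#' their trials, then per valid stride compute iEMG and the 101-node nEMG
#' curve (rectified samples averaged within each of 101 gait-cycle bins; no
#' envelope smoothing is applied before integration).
#'
#' @param trials Named list of [gait_trial()]s.
#' @param strides_by_trial Named list of [build_strides()] results matching
#'   `trials`.
#' @param cutoff_hz,zero_phase Passed to [filter_rectify()].
#' @param cycle_normalized Passed to [iemg_per_stride()].
#' @return List with `iemg` (tibble: identifiers, muscle, side, stride,
#'   `iemg`) and `curves` (tibble: identifiers, muscle, stride, `node`,
#'   `nemg`).
#' @export
process_emg <- function(trials, strides_by_trial, cutoff_hz = 12,
                        zero_phase = TRUE, cycle_normalized = FALSE) {
  participants <- unique(vapply(trials, `[[`, character(1),
                                "participant_id"))
  iemg_rows <- list(); curve_rows <- list()
  for (p in participants) {
    ptrials <- trials[vapply(trials, function(x)
      x$participant_id == p, logical(1))]
    muscles <- unique(unlist(lapply(ptrials, function(x) names(x$emg))))
    for (mu in muscles) {
      have <- names(ptrials)[vapply(ptrials, function(x)
        mu %in% names(x$emg), logical(1))]
      rect <- lapply(ptrials[have], function(x)
        filter_rectify(x$emg[[mu]], x$emg_rate, cutoff_hz, zero_phase))
      nemg <- normalize_participant(rect)
      for (id in have) {
        tr <- ptrials[[id]]
        strides <- strides_by_trial[[id]]
        if (is.null(strides) || !nrow(strides)) next
        te <- emg_times(tr)
        sig <- nemg[[id]]
        sl <- strides[strides$valid & strides$side == "L", ]
        for (i in seq_len(nrow(sl))) {
          st <- sl[i, ]
          iemg_rows[[paste(id, mu, i)]] <- tibble(
            trial_id = id, participant_id = p,
            substrate_id = tr$substrate_id, muscle = mu,
            side = st$side, stride = st$stride,
            iemg = iemg_per_stride(sig, st, times = te,
                                   cycle_normalized = cycle_normalized))
          curve_rows[[paste(id, mu, i)]] <- tibble(
            trial_id = id, participant_id = p,
            substrate_id = tr$substrate_id, muscle = mu,
            side = st$side, stride = st$stride, node = 0:100,
            nemg = bin_average_cycle(te, sig, st))
        }
      }
    }
  }
  list(iemg = bind_rows(iemg_rows), curves = bind_rows(curve_rows))
}

# average samples within each of 101 equal %-cycle bins (bin centres at the
# nodes; endpoint bins are half-width)
bin_average_cycle <- function(times, values, stride) {
  sel <- times >= stride$start - 1e-9 & times <= stride$end + 1e-9
  p <- (times[sel] - stride$start) / (stride$end - stride$start)
  bins <- pmin(100L, pmax(0L, as.integer(round(p * 100))))
  out <- rep(NA_real_, 101L)
  agg <- tapply(values[sel], bins, mean)
  out[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  # fill any empty bin by linear interpolation
  if (anyNA(out)) {
    idx <- which(!is.na(out))
    out <- stats::approx(idx, out[idx], xout = 1:101, rule = 2)$y
  }
  out
}
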