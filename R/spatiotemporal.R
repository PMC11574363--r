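#' Per-stride spatiotemporal parameters
#'
#' For every valid stride: cycle time (`end - start`), stance time
#' (`toe_off - start`), swing time, duty factor (stance/cycle), per-stride
#' speed (mean signed progression velocity of the sacral marker over the
#' stride), stride length (ipsilateral heel progression-axis displacement
#' between consecutive heel-strikes), stride width (mean lateral heel
#' separation at the stride's two heel-strikes) and double-support time
#' (time within the stride when both sides are in stance, from both sides'
#' event sequences). When contralateral events are missing, double support
#' and stride width are `NA` with a reason; the other parameters are still
#' computed.
#'
#' @param trial A [gait_trial()].
#' @param strides A [build_strides()] result.
#' @param events The [detect_events()] result (needed for double support).
#' @param schema A [marker_schema()].
#' @return A tibble, one row per valid stride, with identifier columns and
#'   the parameters above (times s, lengths m, speed m/s).
#' @export
compute_spatiotemporal <- function(trial, strides, events,
                                   schema = default_marker_schema()) {
  s <- trial$travel_direction
  tt <- marker_times(trial)
  dt <- 1 / trial$marker_rate
  sacr <- schema_marker(trial, schema, "SACR")
  heels <- list(L = schema_marker(trial, schema, "LHEE"),
                R = schema_marker(trial, schema, "RHEE"))
  at_frame <- function(t) pmin(length(tt), pmax(1L, round((t - tt[1]) / dt) + 1L))
  stance_intervals <- function(sd_) {
    hs <- sort(events$time[events$side == sd_ &
                             events$event == "heel_strike"])
    to <- sort(events$time[events$side == sd_ & events$event == "toe_off"])
    ivs <- purrr::map_dfr(hs, function(h) {
      nxt <- to[to > h]
      if (!length(nxt)) return(tibble())
      tibble(on = h, off = nxt[1])
    })
    # the final strike has no detected toe-off (partial cycle); close its
    # stance with the side's median stance duration so double support at
    # trial end is not undercounted (the overlap is capped by the other
    # side's own toe-off)
    if (!nrow(ivs)) return(ivs)
    open <- setdiff(hs, ivs$on)
    if (length(open))
      ivs <- bind_rows(ivs, tibble(on = open,
                                   off = open + median(ivs$off - ivs$on)))
    ivs
  }
  rows <- list()
  for (i in seq_len(nrow(strides))) {
    st <- strides[i, ]
    if (!isTRUE(st$valid)) next
    sd_ <- st$side
    other <- if (sd_ == "L") "R" else "L"
    cyc <- st$end - st$start
    stance <- st$toe_off - st$start
    i0 <- at_frame(st$start); i1 <- at_frame(st$end)
    speed <- s * (sacr[i1, 1] - sacr[i0, 1]) / (tt[i1] - tt[i0])
    heel <- heels[[sd_]]
    stride_length <- abs(heel[i1, 1] - heel[i0, 1])
    width <- NA_real_; ds <- NA_real_; reason <- NA_character_
    o_int <- stance_intervals(other)
    if (nrow(o_int)) {
      if (min(o_int$on) > st$start) {
        # contralateral stance state unknown at stride start
        reason <- "contralateral coverage incomplete at stride start"
      } else {
        ov <- pmin(st$toe_off, o_int$off) - pmax(st$start, o_int$on)
        ds <- sum(ov[ov > 0])
      }
      wsep <- abs(heels$L[c(i0, i1), 2] - heels$R[c(i0, i1), 2])
      width <- mean(wsep)
    } else {
      reason <- "no contralateral events"
    }
    rows[[i]] <- tibble(
      trial_id = trial$trial_id, participant_id = trial$participant_id,
      sex = trial$sex, substrate_id = trial$substrate_id,
      side = sd_, stride = st$stride,
      speed = speed, stride_length = stride_length, stride_width = width,
      cycle_time = cyc, stance_time = stance, swing_time = cyc - stance,
      double_support_time = ds, duty_factor = stance / cyc,
      note = reason)
  }
  bind_rows(rows)
}

#' Foot sinkage depth per stride
#'
#' The sinkage proxy: substrate surface height minus the lowest vertical
#' (z) position reached by the calcaneus (heel) and hallux markers within
#' each stride, in cm. Negative values (marker minimum above the surface,
#' e.g. on the hard floor with marker offsets) are reported as-is and
#' QC-flagged rather than clipped. Strides whose window contains missing
#' marker samples yield `NA` with a reason.
#'
#' @param trial A [gait_trial()] with `substrate_surface_z` set.
#' @param strides A [build_strides()] result.
#' @param schema A [marker_schema()].
#' @return A tibble: identifiers, `side`, `stride`, `heel_sink_depth`,
#'   `hallux_sink_depth` (cm), `flagged` (negative depth or gap).
#' @export
compute_sinkage <- function(trial, strides,
                            schema = default_marker_schema()) {
  tt <- marker_times(trial)
  surf <- trial$substrate_surface_z
  rows <- list()
  for (i in seq_len(nrow(strides))) {
    st <- strides[i, ]
    if (!isTRUE(st$valid)) next
    win <- tt >= st$start & tt <= st$end
    depth_of <- function(role) {
      m <- schema_marker(trial, schema, role)
      z <- m[win, 3]
      if (anyNA(z)) return(NA_real_)
      100 * (surf - min(z))
    }
    hd <- depth_of(paste0(st$side, "HEE"))
    xd <- depth_of(paste0(st$side, "HALL"))
    rows[[i]] <- tibble(
      trial_id = trial$trial_id, participant_id = trial$participant_id,
      substrate_id = trial$substrate_id, side = st$side, stride = st$stride,
      heel_sink_depth = hd, hallux_sink_depth = xd,
      flagged = is.na(hd) | is.na(xd) |
        (!is.na(hd) & hd < 0) | (!is.na(xd) & xd < 0))
  }
  bind_rows(rows)
}

#' Coefficient of variation by group
#'
#' CV = sample standard deviation / mean, pooled over all strides of all
#' participants within each group (one CV per substrate per variable, the
#' gait-variability proxy). Requires at least 2 values and a non-zero mean
#' per group.
#'
#' @param data A tidy table (e.g. a stride table).
#' @param vars Character vector of value columns.
#' @param group Grouping column name (default `"substrate_id"`).
#' @return A tibble: `variable`, group column, `n`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' coefficient_of_variation(
#'   tibble::tibble(g = c("a", "a", "a"), v = c(1, 2, 3)),
#'   vars = "v", group = "g")
coefficient_of_variation <- function(data, vars, group = "substrate_id") {
  gr <- data[[group]]
  purrr::map_dfr(vars, function(vn) {
    vals <- data[[vn]]
    purrr::map_dfr(sort(unique(gr)), function(g_) {
      x <- vals[gr == g_ & !is.na(vals)]
      assert_that(length(x) >= 2, "CV needs at least 2 values per group")
      m <- mean(x)
      assert_that(abs(m) > .Machine$double.eps,
                  "CV undefined: group mean is zero")
      out <- tibble(variable = vn, n = length(x), mean = m, sd = sd(x),
                    cv = sd(x) / m)
      out[[group]] <- g_
      out[c("variable", group, "n", "mean", "sd", "cv")]
    })
  })
}

#' Relative CV change against a reference group
#'
#' `100 * (cv_b - cv_ref) / cv_ref` for every non-reference group, per
#' variable.
#'
#' @param cv_tbl A [coefficient_of_variation()] result.
#' @param ref Reference level of the group column (default `"hard_floor"`).
#' @param group Group column name.
#' @return `cv_tbl` with an added `cv_change_pct` column (NA for the
#'   reference rows).
#' @export
cv_relative_change <- function(cv_tbl, ref = "hard_floor",
                               group = "substrate_id") {
  cv_tbl |>
    group_by(.data$variable) |>
    mutate(cv_change_pct = {
      ref_cv <- .data$cv[.data[[group]] == ref]
      if (length(ref_cv) != 1L) NA_real_
      else ifelse(.data[[group]] == ref, NA_real_,
                  100 * (.data$cv - ref_cv) / ref_cv)
    }) |>
    ungroup()
}

stride_table_columns <- c(
  "trial_id", "participant_id", "sex", "substrate_id", "side", "stride",
  "speed", "stride_length", "stride_width", "cycle_time", "stance_time",
  "swing_time", "double_support_time", "duty_factor",
  "heel_sink_depth", "hallux_sink_depth")

#' Write / read a stride table
#'
#' Tidy CSV with one row per (trial, side, stride) and a stable, documented
#' column order; a `#`-prefixed header comment names the columns and units.
#' Numeric columns round-trip to 1e-9.
#'
#' @param rows Stride-table tibble (missing columns are added as `NA`).
#' @param path Destination path.
#' @return `rows` invisibly.
#' @export
write_stride_table <- function(rows, path) {
  for (cn in stride_table_columns)
    if (!cn %in% names(rows)) rows[[cn]] <- NA
  rows <- rows[c(stride_table_columns,
                 setdiff(names(rows), stride_table_columns))]
  hdr <- paste0(
    "# stride table: one row per (trial, side, stride); units: s, m, m/s, ",
    "depths cm\n# columns: ", paste(names(rows), collapse = ", "), "\n")
  con <- file(path, "w")
  writeLines(sub("\n$", "", hdr), con)
  close(con)
  readr::write_csv(rows, path, append = TRUE, col_names = TRUE)
  invisible(rows)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
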