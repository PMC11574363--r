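#' Process one trial through the kinematic pipeline
#'
#' Event detection, stride building, spatiotemporal parameters, sinkage
#' depths, CoM energetics and joint-angle curves for a single trial.
#'
#' @param trial A [gait_trial()].
#' @param schema A [marker_schema()].
#' @param anthropometry Anthropometric table for [body_com()].
#' @param use_direct_com Use a mapped `COM` channel when present.
#' @param keep_curves Keep 101-node energy curves.
#' @return List: `events`, `strides`, `stride_table` (spatiotemporal +
#'   sinkage merged), `exchange` (per-stride R/RA/CO), `angles` (curves +
#'   roms), `qc`.
#' @export
process_trial <- function(trial, schema = default_marker_schema(),
                          anthropometry = default_anthropometric_table(),
                          use_direct_com = TRUE, keep_curves = FALSE) {
  events <- detect_events(trial, schema)
  strides <- build_strides(events, trial, schema)
  spt <- compute_spatiotemporal(trial, strides, events, schema)
  snk <- compute_sinkage(trial, strides, schema)
  stride_table <- left_join(
    spt, select(snk, all_of(c("trial_id", "side", "stride",
                              "heel_sink_depth", "hallux_sink_depth",
                              "flagged"))),
    by = c("trial_id", "side", "stride"))
  exch <- stride_energetics(trial, strides, schema, anthropometry,
                            use_direct = use_direct_com,
                            keep_curves = keep_curves)
  angles <- joint_angle_curves(trial, strides, schema)
  list(events = events, strides = strides, stride_table = stride_table,
       exchange = if (keep_curves) exch$metrics else exch,
       energy_curves = if (keep_curves) exch$curves else NULL,
       angles = angles, qc = event_qc(events))
}

#' Process a set of trials (error-isolated)
#'
#' Runs [process_trial()] on every trial and [process_emg()] across
#' participants; a failing trial is recorded and skipped, the rest are
#' processed.
#'
#' @param trials Named list of [gait_trial()]s.
#' @param schema,anthropometry,use_direct_com See [process_trial()].
#' @param emg Run the EMG chain (needs EMG channels)?
#' @param keep_curves Keep per-stride 101-node energy curves.
#' @return List of bound tibbles: `stride_table`, `exchange`,
#'   `angle_curves`, `roms`, `events`, `qc`, `iemg`, `nemg_curves`,
#'   `errors` (tibble of failed trials), `strides_by_trial`.
#' @export
process_study <- function(trials, schema = default_marker_schema(),
                          anthropometry = default_anthropometric_table(),
                          use_direct_com = TRUE, emg = TRUE,
                          keep_curves = FALSE) {
  acc <- list(stride_table = list(), exchange = list(), curves = list(),
              roms = list(), events = list(), qc = list(),
              energy = list())
  strides_by_trial <- list()
  errors <- list()
  for (id in names(trials)) {
    res <- tryCatch(
      process_trial(trials[[id]], schema, anthropometry,
                    use_direct_com = use_direct_com,
                    keep_curves = keep_curves),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- tibble(trial_id = id, error = conditionMessage(res))
      next
    }
    acc$stride_table[[id]] <- res$stride_table
    acc$exchange[[id]] <- res$exchange
    acc$curves[[id]] <- res$angles$curves
    acc$roms[[id]] <- res$angles$roms
    acc$events[[id]] <- mutate(as_tibble(res$events), trial_id = id)
    acc$qc[[id]] <- mutate(res$qc, trial_id = id)
    if (keep_curves) acc$energy[[id]] <- res$energy_curves
    strides_by_trial[[id]] <- res$strides
  }
  emg_out <- list(iemg = tibble(), curves = tibble())
  if (emg) {
    ok <- names(strides_by_trial)
    with_emg <- ok[vapply(trials[ok], function(x) length(x$emg) > 0,
                          logical(1))]
    if (length(with_emg))
      emg_out <- process_emg(trials[with_emg],
                             strides_by_trial[with_emg])
  }
  list(stride_table = bind_rows(acc$stride_table),
       exchange = bind_rows(acc$exchange),
       angle_curves = bind_rows(acc$curves),
       roms = bind_rows(acc$roms),
       events = bind_rows(acc$events),
       qc = bind_rows(acc$qc),
       energy_curves = if (keep_curves) bind_rows(acc$energy) else NULL,
       iemg = emg_out$iemg, nemg_curves = emg_out$curves,
       errors = bind_rows(errors),
       strides_by_trial = strides_by_trial)
}

#' Participant-mean 101-node curves for SPM
#'
#' Averages stride curves within participant (then the paired t-field works
#' on one mean curve per participant per condition).
#'
#' @param curves Long curve tibble with `participant_id`, `substrate_id`,
#'   `node` and a value column.
#' @param value Value column name.
#' @param extra_groups Additional grouping columns (e.g. `"joint"` or
#'   `"muscle"`).
#' @return Tibble of participant means per node.
#' @export
participant_mean_curves <- function(curves, value,
                                    extra_groups = character(0)) {
  curves |>
    group_by(across(all_of(c("participant_id", "substrate_id",
                             extra_groups, "node")))) |>
    summarise(value = mean(.data[[value]], na.rm = TRUE),
              .groups = "drop")
}

curve_matrix <- function(mean_curves, substrate) {
  sub <- mean_curves[mean_curves$substrate_id == substrate, ]
  wide <- tidyr::pivot_wider(sub[c("participant_id", "node", "value")],
                             names_from = "node", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$participant_id
  m[order(rownames(m)), , drop = FALSE]
}

#' Run the study's statistical battery
#'
#' Linear mixed models per response variable; SPM paired comparisons per
#' joint for every substrate pair (Bonferroni across pairs); ANOVA + Tukey
#' on pooled sinkage depths across the sand substrates; Spearman
#' correlograms of trial means per substrate and combined; and
#' sinkage-depth-versus-metric correlograms.
#'
#' @param proc A [process_study()] result.
#' @param alpha Nominal level (default 0.05).
#' @param spm_method `"rft"` or `"permutation"`.
#' @param n_perm,seed Permutation settings.
#' @param lmm_responses Stride-table variables to model.
#' @return List: `lmm` (named list of `sandgait_lmm`), `spm` (named list of
#'   `sandgait_spm`), `anova_sinkage` (per marker), `correlograms`,
#'   `depth_correlogram`, `cv`.
#' @export
run_stats <- function(proc, alpha = 0.05, spm_method = "rft",
                      n_perm = 10000, seed = 1L,
                      lmm_responses = c("speed", "stride_length",
                                        "cycle_time", "stance_time",
                                        "duty_factor")) {
  st <- proc$stride_table
  trial_means <- trial_mean_table(proc)

  lmm <- list()
  for (resp in lmm_responses) {
    fx <- setdiff(c("substrate_id", "sex", "speed"), resp)
    lmm[[resp]] <- tryCatch(
      fit_lmm(st, resp, fixed = fx),
      error = function(e) e)
  }

  spm <- list()
  if (nrow(proc$angle_curves)) {
    mc <- participant_mean_curves(proc$angle_curves, "angle_deg", "joint")
    subs <- sort(unique(mc$substrate_id))
    pairs <- if (length(subs) >= 2) utils::combn(subs, 2) else NULL
    m_bonf <- if (is.null(pairs)) 1 else ncol(pairs)
    for (j in unique(mc$joint)) {
      mj <- mc[mc$joint == j, ]
      for (k in seq_len(ncol(pairs) %||% 0)) {
        a <- curve_matrix(mj, pairs[1, k]); b <- curve_matrix(mj, pairs[2, k])
        common <- intersect(rownames(a), rownames(b))
        if (length(common) < 3) next
        id <- sprintf("%s:%s_vs_%s", j, pairs[1, k], pairs[2, k])
        spm[[id]] <- spm_compare(a[common, ], b[common, ], alpha = alpha,
                                 bonferroni_m = m_bonf,
                                 method = spm_method, n_perm = n_perm,
                                 seed = seed, comparison = id)
      }
    }
  }

  sands <- st[!is.na(st$heel_sink_depth) &
                st$substrate_id != "hard_floor", ]
  anova_sinkage <- list()
  if (nrow(sands) && length(unique(sands$substrate_id)) >= 2) {
    anova_sinkage$heel <- anova_tukey(sands, "heel_sink_depth",
                                      "substrate_id")
    anova_sinkage$hallux <- anova_tukey(sands, "hallux_sink_depth",
                                        "substrate_id")
  }

  corr_vars <- intersect(
    c("r_pct", "speed", "stride_length", "stride_width", "cycle_time",
      "stance_time", "swing_time", "double_support_time", "duty_factor",
      "rom_hip", "rom_knee", "rom_ankle",
      grep("^iemg_", names(trial_means), value = TRUE)),
    names(trial_means))
  correlograms <- list()
  for (sb in unique(trial_means$substrate_id)) {
    tm <- trial_means[trial_means$substrate_id == sb, ]
    if (nrow(tm) >= 5)
      correlograms[[sb]] <- spearman_correlogram(tm, corr_vars)
  }
  if (nrow(trial_means) >= 5)
    correlograms$combined <- spearman_correlogram(trial_means, corr_vars)

  depth_correlogram <- NULL
  depth_vars <- intersect(c("heel_sink_depth", "hallux_sink_depth"),
                          names(trial_means))
  sands_tm <- trial_means[trial_means$substrate_id != "hard_floor", ]
  if (length(depth_vars) == 2 && nrow(sands_tm) >= 5)
    depth_correlogram <- spearman_correlogram(sands_tm,
                                              c(depth_vars, corr_vars))

  cv <- coefficient_of_variation(
    st, intersect(c("speed", "stride_length", "stride_width", "cycle_time",
                    "stance_time", "swing_time", "double_support_time",
                    "duty_factor"), names(st)))

  list(lmm = lmm, spm = spm, anova_sinkage = anova_sinkage,
       correlograms = correlograms, depth_correlogram = depth_correlogram,
       cv = cv)
}

#' Trial-mean table for correlation analyses
#'
#' One row per trial with stride-mean spatiotemporal parameters and sinkage,
#' mean energy recovery, per-joint ROMs (side-averaged) and per-muscle mean
#' iEMG (columns `iemg_<muscle>`).
#'
#' @param proc A [process_study()] result.
#' @return A tibble, one row per trial.
#' @export
trial_mean_table <- function(proc) {
  num_cols <- intersect(
    c("speed", "stride_length", "stride_width", "cycle_time", "stance_time",
      "swing_time", "double_support_time", "duty_factor",
      "heel_sink_depth", "hallux_sink_depth"), names(proc$stride_table))
  id_cols <- intersect(c("trial_id", "participant_id", "sex",
                         "substrate_id"), names(proc$stride_table))
  base <- proc$stride_table |>
    group_by(across(all_of(id_cols))) |>
    summarise(across(all_of(num_cols), ~mean(.x, na.rm = TRUE)),
              .groups = "drop")
  if (nrow(proc$exchange)) {
    ex <- proc$exchange |>
      group_by(.data$trial_id) |>
      summarise(r_pct = mean(.data$r_pct), ra = mean(.data$ra),
                co_pct = mean(.data$co_pct), .groups = "drop")
    base <- left_join(base, ex, by = "trial_id")
  }
  if (nrow(proc$roms)) {
    rm_ <- proc$roms |>
      group_by(.data$trial_id, .data$joint) |>
      summarise(rom = mean(.data$rom, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "joint", values_from = "rom",
                         names_prefix = "rom_")
    base <- left_join(base, rm_, by = "trial_id")
  }
  if (nrow(proc$iemg)) {
    ie <- proc$iemg |>
      group_by(.data$trial_id, .data$muscle) |>
      summarise(iemg = mean(.data$iemg), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "muscle", values_from = "iemg",
                         names_prefix = "iemg_")
    base <- left_join(base, ie, by = "trial_id")
  }
  base
}

#' Run a configured end-to-end pipeline and write its outputs
#'
#' Simulates (or reads) trials, processes them, and writes the stage outputs
#' as CSV plus a JSON manifest (config hash, package version, seed, outputs,
#' per-trial errors). Deterministic stages re-run byte-identically under the
#' same config.
#'
#' @param config Either a YAML path or a list: fields `source`
#'   (`"simulated"` or `"files"`), `sim` (arguments for
#'   [gait_sim_config()]), `paths` (for `files`: named list of marker/EMG
#'   CSVs), `out_dir`, `seed`, `emg`.
#' @return Invisibly, the [process_study()] result (with `$manifest`).
#' @export
run_process <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emg_on <- cfg$emg %||% TRUE
  if ((cfg$source %||% "simulated") == "simulated") {
    sim_args <- cfg$sim %||% list()
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    gsc <- do.call(gait_sim_config, sim_args)
    study <- simulate_study(gsc, emg = emg_on)
    trials <- study$trials
    readr::write_csv(study$truth$strides,
                     file.path(out_dir, "ground_truth_strides.csv"))
  } else {
    trials <- list()
    for (tr in cfg$paths) {
      t_ <- do.call(read_tabular_trial, tr)
      trials[[t_$trial_id]] <- t_
    }
  }
  proc <- process_study(trials, emg = emg_on, keep_curves = TRUE)
  outputs <- c(stride_table = "stride_table.csv",
               exchange = "exchange_metrics.csv",
               angle_curves = "angle_curves.csv",
               roms = "roms.csv",
               events = "events.csv",
               qc = "event_qc.csv",
               energy_curves = "energy_curves.csv",
               iemg = "iemg.csv",
               nemg_curves = "nemg_curves.csv")
  written <- character(0)
  for (nm in names(outputs)) {
    obj <- proc[[nm]]
    if (is.null(obj) || !nrow(obj)) next
    path <- file.path(out_dir, outputs[[nm]])
    if (nm == "stride_table") write_stride_table(obj, path)
    else readr::write_csv(obj, path)
    written <- c(written, outputs[[nm]])
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sandgait")),
    config_hash = rlang::hash(cfg), seed = cfg$seed %||% NA,
    n_trials = length(trials), outputs = as.list(written),
    errors = if (nrow(proc$errors)) proc$errors$trial_id else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  proc$manifest <- manifest
  invisible(proc)
}
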