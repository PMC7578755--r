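#' Load and validate a run configuration
#'
#' The configuration is a YAML (or plain list) with keys: `manifest`
#' (sessions CSV: `participant_id, side, role, path`), `windows` (CSV:
#' `participant_id, label, start_s, end_s`), `questionnaires` (CSV, see
#' [score_questionnaires()]), `meta` (CSV: `participant_id, group, cause,
#' prosthesis_type`), `pal_scale_max`, `out_dir`, `seed`, and the optional
#' blocks `preprocess` (epoch_len_s, activity_threshold_g, method,
#' cutoff_hz), `detection` (threshold_g, min_dur_s, merge_gap_s),
#' `metrics` (cap, min_active_epochs) and `stats` (exclude_ids, r_scale,
#' outlier_k). Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("manifest", "windows", "questionnaires", "meta",
             "pal_scale_max", "out_dir", "seed", "preprocess", "detection",
             "metrics", "stats")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  need <- c("manifest", "windows", "questionnaires", "meta",
            "pal_scale_max", "out_dir", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("missing config keys: ", paste(miss, collapse = ", "))
  defaults <- list(
    preprocess = list(epoch_len_s = 1, activity_threshold_g = 0.01,
                      method = "highpass", cutoff_hz = 0.25),
    detection = list(threshold_g = 0.05, min_dur_s = 0.25,
                     merge_gap_s = 0.25),
    metrics = list(cap = 7, min_active_epochs = 10),
    stats = list(exclude_ids = character(), r_scale = sqrt(2) / 2,
                 outlier_k = 3))
  for (blk in names(defaults)) {
    user <- config[[blk]] %||% list()
    extra <- setdiff(names(user), names(defaults[[blk]]))
    if (length(extra))
      stop("unknown config keys in '", blk, "': ",
           paste(extra, collapse = ", "))
    config[[blk]] <- utils::modifyList(defaults[[blk]], user)
  }
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Sessions -> epoch files -> per-participant gesture metrics -> cohort
#' table (joined with questionnaire scores and metadata) -> statistical
#' battery, all driven by one configuration. Writes, under `out_dir`:
#' `epochs_<id>.csv`, `metrics.csv`, `cohort.csv`, `stats.txt` (readable
#' report), `stats.csv` (machine-readable twin) and `provenance.txt`
#' (package version, seed, every threshold used, exclusions). Reruns with
#' an identical config are byte-identical.
#'
#' @param config A [run_config()], or a path/list accepted by it.
#' @return The `stat_battery`, invisibly, with the cohort table attached as
#'   attribute `cohort`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  for (f in c("manifest", "windows", "questionnaires", "meta"))
    if (!file.exists(cfg[[f]]))
      stop("pipeline stage 'input validation': missing file for '", f,
           "': ", cfg[[f]])
  man <- utils::read.csv(cfg$manifest)
  wins <- utils::read.csv(cfg$windows)
  meta <- utils::read.csv(cfg$meta)
  qdf <- utils::read.csv(cfg$questionnaires)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pp <- cfg$preprocess; det <- cfg$detection; met <- cfg$metrics
  metrics <- list()
  for (pid in unique(man$participant_id)) {
    rows <- man[man$participant_id == pid, , drop = FALSE]
    if (nrow(rows) != 2)
      stop("pipeline stage 'session assembly': participant ", pid,
           " needs exactly 2 manifest rows, has ", nrow(rows))
    for (pth in rows$path) if (!file.exists(pth))
      stop("pipeline stage 'session assembly': participant ", pid,
           ": missing recording file ", pth)
    recs <- lapply(1:2, function(i)
      read_recording(rows$path[i], pid, rows$side[i], rows$role[i]))
    wrows <- wins[wins$participant_id == pid, , drop = FALSE]
    if (!nrow(wrows))
      stop("pipeline stage 'session assembly': participant ", pid,
           ": no task windows")
    sess <- build_session(recs[[1]], recs[[2]],
                          task_windows(wrows$label, wrows$start_s,
                                       wrows$end_s))
    gm <- tryCatch(
      compute_gesture_metrics(sess,
                              epoch_len_s = pp$epoch_len_s,
                              activity_threshold_g = pp$activity_threshold_g,
                              method = pp$method, cutoff_hz = pp$cutoff_hz,
                              threshold_g = det$threshold_g,
                              min_dur_s = det$min_dur_s,
                              merge_gap_s = det$merge_gap_s,
                              cap = met$cap,
                              min_active_epochs = met$min_active_epochs),
      error = function(e)
        stop("pipeline stage 'gesture metrics': participant ", pid, ": ",
             conditionMessage(e)))
    write_epochs(gm$epochs, file.path(cfg$out_dir,
                                      paste0("epochs_", pid, ".csv")))
    metrics[[pid]] <- gm
  }
  scores <- score_questionnaires(qdf, cfg$pal_scale_max)
  cohort <- cohort_table(metrics, scores, meta)
  battery <- run_stat_battery(cohort,
                              exclude_ids = cfg$stats$exclude_ids,
                              r_scale = cfg$stats$r_scale,
                              outlier_k = cfg$stats$outlier_k)
  write_metrics_csv(metrics, file.path(cfg$out_dir, "metrics.csv"))
  utils::write.csv(as.data.frame(cohort),
                   file.path(cfg$out_dir, "cohort.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(battery)),
             file.path(cfg$out_dir, "stats.txt"))
  utils::write.csv(battery_to_df(battery),
                   file.path(cfg$out_dir, "stats.csv"), row.names = FALSE)
  prov <- c(sprintf("gesticulate %s",
                    as.character(utils::packageVersion("gesticulate"))),
            sprintf("seed: %s", cfg$seed),
            sprintf("config: %s",
                    config_fingerprint(c(pp, det, met,
                                         cfg$stats[c("r_scale",
                                                     "outlier_k")]))),
            sprintf("named exclusions: %s",
                    paste(cfg$stats$exclude_ids, collapse = ", ")),
            sprintf("flagged participants: %s",
                    paste(cohort$participant_id[cohort$excluded],
                          collapse = ", ")))
  writeLines(prov, file.path(cfg$out_dir, "provenance.txt"))
  attr(battery, "cohort") <- cohort
  invisible(battery)
}

write_metrics_csv <- function(metrics, path) {
  df <- do.call(rbind, lapply(metrics, function(m)
    data.frame(participant_id = m$participant_id,
               moves_per_min_arm1 = m$moves_per_min_arm1,
               moves_per_min_arm2 = m$moves_per_min_arm2,
               mmr = as.numeric(m$mmr),
               n_active_epochs = m$n_active_epochs,
               n_unilateral_epochs = m$n_unilateral_epochs,
               alt_use_ratio = as.numeric(m$alt_use_ratio),
               alt_laterality_index = as.numeric(m$alt_laterality_index),
               config = m$config_fingerprint)))
  utils::write.csv(df[order(df$participant_id), ], path, row.names = FALSE)
  invisible(path)
}

#' Flatten a battery to a machine-readable table
#'
#' @param battery A `stat_battery`.
#' @return Data.frame with one row per test: `test, statistic_name,
#'   statistic, df1, df2, p, bf10`.
#' @export
battery_to_df <- function(battery) {
  rows <- list()
  walk <- function(r) {
    if (inherits(r, "stat_result")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        test = r$test, statistic_name = names(r$statistic)[1],
        statistic = unname(r$statistic[1]),
        df1 = if (length(r$df) >= 1) r$df[1] else NA_real_,
        df2 = if (length(r$df) >= 2) r$df[2] else NA_real_,
        p = r$p, bf10 = r$bf10)
    } else if (is.list(r)) lapply(r, walk)
  }
  for (nm in setdiff(names(battery), "parametric_exclusions"))
    walk(battery[[nm]])
  do.call(rbind, rows)
}

#' Originally reported statistics for the public deposit
#'
#' Reference values against which [reproduce_osf()] prints its side-by-side
#' comparison: the headline statistics reported for the dataset deposited at
#' osf.io/spt2a.
#'
#' @return Data.frame: `test`, `statistic`, `reported`.
#' @export
osf_reference_stats <- function() {
  data.frame(
    test = c("u_mmr_group", "moves_paired_onehanders",
             "moves_paired_twohanders", "moves_paired_twohanders_bf",
             "t_embodiment", "u_mmr_embodiment", "spearman_mmr_use",
             "moves_anova_interaction", "ancova_daily_use_score"),
    statistic = c("U", "t", "t", "BF10", "t", "U", "rho", "F", "F"),
    reported = c(47, 2.94, 0.088, 0.263, 2.23, 35, 0.55, 4.25, 13.97))
}

#' Recompute the deposited study's statistics (opt-in)
#'
#' Works from a manually downloaded copy of the public deposit
#' (osf.io/spt2a); nothing is ever downloaded automatically. The deposit's
#' per-participant values must be arranged as `per_participant.csv` in
#' `data_dir` with columns `participant_id, group, cause, prosthesis_type,
#' moves_per_min_preferred, moves_per_min_nonpreferred, mmr,
#' wear_hours_week, pal_score, embodiment_score` (group coded
#' `one_hander` / `two_hander`). Daily-use composites and embodiment groups
#' are recomputed with the package's scoring functions, the full battery is
#' rerun, and a side-by-side table against the originally reported
#' statistics is returned.
#'
#' @param data_dir Directory holding the downloaded deposit.
#' @param exclude_ids Named parametric exclusions (e.g. the deposit's
#'   documented laterality outlier).
#' @param reference Reference table, by default [osf_reference_stats()].
#' @return List with `battery` (the recomputed `stat_battery`) and
#'   `comparison` (data.frame: test, statistic, recomputed, reported).
#' @export
reproduce_osf <- function(data_dir, exclude_ids = "aa11",
                          reference = osf_reference_stats()) {
  if (!dir.exists(data_dir))
    stop("deposit directory not found: ", data_dir,
         "\nDownload the deposit manually (osf.io/spt2a) and point ",
         "data_dir at it; this function never downloads anything.")
  f <- file.path(data_dir, "per_participant.csv")
  if (!file.exists(f))
    stop("unrecognized deposit layout: expected ", f,
         "\nArrange the deposit's per-participant values as ",
         "per_participant.csv with columns participant_id, group, cause, ",
         "prosthesis_type, moves_per_min_preferred, ",
         "moves_per_min_nonpreferred, mmr, wear_hours_week, pal_score, ",
         "embodiment_score.")
  df <- utils::read.csv(f)
  oh <- df$group == "one_hander"
  use <- rep(NA_real_, nrow(df))
  use[oh] <- daily_use_score(df$wear_hours_week[oh], df$pal_score[oh])
  cohort <- data.frame(
    participant_id = df$participant_id, group = df$group,
    cause = df$cause, prosthesis_type = df$prosthesis_type,
    moves_per_min_arm1 = df$moves_per_min_preferred,
    moves_per_min_arm2 = df$moves_per_min_nonpreferred,
    mmr = df$mmr, pal_score = df$pal_score,
    wear_hours_week = df$wear_hours_week,
    daily_use_score = use,
    embodiment_score = df$embodiment_score,
    embodiment_group = vapply(df$embodiment_score, function(e)
      if (is.na(e)) NA_character_ else embodiment_group(e), character(1)),
    excluded = FALSE, exclusion_reason = NA_character_)
  class(cohort) <- c("gesture_cohort", "data.frame")
  battery <- run_stat_battery(cohort, exclude_ids = exclude_ids)
  pick <- function(test, stat) {
    if (stat == "BF10")
      return(battery$moves_paired_twohanders$bf10)
    obj <- switch(test,
                  moves_anova_interaction = battery$moves_anova$interaction,
                  ancova_daily_use_score = battery$ancova$daily_use_score,
                  battery[[test]])
    if (is.null(obj)) NA_real_ else unname(obj$statistic[1])
  }
  comp <- reference
  comp$recomputed <- mapply(pick, reference$test, reference$statistic)
  comp <- comp[, c("test", "statistic", "recomputed", "reported")]
  list(battery = battery, comparison = comp)
}
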