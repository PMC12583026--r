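#' Run configuration for the end-to-end pipeline
#'
#' Bundles the simulation configuration with the processing thresholds.
#' The threshold defaults are exactly the protocol constants: artifact jump
#' 15 bpm, quality minimum 10, retention minimum 0.70, edge trim 10,
#' excision flank 7, rolling window 10. Nothing is hard-coded in the
#' pipeline logic; every threshold used is echoed into the reports.
#'
#' @param simulation a [sim_config()].
#' @param artifact_jump,quality_min,retention_min,edge_trim,excision_flank,roll_window
#'   processing thresholds (see [process_recording()]).
#' @param outcomes outcome contrasts for [evaluate_biomarkers()].
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       artifact_jump = 15,
                       quality_min = 10L,
                       retention_min = 0.70,
                       edge_trim = 10L,
                       excision_flank = 7L,
                       roll_window = 10L,
                       outcomes = c("any_can", "early_can", "manifest_can"),
                       log_level = "info") {
  stopifnot(artifact_jump > 0, quality_min >= 0, retention_min > 0,
            edge_trim > 0, excision_flank > 0, roll_window > 0)
  structure(list(simulation = simulation,
                 artifact_jump = artifact_jump,
                 quality_min = quality_min,
                 retention_min = retention_min,
                 edge_trim = edge_trim,
                 excision_flank = excision_flank,
                 roll_window = roll_window,
                 outcomes = outcomes,
                 log_level = log_level), class = "run_config")
}

pipe_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one beat-series CSV plus a ground-truth JSON sidecar per
#' recording, a cohort metadata CSV, and a manifest JSON with the seed,
#' package version, file list and md5 checksums (reruns of the same
#' configuration produce identical checksums).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$simulation)
  files <- character(0)
  for (rec in c(cohort$recordings, cohort$short_term)) {
    stub <- sprintf("%s_%s_%d", rec$subject_id, rec$kind, rec$recording_index)
    f <- file.path(out_dir, paste0(stub, ".csv"))
    write_recording(rec, f)
    g <- file.path(out_dir, paste0(stub, ".gt.json"))
    write_ground_truth(rec, g)
    files <- c(files, f, g)
  }
  meta_path <- file.path(out_dir, "cohort_metadata.csv")
  write_cohort_metadata(cohort$subjects, meta_path)
  files <- c(files, meta_path)
  manifest <- list(
    seed = config$simulation$seed,
    package_version = as.character(utils::packageVersion("cvtscreen")),
    n_subjects = nrow(cohort$subjects),
    n_night_recordings = length(cohort$recordings),
    n_short_term = length(cohort$short_term),
    files = basename(files),
    md5 = unname(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(config, "simulated %d subjects, %d night recordings -> %s",
           manifest$n_subjects, manifest$n_night_recordings, out_dir)
  invisible(manifest)
}

process_with_config <- function(rec, config) {
  process_recording(rec,
                    roll_window = config$roll_window,
                    edge_trim = config$edge_trim,
                    artifact_jump = config$artifact_jump,
                    excision_flank = config$excision_flank,
                    quality_min = config$quality_min,
                    retention_min = config$retention_min)
}

#' Analyze a cohort directory and write report files
#'
#' Reads the recordings and metadata written by [run_simulate()] (or any
#' user-supplied data in the same dialect), runs the full analysis and
#' writes: `raw_quality.json` (raw-data descriptives), `cvt_summaries.csv`
#' (per-recording summaries), `icc.json` (night-to-night reliability),
#' `group_descriptives.csv` (median/IQR of the biomarkers by group and CAN
#' stage) and `diagnostics.csv`/`diagnostics.json` (ROC table). Every
#' threshold used is echoed into `analysis_config.json`.
#'
#' @param in_dir directory with recordings + `cohort_metadata.csv`.
#' @param config a [run_config()].
#' @param out_dir report directory (default `in_dir`).
#' @return list with all report objects, invisibly.
#' @export
run_analyze <- function(in_dir, config, out_dir = in_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- read_cohort_metadata(file.path(in_dir, "cohort_metadata.csv"))
  paths <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  paths <- paths[basename(paths) != "cohort_metadata.csv"]
  recs <- lapply(paths, read_recording)
  is_night <- vapply(recs, function(r) identical(r$kind, "night"), TRUE)
  nights <- recs[is_night]
  shorts <- recs[!is_night]
  if (length(nights) == 0L) stop("no night recordings found in input directory")

  raw_report <- summarize_raw(nights)
  proc <- lapply(nights, process_with_config, config = config)
  accepted <- Filter(function(p) p$accepted, proc)
  if (length(accepted) == 0L) {
    reasons <- table(vapply(proc, function(p) p$reject_reason, ""))
    stop(sprintf("no accepted recordings; rejection reasons: %s",
                 paste(sprintf("%s (n=%d)", names(reasons), as.integer(reasons)),
                       collapse = "; ")))
  }
  pipe_log(config, "processed %d night recordings, %d accepted",
           length(proc), length(accepted))

  night_summaries <- summarize_recordings(proc)
  proc_short <- lapply(shorts, process_with_config, config = config)
  short_summaries <- if (length(proc_short)) summarize_recordings(proc_short)

  # reliability on the accepted nightly mean CVT values
  acc_sum <- night_summaries[night_summaries$accepted & !is.na(night_summaries$mean_cvt), ]
  icc_res <- tryCatch(
    fit_random_intercept(data.frame(subject_id = acc_sum$subject_id,
                                    recording_number = acc_sum$recording_index,
                                    mean_cvt = acc_sum$mean_cvt)),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "icc_result"))

  # best accepted overnight recording per subject
  best <- list()
  for (id in unique(vapply(accepted, function(p) p$subject_id, ""))) {
    mine <- Filter(function(p) p$subject_id == id, accepted)
    best[[id]] <- select_best_recording(mine)
  }
  best_summaries <- summarize_recordings(best)
  all_summaries <- rbind(night_summaries,
                         if (!is.null(short_summaries)) short_summaries)
  biomarkers <- build_biomarker_table(
    rbind(best_summaries, if (!is.null(short_summaries)) short_summaries))
  staging <- data.frame(
    subject_id = meta$subject_id,
    can_stage = apply(meta[, c("cart_postural", "cart_breathing",
                               "cart_valsalva")], 1L, stage_can))

  diagnostics <- evaluate_biomarkers(biomarkers, staging,
                                     outcomes = config$outcomes)

  # group descriptives (median / IQR), by group and by CAN stage
  gtab <- merge(merge(biomarkers, staging, by = "subject_id"),
                meta[, c("subject_id", "group")], by = "subject_id")
  descr <- function(split_col) {
    do.call(rbind, lapply(split(gtab, gtab[[split_col]]), function(d) {
      row <- data.frame(stratum = d[[split_col]][1L], n = nrow(d))
      for (bm in c("short_mean", "long_mean", "long_capacity")) {
        v <- d[[bm]][!is.na(d[[bm]])]
        row[[paste0(bm, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
        row[[paste0(bm, "_q1")]] <- if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_
        row[[paste0(bm, "_q3")]] <- if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_
      }
      row
    }))
  }
  group_descr <- rbind(cbind(by = "group", descr("group")),
                       cbind(by = "can_stage", descr("can_stage")))

  thresholds <- config[c("artifact_jump", "quality_min", "retention_min",
                         "edge_trim", "excision_flank", "roll_window")]

  jsonlite::write_json(list(
    n_recordings = raw_report$n_recordings,
    length_s = as.list(raw_report$length_s),
    points = as.list(raw_report$points),
    missing_pct = as.list(raw_report$missing_pct),
    quality13_pct = as.list(raw_report$quality13_pct),
    thresholds = thresholds),
    file.path(out_dir, "raw_quality.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(all_summaries, file.path(out_dir, "cvt_summaries.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  jsonlite::write_json(c(unclass(icc_res), list(thresholds = thresholds)),
                       file.path(out_dir, "icc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(group_descr, file.path(out_dir, "group_descriptives.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  jsonlite::write_json(list(table = diagnostics, thresholds = thresholds),
                       file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(thresholds, file.path(out_dir, "analysis_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(raw_quality = raw_report, summaries = all_summaries,
                 icc = icc_res, group_descriptives = group_descr,
                 diagnostics = diagnostics, thresholds = thresholds,
                 processed = proc, best = best))
}

#' Simulate and analyze in one invocation
#'
#' A single seed (in `config$simulation`) governs everything; the same
#' configuration and seed produce identical reports.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; simulated data go to `<out_dir>/sim`,
#'   reports to `<out_dir>/reports`.
#' @return the analysis result list, invisibly.
#' @export
run_end_to_end <- function(config, out_dir) {
  sim_dir <- file.path(out_dir, "sim")
  rep_dir <- file.path(out_dir, "reports")
  run_simulate(config, sim_dir)
  run_analyze(sim_dir, config, rep_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `analyze`, `run` (end-to-end). Flags:
#' `--config <json>` (overrides of [sim_config()] / [run_config()] fields),
#' `--seed <int>`, `--in <dir>`, `--out <dir>`, `--log-level <level>`.
#' Invoke via `Rscript -e 'cvtscreen::cli_main()' <subcommand> ...` or the
#' wrapper script in `inst/cli/`.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 invisibly on success.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: cvtscreen <simulate|analyze|run> [--config f] [--seed n] [--in d] [--out d] [--log-level l]")
  cmd <- args[1L]
  opts <- list(); i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop(sprintf("flag --%s needs a value", key))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  overrides <- if (!is.null(opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  sim_args <- overrides$simulation %||% list()
  if (!is.null(opts$seed)) sim_args$seed <- as.integer(opts$seed)
  sim <- do.call(sim_config, sim_args)
  run_args <- overrides[setdiff(names(overrides), "simulation")]
  run_args$simulation <- sim
  if (!is.null(opts[["log-level"]])) run_args$log_level <- opts[["log-level"]]
  cfg <- do.call(run_config, run_args)
  out <- opts$out %||% "cvtscreen_out"
  switch(cmd,
    simulate = run_simulate(cfg, out),
    analyze = run_analyze(opts[["in"]] %||% out, cfg, out),
    run = run_end_to_end(cfg, out),
    stop(sprintf("unknown subcommand '%s'", cmd)))
  invisible(0L)
}
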