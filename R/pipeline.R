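#' Pipeline stage runners
#'
#' Thin orchestration over the analysis modules for scripted use: each
#' runner validates its inputs, executes one stage, writes its output files
#' into `out_dir`, and records a JSON run manifest
#' (`<stage>_manifest.json`) holding the input paths, the configuration
#' snapshot, the seed, the package version, per-stage record counts —
#' including wells excluded at each step — and a timestamp, so any run can
#' be reproduced from its manifest alone. All randomness flows from the
#' single `seed` argument; identical inputs, configuration and seed
#' reproduce identical outputs.
#'
#' * `pipeline_score()`: plate map + readings -> validation, per-well SSMD*
#'   scores (`scores.csv`).
#' * `pipeline_hits()`: scores for two replicates -> concordant hit table
#'   (`hits.csv`) and threshold summary (`hit_summary.csv`).
#' * `pipeline_qc()`: scores -> per-plate QC (`qc_plates.csv`) and
#'   screen-level JSON summary (`qc_summary.json`).
#' * `pipeline_simulate()`: generator config -> plate map, readings and
#'   truth CSVs.
#' * `pipeline_dose()`: long-format dose CSV (`dose_um`, `fluorescence`) ->
#'   dose report (`dose_report.csv`, `dose_trend.json`).
#'
#' @param plate_map,readings,scores,doses input file paths.
#' @param out_dir output directory (created if missing).
#' @param config an [analysis_config()], or a path to one in YAML form.
#' @param sim_config a [simulation_config()] for `pipeline_simulate()`; its
#'   `planted` argument switches to [simulate_planted_screen()] with the
#'   listed arguments.
#' @param planted optional named list of [simulate_planted_screen()]
#'   arguments; when given, the planted-score benchmark generator is used.
#' @param seed integer seed recorded in the manifest and used for any
#'   randomness in the stage.
#' @param n_permutations permutations for the dose trend test.
#' @return each runner invisibly returns a list of its in-memory results and
#'   output paths.
#' @name pipeline
NULL

.as_config <- function(config) {
  if (is.character(config)) read_analysis_config(config) else config
}

.write_manifest <- function(stage, out_dir, inputs, outputs, config, seed,
                            counts) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    outputs = outputs,
    config = if (is.object(config)) unclass(config) else config,
    seed = seed,
    package_version = as.character(utils::packageVersion("ssmdscreen")),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname pipeline
#' @export
pipeline_score <- function(plate_map, readings, out_dir,
                           config = analysis_config(), seed = NULL) {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skeleton <- read_plate_map(plate_map)
  dataset <- read_readings(readings, skeleton)
  validation <- validate_screen(dataset, config)
  for (w in validation$warnings) warning(w, call. = FALSE)
  screen <- score_screen(dataset, config, on_error = "stop")
  scores_path <- file.path(out_dir, "scores.csv")
  write_scores(screen, scores_path)
  n_excluded <- sum(!is.na(dataset$status) & dataset$status != "ok")
  .write_manifest("score", out_dir,
                  inputs = list(plate_map = plate_map, readings = readings),
                  outputs = list(scores = scores_path),
                  config = config, seed = seed,
                  counts = list(wells = nrow(dataset),
                                wells_excluded = n_excluded,
                                wells_scored = sum(!is.na(
                                  screen$scores$ssmd_star)),
                                plates_failed = nrow(screen$failed)))
  invisible(list(screen = screen, validation = validation,
                 scores_path = scores_path))
}

#' @rdname pipeline
#' @export
pipeline_hits <- function(scores, out_dir, config = analysis_config(),
                          seed = NULL) {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- read_scores(scores, config)
  reps <- sort(unique(screen$scores$replicate))
  if (length(reps) != 2L) {
    stop("hit calling requires scores from exactly two replicates; found ",
         length(reps), call. = FALSE)
  }
  calls <- classify_screen(screen, config)
  hits <- concordant_hits(calls)
  summ <- hit_summary(hits, config = config)
  hits_path <- file.path(out_dir, "hits.csv")
  summary_path <- file.path(out_dir, "hit_summary.csv")
  write_hits(hits, hits_path)
  utils::write.csv(as.data.frame(summ), summary_path, row.names = FALSE)
  rescreen <- toxic_rescreen_list(hits)
  rescreen_path <- NULL
  if (nrow(rescreen)) {
    rescreen_path <- file.path(out_dir, "toxic_rescreen_map.csv")
    utils::write.csv(rescreen, rescreen_path, row.names = FALSE, na = "")
  }
  .write_manifest("hits", out_dir,
                  inputs = list(scores = scores),
                  outputs = list(hits = hits_path, summary = summary_path,
                                 rescreen = rescreen_path),
                  config = config, seed = seed,
                  counts = list(compounds = nrow(hits),
                                toxic = sum(hits$final_call == "toxic"),
                                not_replicated = sum(
                                  hits$final_call == "not_replicated")))
  invisible(list(hits = hits, summary = summ, rescreen = rescreen,
                 hits_path = hits_path, summary_path = summary_path))
}

#' @rdname pipeline
#' @param thresholds inhibitor thresholds for `pipeline_qc()`.
#' @export
pipeline_qc <- function(scores, out_dir, config = analysis_config(),
                        thresholds = c(-0.5, -1.0), seed = NULL) {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- read_scores(scores, config)
  qc <- screen_qc(screen, thresholds)
  flagged <- qc$per_plate$flagged
  if (any(flagged)) {
    warning(sum(flagged), " plate-replicate(s) have undefined QC metrics",
            call. = FALSE)
  }
  csv_path <- file.path(out_dir, "qc_plates.csv")
  json_path <- file.path(out_dir, "qc_summary.json")
  write_qc(qc, csv_path, json_path)
  .write_manifest("qc", out_dir,
                  inputs = list(scores = scores),
                  outputs = list(per_plate = csv_path, summary = json_path),
                  config = config, seed = seed,
                  counts = list(plate_replicates = nrow(qc$per_plate) /
                                  length(thresholds),
                                flagged = sum(flagged)))
  invisible(list(qc = qc, csv_path = csv_path, json_path = json_path))
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(out_dir, sim_config = simulation_config(),
                              planted = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(planted)) {
    planted$seed <- if (is.null(planted$seed)) seed else planted$seed
    sim <- do.call(simulate_planted_screen, planted)
  } else {
    if (!is.null(seed)) sim_config$seed <- as.integer(seed)
    sim <- simulate_screen(sim_config)
  }
  map_path <- file.path(out_dir, "plate_map.csv")
  readings_path <- file.path(out_dir, "readings.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_screen(sim$dataset, map_path, readings_path)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE, na = "")
  .write_manifest("simulate", out_dir,
                  inputs = list(),
                  outputs = list(plate_map = map_path,
                                 readings = readings_path,
                                 truth = truth_path),
                  config = sim$config, seed = seed,
                  counts = list(wells = nrow(sim$dataset),
                                compounds = nrow(sim$truth)))
  invisible(list(sim = sim, plate_map = map_path, readings = readings_path,
                 truth = truth_path))
}

#' @rdname pipeline
#' @export
pipeline_dose <- function(doses, out_dir, n_permutations = 1000L,
                          seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- utils::read.csv(doses, stringsAsFactors = FALSE)
  required <- c("dose_um", "fluorescence")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("dose file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  series <- dose_series(d$dose_um, d$fluorescence,
                        compound_id = if ("compound_id" %in% names(d))
                          d$compound_id[1L] else NA_character_)
  summ <- dose_summary(series, n_permutations = n_permutations, seed = seed)
  csv_path <- file.path(out_dir, "dose_report.csv")
  json_path <- file.path(out_dir, "dose_trend.json")
  write_dose_report(summ, csv_path, json_path)
  .write_manifest("dose", out_dir,
                  inputs = list(doses = doses),
                  outputs = list(report = csv_path, trend = json_path),
                  config = list(n_permutations = n_permutations),
                  seed = seed,
                  counts = list(wells = nrow(series$wells),
                                dose_levels = nrow(summ$per_dose)))
  invisible(list(summary = summ, csv_path = csv_path,
                 json_path = json_path))
}
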