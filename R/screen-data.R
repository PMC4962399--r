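#' @keywords internal
"_PACKAGE"

WELL_ROLES    <- c("positive_control", "negative_control", "test", "empty")
WELL_STATUSES <- c("ok", "dead", "defective", "excluded")
HIT_CLASSES   <- c("strong_inhibitor", "inhibitor", "activator", "inactive",
                   "toxic", "excluded")

#' Parse 96-well addresses
#'
#' Well addresses use the row-letter + 1-based column convention ("A1" ..
#' "H12"), row-major. Parsing is strict: anything outside rows A-H or columns
#' 1-12 is rejected.
#'
#' @param well character vector of well labels.
#' @return `parse_well()` returns a data.frame with columns `row` (letter) and
#'   `column` (integer); `format_well()` returns the canonical labels.
#' @examples
#' parse_well(c("A1", "H12"))
#' format_well("B", 7)
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-H])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  col <- rep(NA_integer_, length(well))
  row <- rep(NA_character_, length(well))
  row[!bad] <- vapply(m[!bad], `[`, "", 2L)
  col[!bad] <- as.integer(vapply(m[!bad], `[`, "", 3L))
  bad <- bad | is.na(col) | col < 1L | col > 12L
  if (any(bad)) {
    stop("malformed well address(es): ",
         paste(unique(well[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(row = row, column = col, stringsAsFactors = FALSE)
}

#' @rdname parse_well
#' @param row,column row letters and column numbers to format.
#' @export
format_well <- function(row, column) {
  paste0(toupper(row), as.integer(column))
}

#' Construct a screen dataset
#'
#' A screen dataset is the long-format table of well records underlying every
#' downstream computation: one row per (plate, well, replicate), carrying the
#' well's role, compound, dose, status and fluorescence reading. Readings are
#' present if and only if the well status is `ok`; dead/defective/excluded
#' wells keep their status but contribute no reading anywhere downstream.
#'
#' @param wells data.frame with columns `plate_id`, `well`, `role`,
#'   `compound_id`, `dose_um`, `status`, `fluorescence`, `replicate` and
#'   optionally `day`.
#' @return an object of class `screen_dataset` (a validated data.frame).
#' @export
screen_dataset <- function(wells) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  required <- c("plate_id", "well", "role", "compound_id", "dose_um",
                "status", "fluorescence", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("screen dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"day" %in% names(wells)) wells$day <- rep(NA_character_, nrow(wells))
  if (nrow(wells)) {
    addr <- parse_well(wells$well)
    wells$well <- format_well(addr$row, addr$column)
    wells$row <- addr$row
    wells$column <- addr$column
  } else {
    wells$row <- character(0)
    wells$column <- integer(0)
  }
  wells$plate_id <- as.character(wells$plate_id)
  wells$compound_id <- as.character(wells$compound_id)
  wells$dose_um <- as.numeric(wells$dose_um)
  wells$fluorescence <- as.numeric(wells$fluorescence)
  wells$replicate <- as.integer(wells$replicate)

  bad_role <- !wells$role %in% WELL_ROLES
  if (any(bad_role)) {
    stop("unknown well role(s): ",
         paste(unique(wells$role[bad_role]), collapse = ", "), call. = FALSE)
  }
  scored <- !is.na(wells$status)
  bad_status <- scored & !wells$status %in% WELL_STATUSES
  if (any(bad_status)) {
    stop("unknown well status(es): ",
         paste(unique(wells$status[bad_status]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(wells$plate_id, wells$well, wells$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate well record: plate ", gsub("\r", " well ", dup),
         call. = FALSE)
  }
  ok <- scored & wells$status == "ok"
  if (any(ok & is.na(wells$fluorescence))) {
    stop("well(s) with status 'ok' but missing fluorescence: ",
         paste(utils::head(wells$well[ok & is.na(wells$fluorescence)], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (any(scored & !ok & !is.na(wells$fluorescence))) {
    stop("non-ok well(s) carry fluorescence readings", call. = FALSE)
  }
  if (any(!is.na(wells$fluorescence) & wells$fluorescence < 0)) {
    stop("negative fluorescence reading(s)", call. = FALSE)
  }
  if (any(!is.na(wells$dose_um) & wells$dose_um < 0)) {
    stop("negative dose(s)", call. = FALSE)
  }
  empty <- wells$role == "empty"
  if (any(empty & !is.na(wells$compound_id))) {
    stop("empty well(s) must not carry a compound", call. = FALSE)
  }
  zero_dose <- !is.na(wells$dose_um) & wells$dose_um == 0
  if (any(zero_dose & wells$role == "test")) {
    stop("dose 0 is reserved for vehicle/negative-control wells",
         call. = FALSE)
  }
  cols <- c("plate_id", "well", "row", "column", "role", "compound_id",
            "dose_um", "status", "fluorescence", "replicate", "day")
  wells <- wells[, cols]
  class(wells) <- c("screen_dataset", "data.frame")
  wells
}

#' Read a plate map
#'
#' Reads the CSV plate-map layout (columns `plate_id`, `well`, `role`,
#' `compound_id`, `dose_um`) into a screen-dataset skeleton with no readings
#' attached. Duplicate wells and unknown role labels are hard errors.
#'
#' @param path path to the plate-map CSV.
#' @return a `screen_dataset` skeleton (status and fluorescence all missing,
#'   replicate NA).
#' @seealso [read_readings()] to attach well readings.
#' @export
read_plate_map <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("plate_id", "well", "role", "compound_id", "dose_um")
  missing_cols <- setdiff(required, names(pm))
  if (length(missing_cols)) {
    stop("plate map is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(pm$plate_id, toupper(trimws(pm$well)))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (plate, well) in plate map at row ", i + 1L, ": ",
         key[i], call. = FALSE)
  }
  pm$compound_id[pm$compound_id == ""] <- NA_character_
  n <- nrow(pm)
  screen_dataset(data.frame(
    plate_id = pm$plate_id,
    well = pm$well,
    role = pm$role,
    compound_id = pm$compound_id,
    dose_um = suppressWarnings(as.numeric(pm$dose_um)),
    status = rep(NA_character_, n),
    fluorescence = rep(NA_real_, n),
    replicate = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  ))
}

#' Attach well readings to a plate map
#'
#' Joins a long-format readings CSV (columns `plate_id`, `well`, `replicate`,
#' `status`, `fluorescence`, optional `day`) onto a plate-map skeleton. Every
#' reading must refer to a mapped well; `ok` wells must carry a numeric,
#' nonnegative fluorescence and non-ok wells must not.
#'
#' @param path path to the readings CSV.
#' @param dataset plate-map skeleton from [read_plate_map()].
#' @return a `screen_dataset` with one record per (plate, well, replicate)
#'   observed in the readings file.
#' @export
read_readings <- function(path, dataset) {
  rd <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("plate_id", "well", "replicate", "status", "fluorescence")
  missing_cols <- setdiff(required, names(rd))
  if (length(missing_cols)) {
    stop("readings file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rd$well <- toupper(trimws(rd$well))
  map_key <- paste(dataset$plate_id, dataset$well)
  idx <- match(paste(rd$plate_id, rd$well), map_key)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1L]
    stop("reading for unmapped well at row ", i + 1L, ": plate ",
         rd$plate_id[i], " well ", rd$well[i], call. = FALSE)
  }
  fl <- suppressWarnings(as.numeric(rd$fluorescence))
  fl[!nzchar(trimws(rd$fluorescence)) | is.na(rd$fluorescence)] <- NA_real_
  ok <- rd$status == "ok"
  if (any(ok & is.na(fl))) {
    stop("ok well(s) with missing fluorescence at row(s) ",
         paste(utils::head(which(ok & is.na(fl)) + 1L, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(fl) & fl < 0)) {
    stop("negative fluorescence at row(s) ",
         paste(utils::head(which(!is.na(fl) & fl < 0) + 1L, 5L),
               collapse = ", "), call. = FALSE)
  }
  fl[!ok] <- NA_real_
  screen_dataset(data.frame(
    plate_id = rd$plate_id,
    well = rd$well,
    role = dataset$role[idx],
    compound_id = dataset$compound_id[idx],
    dose_um = dataset$dose_um[idx],
    status = rd$status,
    fluorescence = fl,
    replicate = as.integer(rd$replicate),
    day = if ("day" %in% names(rd)) rd$day else NA_character_,
    stringsAsFactors = FALSE
  ))
}

#' Write a screen dataset to plate-map and readings CSVs
#'
#' Inverse of [read_plate_map()] + [read_readings()]: a written dataset
#' round-trips to identical records.
#'
#' @param dataset a `screen_dataset`.
#' @param plate_map_path,readings_path output CSV paths; either may be `NULL`
#'   to skip that file.
#' @return invisibly, the paths written.
#' @export
write_screen <- function(dataset, plate_map_path = NULL,
                         readings_path = NULL) {
  if (!is.null(plate_map_path)) {
    pm <- unique(dataset[, c("plate_id", "well", "role", "compound_id",
                             "dose_um")])
    utils::write.csv(pm, plate_map_path, row.names = FALSE, na = "")
  }
  if (!is.null(readings_path)) {
    rd <- dataset[, c("plate_id", "well", "replicate", "status",
                      "fluorescence", "day")]
    utils::write.csv(rd, readings_path, row.names = FALSE, na = "")
  }
  invisible(c(plate_map_path, readings_path))
}

#' Analysis configuration
#'
#' Bundles the thresholds and scoring policy used throughout the pipeline.
#' Defaults follow the screen's published operating point: wells scoring
#' below -0.5 are inhibitors (below -1.0 strong inhibitors) and above +1.0
#' activators.
#'
#' @param inhibitor_threshold SSMD* cutoff below which a well is an inhibitor
#'   (default -0.5).
#' @param strong_inhibitor_threshold stricter inhibitor cutoff (default -1.0).
#' @param activator_threshold SSMD* cutoff above which a well is an activator
#'   (default +1.0).
#' @param reference_policy which wells form the plate-wise SSMD* reference:
#'   `"test"` (all ok test wells, the default), `"test_loo"` (leave the scored
#'   test well out of its own reference) or `"test_plus_negative"` (ok test
#'   plus ok negative-control wells).
#' @param min_reference minimum number of reference wells a plate needs to be
#'   scored (default 8).
#' @param denominator_constant multiplier of the robust scale in the SSMD*
#'   denominator; the default `sqrt(2)` accounts for the variance of a
#'   single-well difference from the reference population. Set to 1 to match
#'   conventions that score against the reference scale directly.
#' @param seed optional integer seed recorded with the configuration.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(inhibitor_threshold = -0.5,
                            strong_inhibitor_threshold = -1.0,
                            activator_threshold = 1.0,
                            reference_policy = c("test", "test_loo",
                                                 "test_plus_negative"),
                            min_reference = 8L,
                            denominator_constant = sqrt(2),
                            seed = NULL) {
  reference_policy <- match.arg(reference_policy)
  stopifnot(is.numeric(inhibitor_threshold),
            is.numeric(strong_inhibitor_threshold),
            is.numeric(activator_threshold),
            min_reference >= 2, denominator_constant > 0)
  if (!(strong_inhibitor_threshold <= inhibitor_threshold &&
        inhibitor_threshold < 0 && 0 < activator_threshold)) {
    stop("thresholds must satisfy strong <= inhibitor < 0 < activator",
         call. = FALSE)
  }
  structure(list(
    inhibitor_threshold = inhibitor_threshold,
    strong_inhibitor_threshold = strong_inhibitor_threshold,
    activator_threshold = activator_threshold,
    reference_policy = reference_policy,
    min_reference = as.integer(min_reference),
    denominator_constant = denominator_constant,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "analysis_config")
}

#' Read or write an analysis configuration file
#'
#' Configurations are stored as YAML with keys mirroring the
#' [analysis_config()] arguments.
#'
#' @param path file path.
#' @param config an `analysis_config`.
#' @return `read_analysis_config()` returns an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a screen dataset
#'
#' Report-only validation ahead of scoring: per-plate control counts, plates
#' whose ok test-well count falls below the minimum reference size, and the
#' plate-replicate inventory. Never mutates the data.
#'
#' @param dataset a `screen_dataset`.
#' @param config an [analysis_config()].
#' @return an object of class `screen_validation` with elements `inventory`
#'   (per plate-replicate well/control counts), `warnings` (character) and
#'   `errors` (character).
#' @export
validate_screen <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "screen_dataset"))
  scored <- dataset[!is.na(dataset$replicate), , drop = FALSE]
  key <- interaction(scored$plate_id, scored$replicate, drop = TRUE)
  inv <- do.call(rbind, lapply(split(scored, key), function(p) {
    ok <- !is.na(p$status) & p$status == "ok"
    data.frame(
      plate_id = p$plate_id[1L],
      replicate = p$replicate[1L],
      n_wells = nrow(p),
      n_ok = sum(ok),
      n_ok_test = sum(ok & p$role == "test"),
      n_ok_positive = sum(ok & p$role == "positive_control"),
      n_ok_negative = sum(ok & p$role == "negative_control"),
      n_excluded = sum(!is.na(p$status) & p$status != "ok"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(inv) <- NULL
  warnings <- character(0)
  if (!is.null(inv) && nrow(inv)) {
    low <- inv$n_ok_test < config$min_reference
    if (any(low)) {
      warnings <- c(warnings, sprintf(
        "insufficient reference: plate %s replicate %d has %d ok test wells (minimum %d)",
        inv$plate_id[low], inv$replicate[low], inv$n_ok_test[low],
        config$min_reference))
    }
    no_neg <- inv$n_ok_negative < 2L
    if (any(no_neg)) {
      warnings <- c(warnings, sprintf(
        "plate %s replicate %d has fewer than 2 ok negative-control wells",
        inv$plate_id[no_neg], inv$replicate[no_neg]))
    }
    no_pos <- inv$n_ok_positive < 1L
    if (any(no_pos)) {
      warnings <- c(warnings, sprintf(
        "plate %s replicate %d has no ok positive-control well",
        inv$plate_id[no_pos], inv$replicate[no_pos]))
    }
  }
  structure(list(inventory = inv, warnings = warnings, errors = character(0),
                 n_compounds = length(unique(
                   dataset$compound_id[dataset$role == "test" &
                                         !is.na(dataset$compound_id)]))),
            class = "screen_validation")
}

#' Standard 96-well screening layout
#'
#' The default plate layout used by the simulators and rescreen manifests:
#' wells are filled row-major with 12 positive-control wells (row A), 12
#' negative-control wells (row B), then test wells; remaining wells are empty.
#'
#' @param n_test,n_pos,n_neg wells per role (defaults 48/12/12).
#' @return data.frame with columns `well` and `role`.
#' @export
plate_layout_96 <- function(n_test = 48L, n_pos = 12L, n_neg = 12L) {
  if (n_test + n_pos + n_neg > 96L) {
    stop("layout exceeds 96 wells", call. = FALSE)
  }
  wells <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  role <- rep("empty", 96L)
  role[seq_len(n_pos)] <- "positive_control"
  role[n_pos + seq_len(n_neg)] <- "negative_control"
  role[n_pos + n_neg + seq_len(n_test)] <- "test"
  data.frame(well = wells, role = role, stringsAsFactors = FALSE)
}
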