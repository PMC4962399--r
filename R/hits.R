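#' Classify a well from its SSMD* score and status
#'
#' Status is consulted first: dead wells are `toxic` and defective/excluded
#' wells are `excluded`, regardless of any score. Ok wells are classified by
#' thresholds: score below the strong-inhibitor cutoff (default -1.0) is a
#' `strong_inhibitor`, below the inhibitor cutoff (default -0.5) an
#' `inhibitor`, above the activator cutoff (default +1.0) an `activator`,
#' otherwise `inactive`. Cutoffs are strict inequalities: a well exactly at
#' -0.5 is not a hit.
#'
#' @param score SSMD* score(s); NA for non-ok wells.
#' @param status well status(es) (`ok`, `dead`, `defective`, `excluded`).
#' @param config an [analysis_config()].
#' @return character vector of well classes.
#' @examples
#' classify_well(c(-0.6, 0, 1.2), rep("ok", 3))
#' classify_well(NA, "dead")
#' @export
classify_well <- function(score, status, config = analysis_config()) {
  n <- max(length(score), length(status))
  score <- rep_len(score, n)
  status <- rep_len(status, n)
  out <- character(n)
  out[status == "dead"] <- "toxic"
  out[status %in% c("defective", "excluded")] <- "excluded"
  ok <- status == "ok"
  if (any(ok & is.na(score))) {
    stop("ok well(s) with missing score", call. = FALSE)
  }
  s <- score[ok]
  cls <- rep("inactive", length(s))
  cls[s < config$inhibitor_threshold] <- "inhibitor"
  cls[s < config$strong_inhibitor_threshold] <- "strong_inhibitor"
  cls[s > config$activator_threshold] <- "activator"
  out[ok] <- cls
  out
}

#' Per-replicate classification of test compounds
#'
#' Classifies every test-compound well of a scored screen with
#' [classify_well()]. Control wells are excluded: their assessment belongs to
#' QC, not hit calling.
#'
#' @param screen an `ssmd_screen` from [score_screen()].
#' @param config an [analysis_config()]; defaults to the one stored in
#'   `screen`.
#' @return data.frame with one row per test-compound well and columns
#'   `compound_id`, `plate_id`, `well`, `replicate`, `ssmd_star`, `status`,
#'   `class`.
#' @export
classify_screen <- function(screen, config = NULL) {
  stopifnot(inherits(screen, "ssmd_screen"))
  if (is.null(config)) config <- screen$config
  sc <- screen$scores[screen$scores$role == "test" &
                        !is.na(screen$scores$compound_id), , drop = FALSE]
  out <- sc[, c("compound_id", "plate_id", "well", "replicate", "ssmd_star",
                "status")]
  out$class <- classify_well(sc$ssmd_star, sc$status, config)
  rownames(out) <- NULL
  out
}

#' Replicate-concordant hit calls
#'
#' Applies the replicated-hit rule: a compound is a final hit only when both
#' screen replicates agree. Concordance at the -0.5 level treats
#' `strong_inhibitor` as an inhibitor, so (strong_inhibitor, inhibitor)
#' yields a final `inhibitor`; only (strong_inhibitor, strong_inhibitor) is a
#' final `strong_inhibitor`. A compound dead in either replicate is called
#' `toxic` and flagged for rescreen at lower doses. Discordant pairs — a hit
#' in one replicate, inactive in the other — become `not_replicated` and are
#' never emitted as hits. Compounds observed in only one replicate are
#' flagged, never silently dropped.
#'
#' Activator calls carry an `autofluorescence_suspect` flag: compounds that
#' auto-fluoresce (or are mildly toxic) can raise the readout without
#' touching the stress pathway, so activator hits warrant an optical
#' counter-assay. The flag is informational only.
#'
#' @param calls per-replicate classification from [classify_screen()], or a
#'   compatible data.frame with columns `compound_id`, `replicate`,
#'   `ssmd_star`, `class`. Exactly two replicates are required.
#' @param replicates which two replicate labels to compare (default: the two
#'   present).
#' @return an object of class `hit_calls`: data.frame with per-replicate
#'   scores/classes, `final_call`, and logical flags `rescreen_recommended`,
#'   `autofluorescence_suspect`, `missing_replicate`.
#' @export
concordant_hits <- function(calls, replicates = NULL) {
  required <- c("compound_id", "replicate", "ssmd_star", "class")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols)) {
    stop("calls are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(replicates)) replicates <- sort(unique(calls$replicate))
  if (length(replicates) != 2L) {
    stop("concordant_hits() requires exactly two replicates; got ",
         length(replicates), call. = FALSE)
  }
  r1 <- calls[calls$replicate == replicates[1L], , drop = FALSE]
  r2 <- calls[calls$replicate == replicates[2L], , drop = FALSE]
  if (anyDuplicated(r1$compound_id) || anyDuplicated(r2$compound_id)) {
    stop("a compound appears more than once within a replicate",
         call. = FALSE)
  }
  compounds <- sort(union(r1$compound_id, r2$compound_id))
  i1 <- match(compounds, r1$compound_id)
  i2 <- match(compounds, r2$compound_id)
  c1 <- r1$class[i1]; c2 <- r2$class[i2]
  out <- data.frame(
    compound_id = compounds,
    score_rep1 = r1$ssmd_star[i1],
    score_rep2 = r2$ssmd_star[i2],
    class_rep1 = c1,
    class_rep2 = c2,
    stringsAsFactors = FALSE
  )
  final <- rep("not_replicated", length(compounds))
  missing_rep <- is.na(c1) | is.na(c2)
  toxic <- (!is.na(c1) & c1 == "toxic") | (!is.na(c2) & c2 == "toxic")
  both <- !missing_rep & !toxic
  agree <- both & c1 == c2
  final[agree] <- c1[agree]
  # concordant at the -0.5 level but not at -1.0
  inh_pair <- both & !agree &
    c1 %in% c("inhibitor", "strong_inhibitor") &
    c2 %in% c("inhibitor", "strong_inhibitor")
  final[inh_pair] <- "inhibitor"
  final[toxic] <- "toxic"
  final[missing_rep & !toxic] <- "not_replicated"
  out$final_call <- final
  out$rescreen_recommended <- toxic
  out$autofluorescence_suspect <- final == "activator"
  out$missing_replicate <- missing_rep
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Screen hit summary
#'
#' Tabulates replicated hits per threshold in the layout of a screen
#' statistics table: compounds concordantly below -0.5 (all inhibitors),
#' below -1.0 (strong inhibitors), above +1.0 (activators), and those that
#' caused death. Percentages are exact (`100 * count / n_screened`); the
#' print method rounds for display.
#'
#' @param calls a `hit_calls` object from [concordant_hits()].
#' @param n_screened number of compounds screened (default: compounds in
#'   `calls`).
#' @param config an [analysis_config()] supplying the threshold labels.
#' @return an object of class `hit_summary`: data.frame with columns
#'   `threshold`, `n_hits`, `n_screened`, `pct_hits`.
#' @export
hit_summary <- function(calls, n_screened = NULL,
                        config = analysis_config()) {
  stopifnot(inherits(calls, "hit_calls"))
  if (is.null(n_screened)) n_screened <- nrow(calls)
  if (n_screened < 1L) stop("n_screened must be >= 1", call. = FALSE)
  n_inh <- sum(calls$final_call %in% c("inhibitor", "strong_inhibitor"))
  n_strong <- sum(calls$final_call == "strong_inhibitor")
  n_act <- sum(calls$final_call == "activator")
  n_tox <- sum(calls$final_call == "toxic")
  out <- data.frame(
    threshold = c(sprintf("below %s", format(config$inhibitor_threshold)),
                  sprintf("below %s",
                          format(config$strong_inhibitor_threshold)),
                  sprintf("above %s", format(config$activator_threshold)),
                  "caused death"),
    n_hits = c(n_inh, n_strong, n_act, n_tox),
    n_screened = n_screened,
    stringsAsFactors = FALSE
  )
  out$pct_hits <- 100 * out$n_hits / out$n_screened
  class(out) <- c("hit_summary", "data.frame")
  out
}

#' Rescreen manifest for toxic compounds
#'
#' Compounds that killed the embryos at the screening dose are rescreened at
#' lower doses to detect activity below the toxic window. The manifest lays
#' the toxic compounds out on fresh plates (standard layout), one row per
#' toxic compound per rescreen dose, and is directly importable by
#' [read_plate_map()]. With `include_controls = TRUE` each generated plate
#' additionally carries the standard riluzole/vehicle control wells.
#'
#' @param calls a `hit_calls` object.
#' @param doses rescreen doses in uM (default 1 and 0.1).
#' @param include_controls also emit control wells on each plate.
#' @param control_dose positive-control dose in uM (default 10).
#' @param plate_prefix prefix for generated plate ids.
#' @return data.frame in plate-map format (`plate_id`, `well`, `role`,
#'   `compound_id`, `dose_um`); zero rows if nothing is toxic.
#' @export
toxic_rescreen_list <- function(calls, doses = c(1, 0.1),
                                include_controls = FALSE, control_dose = 10,
                                plate_prefix = "RS") {
  stopifnot(inherits(calls, "hit_calls"))
  toxic <- calls$compound_id[calls$final_call == "toxic"]
  empty <- data.frame(plate_id = character(0), well = character(0),
                      role = character(0), compound_id = character(0),
                      dose_um = numeric(0), stringsAsFactors = FALSE)
  if (!length(toxic)) return(empty)
  layout <- plate_layout_96()
  test_wells <- layout$well[layout$role == "test"]
  ctrl <- if (include_controls) {
    layout[layout$role %in% c("positive_control", "negative_control"), ]
  } else {
    layout[0L, ]
  }
  out <- list()
  for (d in doses) {
    n_plates <- ceiling(length(toxic) / length(test_wells))
    for (p in seq_len(n_plates)) {
      idx <- ((p - 1L) * length(test_wells) + 1L):
        min(p * length(test_wells), length(toxic))
      plate_id <- sprintf("%s_%g_%02d", plate_prefix, d, p)
      rows <- data.frame(
        plate_id = plate_id,
        well = c(ctrl$well, test_wells[seq_along(idx)]),
        role = c(ctrl$role, rep("test", length(idx))),
        compound_id = c(ifelse(ctrl$role == "positive_control", "riluzole",
                               "vehicle"), toxic[idx]),
        dose_um = c(ifelse(ctrl$role == "positive_control", control_dose, 0),
                    rep(d, length(idx))),
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Export a hit table as CSV
#'
#' @param calls a `hit_calls` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hits <- function(calls, path) {
  stopifnot(inherits(calls, "hit_calls"))
  utils::write.csv(as.data.frame(calls), path, row.names = FALSE, na = "")
  invisible(path)
}
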