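#' Per-plate sensitivity and specificity from control wells
#'
#' The control wells carry a built-in truth: every positive control should be
#' a hit and every negative control should not. At a given inhibitor
#' threshold, a positive control scoring below it is a true positive (else a
#' false negative) and a negative control scoring at or above it is a true
#' negative (else a false positive); a negative control exactly at the
#' threshold therefore counts as a true negative, matching the strict
#' "below threshold" hit definition. Then
#' `sensitivity = 100 * TP / (TP + FN)` and
#' `specificity = 100 * TN / (TN + FP)`.
#'
#' @param plate_scores a `plate_scores` object from [ssmd_star()], or a
#'   data.frame of its `scores` component (single plate-replicate).
#' @param threshold SSMD* inhibitor threshold (default -0.5).
#' @return an object of class `plate_qc`: list with `plate_id`, `replicate`,
#'   `threshold`, counts `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity` (NA when a control type is absent) and `flags`.
#' @export
plate_sensitivity_specificity <- function(plate_scores, threshold = -0.5) {
  sc <- if (inherits(plate_scores, "plate_scores")) plate_scores$scores
        else as.data.frame(plate_scores)
  ok <- !is.na(sc$ssmd_star)
  pos <- sc$ssmd_star[ok & sc$role == "positive_control"]
  neg <- sc$ssmd_star[ok & sc$role == "negative_control"]
  tp <- sum(pos < threshold); fn <- sum(pos >= threshold)
  tn <- sum(neg >= threshold); fp <- sum(neg < threshold)
  flags <- character(0)
  sens <- if (length(pos)) 100 * tp / (tp + fn) else {
    flags <- c(flags, "no scored positive controls"); NA_real_ }
  spec <- if (length(neg)) 100 * tn / (tn + fp) else {
    flags <- c(flags, "no scored negative controls"); NA_real_ }
  structure(list(
    plate_id = sc$plate_id[1L], replicate = sc$replicate[1L],
    threshold = threshold, tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = sens, specificity = spec, flags = flags
  ), class = "plate_qc")
}

#' Screen-level quality control
#'
#' Computes per-plate sensitivity/specificity at one or more inhibitor
#' thresholds and summarizes them across plates as mean +/- SD, per replicate
#' — the layout of a screen QC table. Tightening the threshold (e.g. -0.5 to
#' -1.0) trades sensitivity for specificity; evaluating several thresholds
#' side by side documents that trade-off.
#'
#' @param screen an `ssmd_screen` from [score_screen()].
#' @param thresholds inhibitor thresholds to evaluate (default -0.5 and
#'   -1.0).
#' @return an object of class `screen_qc`: list with `per_plate` (data.frame
#'   of per-plate counts and rates per threshold), `summary` (replicate x
#'   threshold mean/SD of sensitivity and specificity over plates with both
#'   control types), and `failed` copied from the screen.
#' @export
screen_qc <- function(screen, thresholds = c(-0.5, -1.0)) {
  stopifnot(inherits(screen, "ssmd_screen"))
  sc <- screen$scores
  parts <- split(sc, interaction(sc$plate_id, sc$replicate, drop = TRUE))
  rows <- list()
  for (th in thresholds) {
    for (p in parts) {
      q <- plate_sensitivity_specificity(p, th)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = q$plate_id, replicate = q$replicate, threshold = th,
        tp = q$tp, fn = q$fn, tn = q$tn, fp = q$fp,
        sensitivity = q$sensitivity, specificity = q$specificity,
        flagged = length(q$flags) > 0L, stringsAsFactors = FALSE)
    }
  }
  per_plate <- do.call(rbind, rows)
  rownames(per_plate) <- NULL
  usable <- per_plate[!is.na(per_plate$sensitivity) &
                        !is.na(per_plate$specificity), , drop = FALSE]
  summ <- NULL
  if (nrow(usable)) {
    grp <- interaction(usable$replicate, usable$threshold, drop = TRUE)
    summ <- do.call(rbind, lapply(split(usable, grp), function(g) {
      data.frame(
        replicate = g$replicate[1L], threshold = g$threshold[1L],
        n_plates = nrow(g),
        sensitivity_mean = mean(g$sensitivity),
        sensitivity_sd = if (nrow(g) > 1L) stats::sd(g$sensitivity) else 0,
        specificity_mean = mean(g$specificity),
        specificity_sd = if (nrow(g) > 1L) stats::sd(g$specificity) else 0,
        stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  }
  structure(list(per_plate = per_plate, summary = summ,
                 thresholds = thresholds, failed = screen$failed),
            class = "screen_qc")
}

#' Control variability within and between plates
#'
#' Day-to-day animal variation is the dominant noise source in a live-embryo
#' screen; this report quantifies it from the raw control readings. For each
#' control type and replicate it gives the within-plate coefficient of
#' variation (CV, in percent, per plate) and the between-plate CV of the
#' plate control means, with a per-day breakdown when day labels are present.
#'
#' @param dataset a `screen_dataset` with readings.
#' @return an object of class `control_variability`: list with `within_plate`
#'   (per plate/replicate/role CV), `between_plate` (per replicate/role CV of
#'   plate means), and `by_day` (or NULL when no day labels exist).
#' @export
control_variability <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  ctrl <- dataset[dataset$role %in% c("positive_control",
                                      "negative_control") &
                    !is.na(dataset$fluorescence), , drop = FALSE]
  if (!nrow(ctrl)) stop("no control readings in dataset", call. = FALSE)
  cv <- function(x) if (length(x) > 1L && mean(x) > 0)
    100 * stats::sd(x) / mean(x) else NA_real_
  grp <- interaction(ctrl$plate_id, ctrl$replicate, ctrl$role, drop = TRUE)
  within <- do.call(rbind, lapply(split(ctrl, grp), function(g) {
    data.frame(plate_id = g$plate_id[1L], replicate = g$replicate[1L],
               role = g$role[1L], n = nrow(g), mean = mean(g$fluorescence),
               cv = cv(g$fluorescence), stringsAsFactors = FALSE)
  }))
  rownames(within) <- NULL
  bgrp <- interaction(within$replicate, within$role, drop = TRUE)
  between <- do.call(rbind, lapply(split(within, bgrp), function(g) {
    data.frame(replicate = g$replicate[1L], role = g$role[1L],
               n_plates = nrow(g), cv_of_plate_means = cv(g$mean),
               stringsAsFactors = FALSE)
  }))
  rownames(between) <- NULL
  by_day <- NULL
  if (any(!is.na(ctrl$day))) {
    dgrp <- interaction(ctrl$day, ctrl$replicate, ctrl$role, drop = TRUE)
    by_day <- do.call(rbind, lapply(split(ctrl, dgrp), function(g) {
      data.frame(day = g$day[1L], replicate = g$replicate[1L],
                 role = g$role[1L], n = nrow(g),
                 mean = mean(g$fluorescence), cv = cv(g$fluorescence),
                 stringsAsFactors = FALSE)
    }))
    rownames(by_day) <- NULL
  }
  structure(list(within_plate = within, between_plate = between,
                 by_day = by_day), class = "control_variability")
}

#' Advisory plate pass/fail
#'
#' A plate fails when its positive controls show no activity at the
#' inhibitor threshold (no true positives — in a healthy screen the positive
#' control is always active) or when its reference was degenerate and it
#' could not be scored. The verdict is advisory: nothing is deleted.
#'
#' @param plate_qc a `plate_qc` from [plate_sensitivity_specificity()], or
#'   NULL when the plate failed scoring.
#' @param config an [analysis_config()].
#' @param scoring_failure optional character reason recorded by
#'   [score_screen()] for an unscorable plate.
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
plate_pass_fail <- function(plate_qc = NULL, config = analysis_config(),
                            scoring_failure = NULL) {
  reasons <- character(0)
  if (!is.null(scoring_failure)) {
    reasons <- c(reasons, paste("scoring failed:", scoring_failure))
  }
  if (!is.null(plate_qc)) {
    stopifnot(inherits(plate_qc, "plate_qc"))
    if (is.na(plate_qc$sensitivity)) {
      reasons <- c(reasons, "no scored positive controls")
    } else if (plate_qc$tp == 0L) {
      reasons <- c(reasons, "positive controls show no activity")
    }
  } else if (is.null(scoring_failure)) {
    reasons <- c(reasons, "no QC available for plate")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Export a screen QC report
#'
#' Writes the per-plate table as CSV and the screen-level summary as JSON.
#'
#' @param qc a `screen_qc` object.
#' @param csv_path,json_path output paths; either may be NULL.
#' @return invisibly, the paths written.
#' @export
write_qc <- function(qc, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(qc, "screen_qc"))
  if (!is.null(csv_path)) {
    utils::write.csv(qc$per_plate, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(thresholds = qc$thresholds,
                              summary = qc$summary,
                              failed_plates = qc$failed),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(csv_path, json_path))
}
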