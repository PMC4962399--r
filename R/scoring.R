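#' Single-well SSMD* scores for one plate
#'
#' Scores every ok well of a plate against the plate's own robust reference.
#' The reference assumes most test compounds are inert: by default it is the
#' plate's ok test wells, whose median estimates the inert signal level and
#' whose scaled median absolute deviation (1.4826 x MAD) estimates the well
#' noise. Well i is scored as
#' \deqn{score_i = (X_i - median_{ref}) / (c \times 1.4826 \times MAD_{ref})}
#' with \eqn{c = \sqrt 2} by default, the variance inflation of a single-well
#' difference from the reference population. Control wells are scored against
#' the same reference.
#'
#' @param wells the well records of a single plate-replicate (a subset of a
#'   `screen_dataset`).
#' @param config an [analysis_config()]; its `reference_policy`,
#'   `min_reference` and `denominator_constant` are used here.
#' @return an object of class `plate_scores`: list with `plate_id`,
#'   `replicate`, `reference` (`location`, `scale`, `n_reference`) and
#'   `scores`, a data.frame with one row per non-empty well (`ssmd_star` is NA
#'   for non-ok wells).
#' @examples
#' cfg <- analysis_config(min_reference = 4)
#' wells <- data.frame(
#'   plate_id = "P1", well = paste0("C", 1:5), role = "test",
#'   compound_id = paste0("C", 1:5), dose_um = 10, status = "ok",
#'   fluorescence = c(10, 12, 14, 16, 18), replicate = 1L)
#' ssmd_star(screen_dataset(wells), cfg)$scores$ssmd_star
#' @export
ssmd_star <- function(wells, config = analysis_config()) {
  wells <- as.data.frame(wells)
  if (length(unique(wells$plate_id)) != 1L ||
      length(unique(wells$replicate)) != 1L) {
    stop("ssmd_star() scores one plate-replicate at a time", call. = FALSE)
  }
  plate_id <- wells$plate_id[1L]
  replicate <- wells$replicate[1L]
  ok <- !is.na(wells$status) & wells$status == "ok"
  ref_roles <- switch(config$reference_policy,
                      test = "test",
                      test_loo = "test",
                      test_plus_negative = c("test", "negative_control"))
  in_ref <- ok & wells$role %in% ref_roles
  ref <- wells$fluorescence[in_ref]
  if (length(ref) < config$min_reference) {
    stop(sprintf("plate %s replicate %s: only %d reference wells (minimum %d)",
                 plate_id, replicate, length(ref), config$min_reference),
         call. = FALSE)
  }
  location <- stats::median(ref)
  scale <- stats::mad(ref)
  if (scale <= 0) {
    stop(sprintf("plate %s replicate %s: degenerate reference (MAD is zero)",
                 plate_id, replicate), call. = FALSE)
  }
  denom <- config$denominator_constant * scale

  out <- wells[wells$role != "empty",
               c("plate_id", "replicate", "well", "role", "compound_id",
                 "dose_um", "status", "fluorescence")]
  out$ssmd_star <- NA_real_
  ok_out <- !is.na(out$status) & out$status == "ok"
  if (config$reference_policy == "test_loo") {
    # leave-one-out: each scored test well is removed from its own reference
    ref_wells <- wells$well[in_ref]
    sc <- numeric(sum(ok_out))
    idx <- which(ok_out)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (out$role[i] == "test" && out$well[i] %in% ref_wells) {
        r <- ref[ref_wells != out$well[i]]
        if (length(r) < max(2L, config$min_reference - 1L)) {
          stop(sprintf(
            "plate %s replicate %s: leave-one-out reference below minimum",
            plate_id, replicate), call. = FALSE)
        }
        loc_i <- stats::median(r)
        sca_i <- stats::mad(r)
        if (sca_i <= 0) {
          stop(sprintf(
            "plate %s replicate %s: degenerate leave-one-out reference",
            plate_id, replicate), call. = FALSE)
        }
        sc[j] <- (out$fluorescence[i] - loc_i) /
          (config$denominator_constant * sca_i)
      } else {
        sc[j] <- (out$fluorescence[i] - location) / denom
      }
    }
    out$ssmd_star[ok_out] <- sc
  } else {
    out$ssmd_star[ok_out] <- (out$fluorescence[ok_out] - location) / denom
  }
  rownames(out) <- NULL
  structure(list(
    plate_id = plate_id,
    replicate = replicate,
    reference = list(location = location, scale = scale,
                     n_reference = length(ref)),
    scores = out
  ), class = "plate_scores")
}

#' Score a whole screen with SSMD*
#'
#' Applies [ssmd_star()] to every plate-replicate of a dataset. This is the
#' central estimator of the package: the returned object carries one score
#' per ok well, the per-plate robust references, and any plates that could
#' not be scored.
#'
#' @param dataset a `screen_dataset` with readings attached.
#' @param config an [analysis_config()].
#' @param on_error `"stop"` (default) aborts on the first unscorable plate;
#'   `"flag"` records the failure and continues, leaving that plate unscored.
#' @return an object of class `ssmd_screen`: list with `scores` (data.frame
#'   over all scored plates), `references`, `failed` (plate, replicate,
#'   reason) and `config`.
#' @seealso [classify_screen()], [screen_qc()], [plot.ssmd_screen()]
#' @export
score_screen <- function(dataset, config = analysis_config(),
                         on_error = c("stop", "flag")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  on_error <- match.arg(on_error)
  scored <- dataset[!is.na(dataset$replicate), , drop = FALSE]
  if (!nrow(scored)) stop("dataset has no readings to score", call. = FALSE)
  parts <- split(scored,
                 interaction(scored$plate_id, scored$replicate, drop = TRUE))
  scores <- list(); refs <- list(); failed <- list()
  for (p in parts) {
    res <- tryCatch(ssmd_star(p, config), error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      failed[[length(failed) + 1L]] <- data.frame(
        plate_id = p$plate_id[1L], replicate = p$replicate[1L],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      scores[[length(scores) + 1L]] <- res$scores
      refs[[length(refs) + 1L]] <- data.frame(
        plate_id = res$plate_id, replicate = res$replicate,
        location = res$reference$location, scale = res$reference$scale,
        n_reference = res$reference$n_reference, stringsAsFactors = FALSE)
    }
  }
  empty_fail <- data.frame(plate_id = character(0), replicate = integer(0),
                           reason = character(0), stringsAsFactors = FALSE)
  structure(list(
    scores = if (length(scores)) do.call(rbind, scores) else NULL,
    references = if (length(refs)) do.call(rbind, refs) else NULL,
    failed = if (length(failed)) do.call(rbind, failed) else empty_fail,
    config = config
  ), class = "ssmd_screen")
}

#' Control-group SSMD
#'
#' The replicated-control form of the strictly standardized median
#' difference: the median of all pairwise differences between positive and
#' negative control readings, divided by the sample standard deviation of
#' those differences. Inhibitory positives (lower fluorescence than the
#' vehicle wells) give negative values.
#'
#' @param positive,negative numeric reading vectors (at least 2 each).
#' @return a single SSMD value.
#' @examples
#' ssmd_controls(c(4, 6), c(10, 12))  # -3.674
#' @export
ssmd_controls <- function(positive, negative) {
  positive <- positive[!is.na(positive)]
  negative <- negative[!is.na(negative)]
  if (length(positive) < 2L || length(negative) < 2L) {
    stop("ssmd_controls() needs at least 2 readings per group", call. = FALSE)
  }
  d <- as.vector(outer(positive, negative, `-`))
  s <- stats::sd(d)
  if (s == 0) {
    stop("degenerate control groups: all pairwise differences identical",
         call. = FALSE)
  }
  stats::median(d) / s
}

#' Percent reduction in signal
#'
#' `100 * (1 - mean(treated) / mean(control))`; negative values indicate
#' activation. A median-based variant is available for skewed groups.
#'
#' @param treated,control numeric reading vectors.
#' @param use_median use group medians instead of means.
#' @return percent reduction (a single number).
#' @examples
#' percent_reduction(c(45, 55), c(90, 110))  # 50
#' @export
percent_reduction <- function(treated, control, use_median = FALSE) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (!length(treated) || !length(control)) {
    stop("percent_reduction() needs at least 1 reading per group",
         call. = FALSE)
  }
  avg <- if (use_median) stats::median else mean
  if (avg(control) <= 0) {
    stop("control average must be positive", call. = FALSE)
  }
  100 * (1 - avg(treated) / avg(control))
}

#' Conventional assay-window metrics
#'
#' Signal-to-background, signal-to-noise, z-score separation and Z'-factor
#' from positive- and negative-control readings, for side-by-side comparison
#' with SSMD. Metrics with zero denominators are returned as NA with an
#' `undefined` flag rather than erroring.
#'
#' @param positive,negative numeric reading vectors (at least 2 each).
#' @return list with `signal_to_background`, `signal_to_noise`,
#'   `z_score_separation`, `z_prime` and a character vector `undefined`.
#' @export
comparison_metrics <- function(positive, negative) {
  positive <- positive[!is.na(positive)]
  negative <- negative[!is.na(negative)]
  if (length(positive) < 2L || length(negative) < 2L) {
    stop("comparison_metrics() needs at least 2 readings per group",
         call. = FALSE)
  }
  mp <- mean(positive); mn <- mean(negative)
  sp <- stats::sd(positive); sn <- stats::sd(negative)
  undefined <- character(0)
  sb <- if (mn != 0) mp / mn else {undefined <- c(undefined, "signal_to_background"); NA_real_}
  s2n <- if (sn != 0) (mp - mn) / sn else {undefined <- c(undefined, "signal_to_noise"); NA_real_}
  zsep <- if (sp + sn != 0) (mp - mn) / (sp + sn) else {undefined <- c(undefined, "z_score_separation"); NA_real_}
  zp <- if (mp != mn) 1 - 3 * (sp + sn) / abs(mp - mn) else {undefined <- c(undefined, "z_prime"); NA_real_}
  list(signal_to_background = sb, signal_to_noise = s2n,
       z_score_separation = zsep, z_prime = zp, undefined = undefined)
}

#' Export per-well scores as CSV
#'
#' @param screen an `ssmd_screen` from [score_screen()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scores <- function(screen, path) {
  stopifnot(inherits(screen, "ssmd_screen"))
  utils::write.csv(screen$scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a scores CSV written by [write_scores()]
#'
#' @param path scores CSV path.
#' @param config the [analysis_config()] to attach.
#' @return an `ssmd_screen` (references are not recomputed; `failed` empty).
#' @export
read_scores <- function(path, config = analysis_config()) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate_id", "replicate", "well", "role", "compound_id",
                "status", "fluorescence", "ssmd_star")
  missing_cols <- setdiff(required, names(sc))
  if (length(missing_cols)) {
    stop("scores file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sc$plate_id <- as.character(sc$plate_id)
  sc$compound_id <- as.character(sc$compound_id)
  structure(list(scores = sc, references = NULL,
                 failed = data.frame(plate_id = character(0),
                                     replicate = integer(0),
                                     reason = character(0)),
                 config = config),
            class = "ssmd_screen")
}
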