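#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  inhibitor threshold:        SSMD* < %g\n",
              x$inhibitor_threshold))
  cat(sprintf("  strong inhibitor threshold: SSMD* < %g\n",
              x$strong_inhibitor_threshold))
  cat(sprintf("  activator threshold:        SSMD* > %g\n",
              x$activator_threshold))
  cat(sprintf("  reference policy: %s (minimum %d wells)\n",
              x$reference_policy, x$min_reference))
  cat(sprintf("  denominator constant: %.4f\n", x$denominator_constant))
  invisible(x)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "Screen dataset: %d well records, %d plate(s), %d replicate(s)\n",
    nrow(x), length(unique(x$plate_id)),
    length(unique(x$replicate[!is.na(x$replicate)]))))
  NextMethod()
}

#' @export
print.screen_validation <- function(x, ...) {
  cat("Screen validation report\n")
  cat(sprintf("  %d plate-replicate(s), %d test compound(s)\n",
              if (is.null(x$inventory)) 0L else nrow(x$inventory),
              x$n_compounds))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  } else cat("  no warnings\n")
  invisible(x)
}

#' @export
print.plate_scores <- function(x, ...) {
  cat(sprintf("SSMD* scores, plate %s replicate %s\n", x$plate_id,
              x$replicate))
  cat(sprintf("  reference: median %.4g, scale %.4g (n = %d)\n",
              x$reference$location, x$reference$scale,
              x$reference$n_reference))
  cat(sprintf("  %d well(s) scored\n", sum(!is.na(x$scores$ssmd_star))))
  invisible(x)
}

#' @export
print.ssmd_screen <- function(x, ...) {
  n_pr <- if (is.null(x$references)) 0L else nrow(x$references)
  cat(sprintf("SSMD*-scored screen: %d plate-replicate(s), %d scored well(s)\n",
              n_pr, if (is.null(x$scores)) 0L
              else sum(!is.na(x$scores$ssmd_star))))
  if (nrow(x$failed)) {
    cat(sprintf("  %d plate-replicate(s) failed scoring\n", nrow(x$failed)))
  }
  invisible(x)
}

#' Summarize a scored screen
#'
#' Per-role score distribution (median and range of SSMD*) plus the
#' per-plate reference statistics.
#'
#' @param object an `ssmd_screen`.
#' @param ... unused.
#' @return a list with `by_role` and `references`, invisibly printed.
#' @export
summary.ssmd_screen <- function(object, ...) {
  sc <- object$scores[!is.na(object$scores$ssmd_star), , drop = FALSE]
  by_role <- do.call(rbind, lapply(split(sc, sc$role), function(g) {
    data.frame(role = g$role[1L], n = nrow(g),
               median_score = stats::median(g$ssmd_star),
               min_score = min(g$ssmd_star), max_score = max(g$ssmd_star),
               stringsAsFactors = FALSE)
  }))
  rownames(by_role) <- NULL
  out <- list(by_role = by_role, references = object$references,
              failed = object$failed)
  class(out) <- "summary.ssmd_screen"
  out
}

#' @export
print.summary.ssmd_screen <- function(x, ...) {
  cat("SSMD* score distribution by role:\n")
  print(x$by_role, row.names = FALSE)
  if (nrow(x$failed)) {
    cat("Unscored plate-replicates:\n")
    print(x$failed, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a scored screen
#'
#' Strip plot of per-well SSMD* by well role, with the hit thresholds drawn
#' as horizontal lines — the standard picture for judging the separation of
#' positive controls from the inert test-well mass.
#'
#' @param x an `ssmd_screen`.
#' @param config an [analysis_config()] for the threshold lines (defaults to
#'   the one stored in `x`).
#' @param ... passed to [graphics::stripchart()].
#' @return invisibly, `x`.
#' @export
plot.ssmd_screen <- function(x, config = NULL, ...) {
  if (is.null(config)) config <- x$config
  sc <- x$scores[!is.na(x$scores$ssmd_star), , drop = FALSE]
  sc$role <- factor(sc$role, levels = c("negative_control", "test",
                                        "positive_control"))
  graphics::stripchart(ssmd_star ~ role, data = sc, vertical = TRUE,
                       method = "jitter", pch = 16,
                       cex = 0.5, col = c("grey40", "grey70", "black"),
                       ylab = "SSMD*", ...)
  graphics::abline(h = c(config$inhibitor_threshold,
                         config$strong_inhibitor_threshold,
                         config$activator_threshold),
                   lty = c(2, 3, 2), col = "red3")
  invisible(x)
}

#' @export
print.hit_calls <- function(x, ...) {
  tab <- table(x$final_call)
  cat(sprintf("Replicate-concordant hit calls for %d compound(s)\n",
              nrow(x)))
  for (cl in names(tab)) cat(sprintf("  %-16s %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' @export
print.hit_summary <- function(x, ...) {
  cat("Screen hit summary (replicated hits)\n")
  out <- as.data.frame(x)
  out$pct_hits <- paste0(signif(out$pct_hits, 2), " %")
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("Plate QC: plate %s replicate %s (threshold %g)\n",
              x$plate_id, x$replicate, x$threshold))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f %%  specificity %.1f %%\n",
              x$sensitivity, x$specificity))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("Screen QC summary (mean +/- SD over plates)\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf(
        "  replicate %s, threshold %g: sensitivity %.1f %% +/- %.1f, specificity %.1f %% +/- %.1f (%d plates)\n",
        s$replicate[i], s$threshold[i], s$sensitivity_mean[i],
        s$sensitivity_sd[i], s$specificity_mean[i], s$specificity_sd[i],
        s$n_plates[i]))
    }
  } else cat("  no plates with both control types scored\n")
  invisible(x)
}

#' @export
print.control_variability <- function(x, ...) {
  cat("Control variability\n")
  cat("  between-plate CV of plate control means:\n")
  print(x$between_plate, row.names = FALSE)
  cat(sprintf("  within-plate CV: %d plate/role group(s), median %.2f %%\n",
              nrow(x$within_plate),
              stats::median(x$within_plate$cv, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.dose_summary <- function(x, ...) {
  cat(sprintf("Dose-response summary (%s)\n", x$compound_id))
  print(x$per_dose, row.names = FALSE)
  if (!is.na(x$trend$statistic)) {
    cat(sprintf(
      "  trend: Spearman rho = %.3f, permutation p = %.4g (%d permutations)\n",
      x$trend$statistic, x$trend$p_permutation, x$trend$n_permutations))
  } else cat("  trend undefined (single dose level)\n")
  invisible(x)
}

#' Plot a dose summary
#'
#' Per-dose mean +/- SD of fluorescence against dose.
#'
#' @param x a `dose_summary`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.dose_summary <- function(x, ...) {
  pd <- x$per_dose
  ylim <- range(c(pd$mean - pd$sd, pd$mean + pd$sd), na.rm = TRUE)
  graphics::plot(pd$dose_um, pd$mean, ylim = ylim, pch = 16,
                 xlab = "dose (uM)", ylab = "fluorescence (AU)", ...)
  graphics::arrows(pd$dose_um, pd$mean - pd$sd, pd$dose_um, pd$mean + pd$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' @export
print.sim_screen <- function(x, ...) {
  tab <- table(x$truth$class)
  cat(sprintf("Simulated screen: %d compound(s), %d well record(s)\n",
              nrow(x$truth), nrow(x$dataset)))
  cat("  planted classes:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Pipeline recovery against planted truth\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
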