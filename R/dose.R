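#' Construct a dose series
#'
#' One compound's dose-response data: per-well readings at a vehicle dose
#' (0 uM) and one or more positive doses.
#'
#' @param dose_um numeric vector of per-well doses (0 = vehicle).
#' @param fluorescence numeric vector of per-well readings.
#' @param compound_id optional compound label.
#' @return an object of class `dose_series`.
#' @export
dose_series <- function(dose_um, fluorescence, compound_id = NA_character_) {
  stopifnot(length(dose_um) == length(fluorescence))
  keep <- !is.na(dose_um) & !is.na(fluorescence)
  dose_um <- dose_um[keep]; fluorescence <- fluorescence[keep]
  if (any(dose_um < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (!any(dose_um == 0)) {
    stop("dose series needs a vehicle (dose 0) group", call. = FALSE)
  }
  if (!any(dose_um > 0)) {
    stop("dose series needs at least one positive dose", call. = FALSE)
  }
  structure(list(compound_id = compound_id,
                 wells = data.frame(dose_um = dose_um,
                                    fluorescence = fluorescence)),
            class = "dose_series")
}

#' Summarize a dose series and test for monotone trend
#'
#' Per-dose mean, SD, n and percent reduction versus vehicle, plus a
#' rank-based monotone trend statistic: the Spearman correlation between dose
#' and per-well fluorescence over all wells (negative = dose-dependent
#' reduction). Because per-dose group sizes are small, significance comes
#' from a permutation test (readings shuffled across wells, two-sided on
#' |rho|, with the add-one correction) rather than an asymptotic formula.
#' No sigmoid/IC50 curve is fitted: the claim being tested is monotone
#' dose-dependence, not a potency estimate.
#'
#' @param series a [dose_series()].
#' @param n_permutations permutations for the trend p-value (default 1000).
#' @param seed integer seed for the permutation draw.
#' @param use_median passed to [percent_reduction()].
#' @return an object of class `dose_summary`: list with `per_dose`
#'   (data.frame `dose_um`, `n`, `mean`, `sd`, `pct_reduction`) and `trend`
#'   (`statistic`, `p_permutation`, `n_permutations`, `seed`; statistic NA
#'   when all wells share one dose level).
#' @export
dose_summary <- function(series, n_permutations = 1000L, seed = 1L,
                         use_median = FALSE) {
  stopifnot(inherits(series, "dose_series"))
  w <- series$wells
  vehicle <- w$fluorescence[w$dose_um == 0]
  if (mean(vehicle) <= 0) {
    stop("vehicle group mean must be positive", call. = FALSE)
  }
  per_dose <- do.call(rbind, lapply(split(w, w$dose_um), function(g) {
    data.frame(dose_um = g$dose_um[1L], n = nrow(g),
               mean = mean(g$fluorescence),
               sd = if (nrow(g) > 1L) stats::sd(g$fluorescence) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_dose <- per_dose[order(per_dose$dose_um), ]
  rownames(per_dose) <- NULL
  per_dose$pct_reduction <- vapply(per_dose$dose_um, function(d) {
    if (d == 0) 0 else percent_reduction(w$fluorescence[w$dose_um == d],
                                         vehicle, use_median = use_median)
  }, numeric(1))

  trend <- list(statistic = NA_real_, p_permutation = NA_real_,
                n_permutations = as.integer(n_permutations),
                seed = as.integer(seed))
  if (length(unique(w$dose_um)) >= 2L) {
    dr <- rank(w$dose_um)
    fr <- rank(w$fluorescence)
    rho <- stats::cor(dr, fr)
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      if (abs(stats::cor(dr, sample(fr))) >= abs(rho)) exceed <- exceed + 1L
    }
    trend$statistic <- rho
    trend$p_permutation <- (1 + exceed) / (1 + n_permutations)
  }
  structure(list(compound_id = series$compound_id, per_dose = per_dose,
                 trend = trend),
            class = "dose_summary")
}

#' Export a dose report
#'
#' Per-dose table as CSV and the trend block as JSON.
#'
#' @param summary a `dose_summary`.
#' @param csv_path,json_path output paths; either may be NULL.
#' @return invisibly, the paths written.
#' @export
write_dose_report <- function(summary, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(summary, "dose_summary"))
  if (!is.null(csv_path)) {
    utils::write.csv(summary$per_dose, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary$trend, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(c(csv_path, json_path))
}
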