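#' Simulation configuration for synthetic screens
#'
#' Parameters of the stochastic screen generator. Defaults emulate the
#' screen's design: 96-well plates with 48 test, 12 positive-control
#' (riluzole-like, 50 percent signal reduction) and 12 negative-control
#' (vehicle) wells, one embryo per well, two independent replicates of the
#' whole screen, log-normal well fluorescence with a coefficient of
#' variation of about 15 percent, multiplicative plate and day effects, a
#' mostly inert compound library with small inhibitor/activator minorities,
#' a toxic fraction whose embryos die, and a low background rate of
#' dead/defective wells unrelated to compound class.
#'
#' @param n_plates number of plates per replicate.
#' @param n_test,n_pos,n_neg wells per plate per role (must fit in 96).
#' @param replicates number of screen replicates (default 2).
#' @param baseline mean-scale fluorescence of an untreated well (arbitrary
#'   units).
#' @param cv well-to-well coefficient of variation of the log-normal
#'   baseline (default 0.15).
#' @param positive_control_effect multiplicative effect of the positive
#'   control (default 0.5, i.e. 50 percent reduction).
#' @param frac_inhibitor,frac_strong_inhibitor,frac_activator,frac_toxic
#'   fractions of test compounds planted in each class (remainder inert).
#' @param effect_inhibitor,effect_strong_inhibitor,effect_activator
#'   multiplicative effect factors for the planted classes.
#' @param toxicity_prob per-replicate death probability of a toxic
#'   compound's well (default 1).
#' @param exclusion_rate background probability that a non-toxic well is
#'   dead/defective (default 0.02).
#' @param plate_effect_sd,day_effect_sd SD of the multiplicative plate and
#'   day effects on the log scale.
#' @param plates_per_day plates sharing one experimental day.
#' @param planted_truth optional data.frame (`compound_id`, `class`,
#'   `effect_factor`) overriding the random class assignment.
#' @param seed integer seed; a fixed seed makes the generated screen
#'   byte-identical across calls.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_plates = 5L,
                              n_test = 48L, n_pos = 12L, n_neg = 12L,
                              replicates = 2L,
                              baseline = 1000,
                              cv = 0.15,
                              positive_control_effect = 0.5,
                              frac_inhibitor = 0.015,
                              frac_strong_inhibitor = 0.004,
                              frac_activator = 0.010,
                              frac_toxic = 0.070,
                              effect_inhibitor = 0.60,
                              effect_strong_inhibitor = 0.35,
                              effect_activator = 1.60,
                              toxicity_prob = 1.0,
                              exclusion_rate = 0.02,
                              plate_effect_sd = 0.05,
                              day_effect_sd = 0.10,
                              plates_per_day = 5L,
                              planted_truth = NULL,
                              seed = NULL) {
  if (n_test + n_pos + n_neg > 96L) {
    stop("occupied wells exceed a 96-well plate", call. = FALSE)
  }
  stopifnot(n_plates >= 1, replicates >= 1, baseline > 0, cv > 0,
            positive_control_effect > 0,
            effect_inhibitor > 0, effect_strong_inhibitor > 0,
            effect_activator > 0,
            toxicity_prob >= 0, toxicity_prob <= 1,
            exclusion_rate >= 0, exclusion_rate < 1,
            plate_effect_sd >= 0, day_effect_sd >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# lognormal sdlog giving a target coefficient of variation
.sdlog_for_cv <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a plate screen with planted ground truth
#'
#' Draws a full multi-plate, multi-replicate screen under the stochastic
#' model of [simulation_config()]: per ok well,
#' `fluorescence = exp(Normal(log baseline, sdlog)) * effect * plate * day`,
#' toxic wells are emitted with status `dead`, and background exclusions are
#' applied independently of compound class. Both replicates share the same
#' planted truth and plate layout but are independent noise draws.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_screen`: list with `dataset` (a
#'   `screen_dataset`), `truth` (data.frame `compound_id`, `class`,
#'   `effect_factor`) and `config`.
#' @export
simulate_screen <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_compounds <- config$n_plates * config$n_test
  truth <- config$planted_truth
  if (is.null(truth)) {
    n_inh <- round(config$frac_inhibitor * n_compounds)
    n_str <- round(config$frac_strong_inhibitor * n_compounds)
    n_act <- round(config$frac_activator * n_compounds)
    n_tox <- round(config$frac_toxic * n_compounds)
    cls <- rep("inactive", n_compounds)
    planted <- sample.int(n_compounds, n_inh + n_str + n_act + n_tox)
    cls[planted] <- rep(c("inhibitor", "strong_inhibitor", "activator",
                          "toxic"), c(n_inh, n_str, n_act, n_tox))
    eff <- rep(1, n_compounds)
    eff[cls == "inhibitor"] <- config$effect_inhibitor
    eff[cls == "strong_inhibitor"] <- config$effect_strong_inhibitor
    eff[cls == "activator"] <- config$effect_activator
    eff[cls == "toxic"] <- NA_real_
    truth <- data.frame(
      compound_id = sprintf("C%04d", seq_len(n_compounds)),
      class = cls, effect_factor = eff, stringsAsFactors = FALSE)
  } else {
    if (nrow(truth) != n_compounds) {
      stop("planted_truth must have one row per test compound (",
           n_compounds, ")", call. = FALSE)
    }
  }
  layout <- plate_layout_96(config$n_test, config$n_pos, config$n_neg)
  occupied <- layout[layout$role != "empty", ]
  test_wells <- occupied$well[occupied$role == "test"]
  sdlog <- .sdlog_for_cv(config$cv)
  mulog <- log(config$baseline)

  rows <- vector("list", config$replicates * config$n_plates)
  ri <- 0L
  for (rep_i in seq_len(config$replicates)) {
    n_days <- ceiling(config$n_plates / config$plates_per_day)
    day_eff <- exp(stats::rnorm(n_days, 0, config$day_effect_sd))
    plate_eff <- exp(stats::rnorm(config$n_plates, 0,
                                  config$plate_effect_sd))
    for (p in seq_len(config$n_plates)) {
      day_i <- ceiling(p / config$plates_per_day)
      batch <- plate_eff[p] * day_eff[day_i]
      idx <- (p - 1L) * config$n_test + seq_len(config$n_test)
      cmp <- truth[idx, ]
      w <- data.frame(
        plate_id = sprintf("P%02d", p),
        well = occupied$well,
        role = occupied$role,
        compound_id = NA_character_,
        dose_um = 0,
        status = "ok",
        fluorescence = NA_real_,
        replicate = rep_i,
        day = sprintf("D%d", day_i),
        stringsAsFactors = FALSE
      )
      is_pos <- w$role == "positive_control"
      is_neg <- w$role == "negative_control"
      is_test <- w$role == "test"
      w$compound_id[is_pos] <- "riluzole"
      w$compound_id[is_neg] <- "vehicle"
      w$compound_id[is_test] <- cmp$compound_id[match(w$well[is_test],
                                                      test_wells)]
      w$dose_um[is_pos] <- 10
      w$dose_um[is_test] <- 10
      eff <- rep(1, nrow(w))
      eff[is_pos] <- config$positive_control_effect
      mcmp <- match(w$compound_id, truth$compound_id)
      planted_eff <- truth$effect_factor[mcmp]
      sel <- is_test & !is.na(planted_eff)
      eff[sel] <- planted_eff[sel]
      # toxic compounds: embryo dies with toxicity_prob, no reading
      toxic_cmp <- !is.na(mcmp) & truth$class[mcmp] == "toxic"
      dies <- toxic_cmp & stats::runif(nrow(w)) < config$toxicity_prob
      # background exclusions, independent of compound class
      bg <- !dies & stats::runif(nrow(w)) < config$exclusion_rate
      bg_kind <- sample(c("dead", "defective"), nrow(w), replace = TRUE)
      w$status[dies] <- "dead"
      w$status[bg] <- bg_kind[bg]
      ok <- w$status == "ok"
      w$fluorescence[ok] <- exp(stats::rnorm(sum(ok), mulog, sdlog)) *
        eff[ok] * batch
      rows[[ri <- ri + 1L]] <- w
    }
  }
  dataset <- screen_dataset(do.call(rbind, rows))
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "sim_screen")
}

# Draw the signed offset design for one plate's scored test wells.
# Returns fluorescence values for inert wells plus exact reference
# statistics: the constructed multiset has median(X) = m and
# median(|X - m|) = d (up to floating point), so every well's SSMD* score is
# fixed by construction. `planted_z` are the target scores of planted wells.
.planted_plate_values <- function(n, planted_z, m, d) {
  k <- length(planted_z)
  q <- n - k
  k_low <- sum(planted_z < 0)
  k_high <- k - k_low
  if (n %% 2L == 1L) {
    n_side <- (n - 1L) %/% 2L
    if (k > n_side - 1L) stop("too many planted wells on one plate")
    small <- stats::runif(n_side - 1L, 0.40, 0.95) * d
    mags <- c(0, small, d, stats::runif(n_side - k, 1.005, 1.020) * d)
    neg_n <- n_side - k_low
    pos_n <- n_side - k_high
    signs <- c(0, sample(rep(c(-1, 1), c(neg_n, pos_n))))
  } else {
    n_side <- n %/% 2L
    if (k > n_side - 1L || n < 6L) stop("too many planted wells on one plate")
    o0 <- 0.30 * d
    small <- stats::runif(n_side - 3L, 0.40, 0.95) * d
    mags <- c(o0, o0, small, d, d,
              stats::runif(n_side - 1L - k, 1.005, 1.020) * d)
    neg_n <- n_side - 1L - k_low
    pos_n <- n_side - 1L - k_high
    signs <- c(-1, 1, sample(rep(c(-1, 1), c(neg_n, pos_n))))
  }
  if (neg_n < 0L || pos_n < 0L) {
    stop("planted wells too one-sided for this plate")
  }
  inert <- m + signs * mags
  planted <- m + planted_z * (sqrt(2) * 1.4826) * d
  list(inert = sample(inert), planted = planted)
}

#' Simulate a screen with exact planted SSMD* outcomes
#'
#' Benchmark generator for validating the score -> classify -> concordance ->
#' summary chain end to end. Unlike [simulate_screen()], which draws i.i.d.
#' noise, this generator plants target SSMD* scores and constructs the well
#' readings by inverting the score map: each plate's scored test wells are
#' laid out so that their median and scaled MAD are fixed by construction,
#' inert wells sit strictly inside (-0.5, 0.5), moderate inhibitors inside
#' (-1, -0.5), strong inhibitors below -1 and activators above +1 — in every
#' replicate, for every seed. The realized classification therefore equals
#' the planted one exactly, which an i.i.d. noise model cannot achieve: a
#' well scored against its own plate's reference population has score
#' standard deviation of about `1/sqrt(2)` however small the noise, so inert
#' wells would routinely cross -0.5 and banded effects could not replicate.
#' Plate and day effects are still drawn randomly; SSMD* is invariant to
#' them, so they exercise the plate-wise normalization without disturbing
#' the planted outcome.
#'
#' @param n_compounds test compounds in the screen (default 2000).
#' @param n_inhibitors compounds planted concordantly below -0.5 (default
#'   38); `n_strong_inhibitors` of these (default 7) are planted below -1.0.
#' @param n_strong_inhibitors see above.
#' @param n_activators compounds planted concordantly above +1.0 (default
#'   20).
#' @param n_toxic compounds planted toxic — embryos die in every replicate
#'   (default 142).
#' @param replicates screen replicates (default 2).
#' @param baseline,rel_scale plate signal level and the ratio of the
#'   constructed robust scale to it (defaults 1000 and 0.10).
#' @param plate_effect_sd,day_effect_sd,plates_per_day multiplicative batch
#'   structure, as in [simulation_config()].
#' @param seed integer seed.
#' @return a `sim_screen` (see [simulate_screen()]); `truth$class` holds the
#'   planted classes with `inactive` for the inert remainder.
#' @export
simulate_planted_screen <- function(n_compounds = 2000L,
                                    n_inhibitors = 38L,
                                    n_strong_inhibitors = 7L,
                                    n_activators = 20L,
                                    n_toxic = 142L,
                                    replicates = 2L,
                                    baseline = 1000,
                                    rel_scale = 0.10,
                                    plate_effect_sd = 0.05,
                                    day_effect_sd = 0.10,
                                    plates_per_day = 5L,
                                    seed = NULL) {
  stopifnot(n_strong_inhibitors <= n_inhibitors,
            n_inhibitors + n_activators + n_toxic <= n_compounds,
            rel_scale > 0, baseline > 0)
  if (!is.null(seed)) set.seed(seed)
  n_moderate <- n_inhibitors - n_strong_inhibitors
  cls <- rep("inactive", n_compounds)
  planted <- sample.int(n_compounds,
                        n_moderate + n_strong_inhibitors + n_activators +
                          n_toxic)
  cls[planted] <- rep(c("inhibitor", "strong_inhibitor", "activator",
                        "toxic"),
                      c(n_moderate, n_strong_inhibitors, n_activators,
                        n_toxic))
  eff <- rep(1, n_compounds)
  eff[cls == "inhibitor"] <- 1 + (-0.75) * sqrt(2) * 1.4826 * rel_scale
  eff[cls == "strong_inhibitor"] <- 1 + (-1.85) * sqrt(2) * 1.4826 * rel_scale
  eff[cls == "activator"] <- 1 + 1.85 * sqrt(2) * 1.4826 * rel_scale
  eff[cls == "toxic"] <- NA_real_
  truth <- data.frame(compound_id = sprintf("C%04d", seq_len(n_compounds)),
                      class = cls, effect_factor = eff,
                      stringsAsFactors = FALSE)

  n_test <- 48L
  n_plates <- ceiling(n_compounds / n_test)
  layout <- plate_layout_96(n_test, 12L, 12L)
  occupied <- layout[layout$role != "empty", ]
  test_wells <- occupied$well[occupied$role == "test"]
  z_band <- function(class) switch(class,
    inhibitor = stats::runif(1, -0.90, -0.60),
    strong_inhibitor = stats::runif(1, -2.20, -1.50),
    activator = stats::runif(1, 1.50, 2.20))

  rows <- vector("list", replicates * n_plates)
  ri <- 0L
  for (rep_i in seq_len(replicates)) {
    n_days <- ceiling(n_plates / plates_per_day)
    day_eff <- exp(stats::rnorm(n_days, 0, day_effect_sd))
    plate_eff <- exp(stats::rnorm(n_plates, 0, plate_effect_sd))
    for (p in seq_len(n_plates)) {
      day_i <- ceiling(p / plates_per_day)
      m <- baseline * plate_eff[p] * day_eff[day_i]
      d <- rel_scale * m
      idx <- ((p - 1L) * n_test + 1L):min(p * n_test, n_compounds)
      cmp <- truth[idx, ]
      wells_here <- test_wells[seq_along(idx)]
      toxic_here <- cmp$class == "toxic"
      scored <- !toxic_here
      planted_here <- scored & cmp$class != "inactive"
      z <- vapply(cmp$class[planted_here], z_band, numeric(1))
      vals <- .planted_plate_values(sum(scored) , z, m, d)
      fl <- rep(NA_real_, length(idx))
      fl[scored & !planted_here] <- vals$inert
      fl[planted_here] <- vals$planted
      pos_w <- occupied$well[occupied$role == "positive_control"]
      neg_w <- occupied$well[occupied$role == "negative_control"]
      w <- data.frame(
        plate_id = sprintf("P%02d", p),
        well = c(pos_w, neg_w, wells_here),
        role = c(rep("positive_control", length(pos_w)),
                 rep("negative_control", length(neg_w)),
                 rep("test", length(idx))),
        compound_id = c(rep("riluzole", length(pos_w)),
                        rep("vehicle", length(neg_w)), cmp$compound_id),
        dose_um = c(rep(10, length(pos_w)), rep(0, length(neg_w)),
                    rep(10, length(idx))),
        status = c(rep("ok", length(pos_w) + length(neg_w)),
                   ifelse(toxic_here, "dead", "ok")),
        fluorescence = c(
          0.5 * m * exp(stats::runif(length(pos_w), -0.05, 0.05)),
          m * exp(stats::runif(length(neg_w), -0.05, 0.05)),
          fl),
        replicate = rep_i,
        day = sprintf("D%d", day_i),
        stringsAsFactors = FALSE
      )
      rows[[ri <- ri + 1L]] <- w
    }
  }
  dataset <- screen_dataset(do.call(rbind, rows))
  cfg <- list(n_compounds = n_compounds, n_inhibitors = n_inhibitors,
              n_strong_inhibitors = n_strong_inhibitors,
              n_activators = n_activators, n_toxic = n_toxic,
              replicates = replicates, baseline = baseline,
              rel_scale = rel_scale, plate_effect_sd = plate_effect_sd,
              day_effect_sd = day_effect_sd, seed = seed,
              generator = "planted_scores")
  structure(list(dataset = dataset, truth = truth, config = cfg),
            class = "sim_screen")
}

#' Simulate treated and vehicle control groups
#'
#' The validation-experiment design: two groups of embryos (one per well),
#' log-normal fluorescence with a given coefficient of variation, and a
#' multiplicative treatment effect. Used to check that
#' [percent_reduction()] recovers a planted effect (e.g. a riluzole-like
#' 50 percent reduction with n = 19 per group).
#'
#' @param n embryos per group (default 19).
#' @param effect multiplicative treatment effect (default 0.5).
#' @param cv coefficient of variation of the well noise (default 0.15).
#' @param baseline vehicle signal level.
#' @param seed integer seed.
#' @return list with numeric vectors `treated` and `control`.
#' @export
simulate_control_groups <- function(n = 19L, effect = 0.5, cv = 0.15,
                                    baseline = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- .sdlog_for_cv(cv)
  mulog <- log(baseline)
  list(treated = effect * exp(stats::rnorm(n, mulog, sdlog)),
       control = exp(stats::rnorm(n, mulog, sdlog)))
}

#' Simulate a dose-response series
#'
#' Emulates the dose-response validation design: one embryo per well, a
#' vehicle group and a log-spaced dose grid, with the planted percent
#' reduction interpolated log-linearly from 0 at the lowest positive dose to
#' the top-dose effect.
#'
#' @param top_effect fractional reduction at the top dose (default 0.5).
#' @param doses dose grid in uM including 0 (default c(0, 1, 3, 10, 30)).
#' @param n_per_dose embryos per dose (default 12).
#' @param cv well noise coefficient of variation (default 0.15).
#' @param baseline vehicle signal level.
#' @param seed integer seed.
#' @param compound_id label for the series.
#' @return a [dose_series()]; the planted per-dose effect factors are
#'   attached as attribute `"planted"`.
#' @export
simulate_dose_response <- function(top_effect = 0.5,
                                   doses = c(0, 1, 3, 10, 30),
                                   n_per_dose = 12L, cv = 0.15,
                                   baseline = 1000, seed = NULL,
                                   compound_id = "simulated") {
  stopifnot(any(doses == 0), any(doses > 0), top_effect < 1)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- .sdlog_for_cv(cv)
  pos <- sort(unique(doses[doses > 0]))
  red <- function(d) {
    if (d == 0) return(0)
    if (length(pos) == 1L) return(top_effect)
    top_effect * (log(d) - log(min(pos))) / (log(max(pos)) - log(min(pos)))
  }
  planted <- data.frame(dose_um = sort(unique(doses)),
                        effect_factor = 1 - vapply(sort(unique(doses)), red,
                                                   numeric(1)))
  dose_vec <- rep(doses, each = n_per_dose)
  fl <- vapply(dose_vec, function(d) {
    (1 - red(d)) * exp(stats::rnorm(1, log(baseline), sdlog))
  }, numeric(1))
  out <- dose_series(dose_vec, fl, compound_id = compound_id)
  attr(out, "planted") <- planted
  out
}

#' Pipeline recovery against planted truth
#'
#' Confronts final hit calls with the generator's planted classes: confusion
#' matrix plus per-class precision and recall of the full
#' score -> classify -> concordance pipeline.
#'
#' @param calls a `hit_calls` object over the simulated compounds.
#' @param truth the `truth` data.frame of a `sim_screen`.
#' @return an object of class `recovery_report`: list with `confusion`
#'   (truth class x final call table) and `per_class` (data.frame `class`,
#'   `n_true`, `n_called`, `recall`, `precision`).
#' @export
recovery_report <- function(calls, truth) {
  stopifnot(inherits(calls, "hit_calls"))
  if (!setequal(calls$compound_id, truth$compound_id)) {
    stop("calls and truth cover different compound sets", call. = FALSE)
  }
  m <- match(calls$compound_id, truth$compound_id)
  tc <- truth$class[m]
  fc <- calls$final_call
  confusion <- table(truth = tc, called = fc)
  classes <- sort(unique(c(tc, fc)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    n_true <- sum(tc == cl)
    n_called <- sum(fc == cl)
    hits <- sum(tc == cl & fc == cl)
    data.frame(class = cl, n_true = n_true, n_called = n_called,
               recall = if (n_true) hits / n_true else NA_real_,
               precision = if (n_called) hits / n_called else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(confusion = confusion, per_class = per_class),
            class = "recovery_report")
}
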