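test_that("plate sensitivity/specificity follow the contingency formulas", {
  # build a plate whose control scores realize chosen TP/FN/TN/FP counts
  make_qc_plate <- function(tp, fn, tn, fp, threshold = -0.5) {
    scores <- data.frame(
      plate_id = "P1", replicate = 1L,
      well = format_well("A", 1),  # overwritten below
      role = c(rep("positive_control", tp + fn),
               rep("negative_control", tn + fp)),
      ssmd_star = c(rep(threshold - 1, tp), rep(threshold + 0.2, fn),
                    rep(threshold + 0.2, tn), rep(threshold - 1, fp)),
      stringsAsFactors = FALSE)
    scores$well <- paste0(rep(LETTERS[1:8], each = 12),
                          1:12)[seq_len(nrow(scores))]
    scores
  }
  q <- plate_sensitivity_specificity(make_qc_plate(11, 1, 10, 2))
  expect_equal(c(q$tp, q$fn, q$tn, q$fp), c(11, 1, 10, 2))
  expect_equal(q$sensitivity, 100 * 11 / 12)
  expect_equal(q$specificity, 100 * 10 / 12)

  # all positive controls active
  q2 <- plate_sensitivity_specificity(make_qc_plate(12, 0, 12, 0))
  expect_equal(q2$sensitivity, 100)
  expect_equal(q2$specificity, 100)

  # property: formulas match independent integer arithmetic on random counts
  set.seed(71)
  for (i in 1:50) {
    n <- sample(1:12, 4, replace = TRUE)
    q <- plate_sensitivity_specificity(make_qc_plate(n[1], n[2], n[3], n[4]))
    expect_equal(q$sensitivity, 100 * n[1] / (n[1] + n[2]))
    expect_equal(q$specificity, 100 * n[3] / (n[3] + n[4]))
  }

  # a negative control exactly at the threshold is a true negative
  at <- data.frame(plate_id = "P1", replicate = 1L, well = c("A1", "B1"),
                   role = c("positive_control", "negative_control"),
                   ssmd_star = c(-2, -0.5), stringsAsFactors = FALSE)
  qa <- plate_sensitivity_specificity(at, threshold = -0.5)
  expect_equal(qa$tn, 1)
  expect_equal(qa$fp, 0)
})

test_that("screen QC trades sensitivity for specificity as the cutoff tightens", {
  sim <- simulate_screen(simulation_config(n_plates = 8L, seed = 55L))
  scr <- score_screen(sim$dataset)
  qc <- screen_qc(scr, thresholds = c(-0.5, -1.0))
  s <- qc$summary
  for (r in unique(s$replicate)) {
    loose <- s[s$replicate == r & s$threshold == -0.5, ]
    tight <- s[s$replicate == r & s$threshold == -1.0, ]
    expect_lte(tight$sensitivity_mean, loose$sensitivity_mean)
    expect_gte(tight$specificity_mean, loose$specificity_mean)
  }
  # per-plate monotonicity, not just on average
  pp <- qc$per_plate
  key <- paste(pp$plate_id, pp$replicate)
  for (k in unique(key)) {
    a <- pp[key == k & pp$threshold == -0.5, ]
    b <- pp[key == k & pp$threshold == -1.0, ]
    expect_lte(b$sensitivity, a$sensitivity)
    expect_gte(b$specificity, a$specificity)
  }
})

test_that("screen QC approaches perfection when effect dwarfs noise", {
  # the separation-by-construction screen: controls sit far inside their
  # classification regions, so both metrics reach 100 %
  sim <- simulate_planted_screen(n_compounds = 288L, n_inhibitors = 6L,
                                 n_strong_inhibitors = 2L, n_activators = 3L,
                                 n_toxic = 10L, seed = 77L)
  qc <- screen_qc(score_screen(sim$dataset), thresholds = -0.5)
  expect_equal(min(qc$summary$sensitivity_mean), 100)
  expect_equal(min(qc$summary$specificity_mean), 100)

  # under i.i.d. well noise sensitivity still saturates, but specificity is
  # capped: a negative control scored against the test-well reference keeps
  # score spread ~1/sqrt(2) however small the CV is
  stoch <- simulate_screen(simulation_config(n_plates = 6L, cv = 0.05,
                                             positive_control_effect = 0.4,
                                             seed = 77L))
  qs <- screen_qc(score_screen(stoch$dataset), thresholds = -0.5)
  expect_gte(min(qs$summary$sensitivity_mean), 99)
  expect_gt(min(qs$summary$specificity_mean), 60)
})

test_that("a single QC'd plate reports SD 0 and missing controls flag", {
  plate <- make_plate(test_values = c(100, 110, 120, 130, 140),
                      pos_values = c(40, 45, 50),
                      neg_values = c(115, 120, 125))
  scr <- score_screen(plate, analysis_config(min_reference = 4))
  qc <- screen_qc(scr, thresholds = -0.5)
  expect_equal(qc$summary$sensitivity_sd, 0)
  expect_equal(qc$summary$specificity_sd, 0)

  bare <- make_plate(test_values = c(100, 110, 120, 130, 140))
  qb <- screen_qc(score_screen(bare, analysis_config(min_reference = 4)),
                  thresholds = -0.5)
  expect_true(all(qb$per_plate$flagged))
  expect_null(qb$summary)
})

test_that("control variability reports within- and between-plate CVs", {
  two_plates <- function(m1, m2) {
    a <- make_plate(test_values = seq(90, 135, by = 5),
                    pos_values = rep(50, 3) + c(0, 1, -1),
                    neg_values = m1 + c(-5, 0, 5), plate_id = "P1")
    b <- make_plate(test_values = seq(90, 135, by = 5),
                    pos_values = rep(50, 3) + c(0, 1, -1),
                    neg_values = m2 + c(-5, 0, 5), plate_id = "P2")
    screen_dataset(rbind(as.data.frame(a), as.data.frame(b)))
  }
  cvr <- control_variability(two_plates(100, 110))
  neg <- cvr$between_plate[cvr$between_plate$role == "negative_control", ]
  # frozen: CV of plate means {100, 110} with sample SD = 6.7344 %
  expect_equal(neg$cv_of_plate_means, 100 * sd(c(100, 110)) / 105,
               tolerance = 1e-12)
  expect_equal(neg$cv_of_plate_means, 6.7343503, tolerance = 1e-6)

  # equal plate means -> between-plate CV 0
  fn <- control_variability(two_plates(100, 100))$between_plate
  expect_equal(fn$cv_of_plate_means[fn$role == "negative_control"], 0)

  # identical control readings everywhere -> all CVs 0
  mk_flat <- function(id) make_plate(test_values = seq(90, 135, by = 5),
                                     pos_values = rep(50, 3),
                                     neg_values = rep(100, 3), plate_id = id)
  flat <- control_variability(screen_dataset(
    rbind(as.data.frame(mk_flat("P1")), as.data.frame(mk_flat("P2")))))
  expect_true(all(flat$within_plate$cv == 0))
  expect_true(all(flat$between_plate$cv_of_plate_means == 0))

  # a planted day effect inflates the between-plate CV
  base_cfg <- function(dsd, seed) simulation_config(
    n_plates = 8L, replicates = 1L, day_effect_sd = dsd,
    plates_per_day = 2L, plate_effect_sd = 0, seed = seed)
  cv_at <- function(dsd) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_screen(base_cfg(dsd, seed = s))
      cv <- control_variability(sim$dataset)
      mean(cv$between_plate$cv_of_plate_means)
    }, numeric(1)))
  }
  expect_gt(cv_at(0.25), cv_at(0.01))
})

test_that("plate pass/fail is advisory and names its reasons", {
  plate <- make_plate(test_values = c(100, 110, 120, 130, 140),
                      pos_values = c(40, 45, 50),
                      neg_values = c(115, 120, 125))
  scr <- score_screen(plate, analysis_config(min_reference = 4))
  q <- plate_sensitivity_specificity(scr$scores)
  healthy <- plate_pass_fail(q)
  expect_true(healthy$pass)
  expect_length(healthy$reasons, 0L)

  # positive controls indistinguishable from the plate -> fail
  lazy <- make_plate(test_values = c(100, 110, 120, 130, 140),
                     pos_values = c(115, 120, 125),
                     neg_values = c(115, 120, 125))
  ql <- plate_sensitivity_specificity(
    score_screen(lazy, analysis_config(min_reference = 4))$scores)
  verdict <- plate_pass_fail(ql)
  expect_false(verdict$pass)
  expect_match(verdict$reasons, "no activity")

  # degenerate reference propagates as a failure reason
  v2 <- plate_pass_fail(NULL, scoring_failure = "degenerate reference")
  expect_false(v2$pass)
  expect_match(v2$reasons, "degenerate")
})
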