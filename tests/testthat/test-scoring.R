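cfg_small <- analysis_config(min_reference = 4)

test_that("ssmd_star matches step-by-step robust arithmetic", {
  plate <- make_plate(test_values = c(10, 12, 14, 16, 18))
  ps <- ssmd_star(plate, cfg_small)
  # median 14, MAD 2, scale 1.4826 * 2 = 2.9652
  expect_equal(ps$reference$location, 14)
  expect_equal(ps$reference$scale, 2.9652)
  sc <- ps$scores
  # the reference-median well scores exactly 0
  expect_equal(sc$ssmd_star[sc$fluorescence == 14], 0)
  # frozen value from independent recomputation: (8-14)/(sqrt(2)*2.9652)
  expect_equal(oracle_ssmd_star(8, c(10, 12, 14, 16, 18)), -1.4308110,
               tolerance = 1e-7)
  expect_equal((8 - ps$reference$location) /
                 (sqrt(2) * ps$reference$scale), -1.4308110,
               tolerance = 1e-7)
  # monotone in the reading: below median negative, above positive
  expect_true(all(diff(sc$ssmd_star[order(sc$fluorescence)]) > 0))
  expect_lt(sc$ssmd_star[sc$fluorescence == 10], 0)
  expect_gt(sc$ssmd_star[sc$fluorescence == 18], 0)
})

test_that("ssmd_star is invariant under affine transforms of the plate", {
  set.seed(101)
  vals <- rlnorm(20, log(1000), 0.15)
  plate <- make_plate(test_values = vals, pos_values = 0.5 * vals[1:4],
                      neg_values = vals[5:8])
  base <- ssmd_star(plate, cfg_small)$scores$ssmd_star
  for (ab in list(c(3, 0), c(2.5, 40), c(0.1, 7))) {
    p2 <- as.data.frame(plate)
    p2$fluorescence <- ab[1] * p2$fluorescence + ab[2]
    tr <- ssmd_star(screen_dataset(p2), cfg_small)$scores$ssmd_star
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("ssmd_star agrees with a brute-force oracle on many small plates", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5:10, 1)
    vals <- round(rlnorm(n, log(100), 0.3), 6)
    plate <- make_plate(test_values = vals)
    got <- ssmd_star(plate, analysis_config(min_reference = 4))
    sc <- got$scores
    want <- oracle_ssmd_star(sc$fluorescence, vals)
    expect_equal(sc$ssmd_star, want, tolerance = 1e-12)
  }
})

test_that("ssmd_star reference policies and error paths behave", {
  # controls are scored against the test-well reference, not their own group
  plate <- make_plate(test_values = c(10, 12, 14, 16, 18),
                      pos_values = c(6, 7), neg_values = c(30, 31))
  ps <- ssmd_star(plate, cfg_small)
  pos <- ps$scores[ps$scores$role == "positive_control", ]
  expect_equal(pos$ssmd_star, (c(6, 7) - 14) / (sqrt(2) * 2.9652),
               tolerance = 1e-12)
  # negative controls join the reference only under test_plus_negative
  cfg_tpn <- analysis_config(min_reference = 4,
                             reference_policy = "test_plus_negative")
  ps2 <- ssmd_star(plate, cfg_tpn)
  expect_equal(ps2$reference$n_reference, 7L)
  expect_false(isTRUE(all.equal(ps2$reference$location,
                                ps$reference$location)))

  # leave-one-out excludes the scored well from its own reference
  cfg_loo <- analysis_config(min_reference = 4, reference_policy = "test_loo")
  ps3 <- ssmd_star(plate, cfg_loo)
  sc3 <- ps3$scores[ps3$scores$role == "test", ]
  for (i in seq_len(nrow(sc3))) {
    others <- setdiff(c(10, 12, 14, 16, 18), sc3$fluorescence[i])
    expect_equal(sc3$ssmd_star[i],
                 oracle_ssmd_star(sc3$fluorescence[i], others),
                 tolerance = 1e-12)
  }

  # degenerate reference and too-few wells are scoring errors
  flat <- make_plate(test_values = rep(100, 10))
  expect_error(ssmd_star(flat, cfg_small), "degenerate")
  tiny <- make_plate(test_values = c(1, 2, 3))
  expect_error(ssmd_star(tiny, cfg_small), "reference wells")
})

test_that("score_screen flags unscorable plates instead of dying on request", {
  good <- make_plate(test_values = c(10, 12, 14, 16, 18), plate_id = "P1")
  flat <- make_plate(test_values = rep(100, 10), plate_id = "P2")
  ds <- screen_dataset(rbind(as.data.frame(good), as.data.frame(flat)))
  expect_error(score_screen(ds, cfg_small), "degenerate")
  scr <- score_screen(ds, cfg_small, on_error = "flag")
  expect_equal(nrow(scr$failed), 1L)
  expect_equal(scr$failed$plate_id, "P2")
  expect_true(all(scr$scores$plate_id == "P1"))
})

test_that("ssmd_controls enumerates pairwise differences", {
  # frozen from brute-force enumeration: diffs {-6,-8,-4,-6}, median -6,
  # sample SD 1.63299
  expect_equal(ssmd_controls(c(4, 6), c(10, 12)), -3.6742346,
               tolerance = 1e-7)
  expect_equal(ssmd_controls(c(4, 6), c(10, 12)),
               oracle_ssmd_controls(c(4, 6), c(10, 12)), tolerance = 1e-12)
  set.seed(303)
  for (i in 1:25) {
    pos <- rlnorm(sample(2:6, 1), log(50), 0.4)
    neg <- rlnorm(sample(2:6, 1), log(100), 0.4)
    expect_equal(ssmd_controls(pos, neg), oracle_ssmd_controls(pos, neg),
                 tolerance = 1e-12)
  }
  # identical multisets give SSMD 0; constant groups are degenerate
  expect_equal(ssmd_controls(c(5, 9, 7), c(9, 7, 5)), 0)
  expect_error(ssmd_controls(c(5, 5), c(5, 5)), "degenerate")
  # inhibitory positives (lower signal) score negative
  expect_lt(ssmd_controls(c(40, 45, 50), c(95, 100, 105)), 0)
})

test_that("percent_reduction is the relative mean difference in percent", {
  expect_equal(percent_reduction(c(50, 50), c(100, 100)), 50)
  expect_equal(percent_reduction(c(80, 120), c(80, 120)), 0)
  expect_equal(percent_reduction(c(150, 150), c(100, 100)), -50)
  expect_equal(percent_reduction(c(10, 90), c(100, 100), use_median = TRUE),
               50)
  expect_error(percent_reduction(c(1, 2), c(0, 0)), "positive")
  # recovers a planted 50 % effect within sampling error at the
  # validation-experiment design (n = 19, CV 15 %)
  reds <- vapply(1:40, function(s) {
    g <- simulate_control_groups(n = 19, effect = 0.5, cv = 0.15, seed = s)
    percent_reduction(g$treated, g$control)
  }, numeric(1))
  expect_lt(abs(mean(reds) - 50), 3)
})

test_that("comparison metrics follow their textbook formulas", {
  pos <- c(38, 40, 42); neg <- c(97, 100, 103)
  m <- comparison_metrics(pos, neg)
  expect_equal(m$signal_to_background, mean(pos) / mean(neg))
  expect_equal(m$signal_to_noise, (mean(pos) - mean(neg)) / sd(neg))
  expect_equal(m$z_prime, 1 - 3 * (sd(pos) + sd(neg)) /
                 abs(mean(pos) - mean(neg)))
  # frozen arithmetic: sd_pos 2, sd_neg 3, means 40/100 -> Z' = 0.75
  p2 <- c(38, 42); n2 <- c(97, 103)
  expect_equal(comparison_metrics(p2, n2)$z_prime,
               1 - 3 * (sd(p2) + sd(n2)) / 60)
  # degenerate groups flag metrics as undefined instead of erroring
  d <- comparison_metrics(c(10, 10), c(10, 10))
  expect_equal(d$signal_to_background, 1)
  expect_true(all(c("signal_to_noise", "z_prime") %in% d$undefined))
  # Z' is invariant under common rescaling
  m1 <- comparison_metrics(pos, neg)$z_prime
  m2 <- comparison_metrics(7 * pos, 7 * neg)$z_prime
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("non-ok readings can never leak into scores", {
  # poison the non-ok wells with a sentinel (bypassing the constructor) and
  # check the scores are unchanged
  set.seed(404)
  statuses <- c(rep("ok", 20), "dead", "defective", "excluded")
  plate <- make_plate(test_values = c(rlnorm(20, log(1000), 0.2), 1, 2, 3),
                      statuses = statuses)
  base <- ssmd_star(plate, cfg_small)
  poisoned <- as.data.frame(plate)
  poisoned$fluorescence[poisoned$status != "ok"] <- 1e9
  ps <- ssmd_star(poisoned, cfg_small)
  expect_equal(ps$scores$ssmd_star[!is.na(ps$scores$ssmd_star)],
               base$scores$ssmd_star[!is.na(base$scores$ssmd_star)])
  expect_true(all(is.na(ps$scores$ssmd_star[ps$scores$status != "ok"])))
})

test_that("scores round-trip through the CSV exporter", {
  sim <- simulate_screen(simulation_config(n_plates = 2L, seed = 5L))
  scr <- score_screen(sim$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(scr, path)
  back <- read_scores(path)
  expect_equal(back$scores$ssmd_star, scr$scores$ssmd_star,
               tolerance = 1e-12)
  expect_equal(back$scores$compound_id, scr$scores$compound_id)
})
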