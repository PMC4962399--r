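test_that("simulated screens are valid, deterministic and well-formed", {
  cfg <- simulation_config(n_plates = 3L, seed = 17L)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(as.data.frame(a$dataset), as.data.frame(b$dataset))
  expect_identical(a$truth, b$truth)

  v <- validate_screen(a$dataset)
  expect_length(v$errors, 0L)
  expect_length(v$warnings, 0L)
  expect_equal(nrow(a$truth), 3L * 48L)
  # layout: 12 + 12 + 48 occupied wells per plate-replicate
  one <- a$dataset[a$dataset$plate_id == "P01" & a$dataset$replicate == 1L, ]
  expect_equal(sum(one$role == "positive_control"), 12L)
  expect_equal(sum(one$role == "negative_control"), 12L)
  expect_equal(sum(one$role == "test"), 48L)
})

test_that("an all-inert screen is quiet and specific", {
  cfg <- simulation_config(n_plates = 4L, frac_inhibitor = 0,
                           frac_strong_inhibitor = 0, frac_activator = 0,
                           frac_toxic = 0, exclusion_rate = 0,
                           plate_effect_sd = 0, day_effect_sd = 0,
                           seed = 23L)
  sim <- simulate_screen(cfg)
  scr <- score_screen(sim$dataset)
  test_scores <- scr$scores$ssmd_star[scr$scores$role == "test"]
  # scores centre on 0 by construction of the plate-wise reference
  expect_lt(abs(median(test_scores)), 0.1)
  # false-hit rate of inert wells at +/-0.5 is far from catastrophic but
  # nonzero: the reference population itself has score spread ~1/sqrt(2)
  fp <- mean(test_scores < -0.5)
  expect_gt(fp, 0.05)
  expect_lt(fp, 0.5)
  # concordance squashes the inert false-hit rate roughly quadratically
  hits <- concordant_hits(classify_screen(scr))
  fp_final <- mean(hits$final_call %in% c("inhibitor", "strong_inhibitor"))
  expect_lt(fp_final, 2.5 * fp^2 + 0.05)
})

test_that("planted positive controls behave like the reference compound", {
  sim <- simulate_screen(simulation_config(n_plates = 5L, seed = 29L))
  ds <- sim$dataset
  pooled_pos <- ds$fluorescence[ds$role == "positive_control" &
                                  !is.na(ds$fluorescence)]
  pooled_neg <- ds$fluorescence[ds$role == "negative_control" &
                                  !is.na(ds$fluorescence)]
  # day/plate effects cancel on average; ~50 % reduction recovered
  expect_lt(abs(percent_reduction(pooled_pos, pooled_neg) - 50), 8)

  # positive controls are called active in the overwhelming majority of wells
  scr <- score_screen(ds)
  pos_scores <- scr$scores$ssmd_star[scr$scores$role == "positive_control" &
                                       !is.na(scr$scores$ssmd_star)]
  expect_gt(mean(pos_scores < -0.5), 0.95)
})

test_that("toxic and excluded wells carry status, not readings", {
  cfg <- simulation_config(n_plates = 4L, frac_toxic = 0.10,
                           exclusion_rate = 0.05, seed = 41L)
  sim <- simulate_screen(cfg)
  ds <- sim$dataset
  toxic_cmp <- sim$truth$compound_id[sim$truth$class == "toxic"]
  toxic_wells <- ds[ds$compound_id %in% toxic_cmp & ds$role == "test", ]
  expect_true(all(toxic_wells$status == "dead"))
  expect_true(all(is.na(toxic_wells$fluorescence)))
  # background exclusions hit non-toxic wells too
  bg <- ds[!ds$compound_id %in% toxic_cmp & !is.na(ds$status) &
             ds$status != "ok", ]
  expect_gt(nrow(bg), 0L)
})

test_that("pipeline recall rises with planted effect size", {
  recall_at <- function(effect, seeds = 1:20) {
    mean(vapply(seeds, function(s) {
      truth <- data.frame(
        compound_id = sprintf("C%04d", 1:96),
        class = rep(c("inhibitor", "inactive"), c(6, 90)),
        effect_factor = rep(c(effect, 1), c(6, 90)),
        stringsAsFactors = FALSE)
      cfg <- simulation_config(n_plates = 2L, planted_truth = truth,
                               frac_toxic = 0, exclusion_rate = 0,
                               seed = s)
      sim <- simulate_screen(cfg)
      hits <- concordant_hits(classify_screen(score_screen(sim$dataset)))
      called <- hits$final_call[match(sprintf("C%04d", 1:6),
                                      hits$compound_id)]
      mean(called %in% c("inhibitor", "strong_inhibitor"))
    }, numeric(1)))
  }
  r_weak <- recall_at(0.9)
  r_mid <- recall_at(0.6)
  r_strong <- recall_at(0.3)
  expect_lte(r_weak, r_mid + 0.05)
  expect_lte(r_mid, r_strong + 0.05)
  expect_gt(r_strong, 0.9)
  expect_lt(r_weak, 0.5)
})

test_that("recovery_report demands matching compound sets and counts truly", {
  sim <- simulate_planted_screen(n_compounds = 240L, n_inhibitors = 6L,
                                 n_strong_inhibitors = 2L, n_activators = 4L,
                                 n_toxic = 10L, seed = 3L)
  hits <- concordant_hits(classify_screen(score_screen(sim$dataset)))
  rec <- recovery_report(hits, sim$truth)
  pc <- rec$per_class
  expect_equal(pc$recall[pc$class == "inhibitor"], 1)
  expect_equal(pc$recall[pc$class == "strong_inhibitor"], 1)
  expect_equal(pc$recall[pc$class == "activator"], 1)
  expect_equal(pc$recall[pc$class == "toxic"], 1)
  expect_error(recovery_report(hits, sim$truth[-1, ]), "different compound")
})

test_that("the planted-score generator realizes its classes exactly", {
  for (s in c(2L, 77L, 1234L)) {
    sim <- simulate_planted_screen(n_compounds = 480L, n_inhibitors = 12L,
                                   n_strong_inhibitors = 4L,
                                   n_activators = 6L, n_toxic = 30L,
                                   seed = s)
    scr <- score_screen(sim$dataset)
    calls <- classify_screen(scr)
    m <- match(calls$compound_id, sim$truth$compound_id)
    planted <- sim$truth$class[m]
    realized <- calls$class
    expect_identical(realized[planted == "toxic"],
                     rep("toxic", sum(planted == "toxic")))
    expect_identical(realized[planted != "toxic"],
                     ifelse(planted[planted != "toxic"] == "inactive",
                            "inactive", planted[planted != "toxic"]))
  }
  # determinism
  a <- simulate_planted_screen(n_compounds = 96L, n_toxic = 5L,
                               n_inhibitors = 3L, n_strong_inhibitors = 1L,
                               n_activators = 2L, seed = 8L)
  b <- simulate_planted_screen(n_compounds = 96L, n_toxic = 5L,
                               n_inhibitors = 3L, n_strong_inhibitors = 1L,
                               n_activators = 2L, seed = 8L)
  expect_identical(as.data.frame(a$dataset), as.data.frame(b$dataset))
})

test_that("control-group simulation hits its planted effect and CV", {
  g <- simulate_control_groups(n = 5000, effect = 0.5, cv = 0.15, seed = 1)
  expect_lt(abs(mean(g$treated) / mean(g$control) - 0.5), 0.01)
  expect_lt(abs(sd(g$control) / mean(g$control) - 0.15), 0.01)
})
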