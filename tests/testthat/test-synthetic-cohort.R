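test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(subtype_fractions = c(0.5, 0.4)), "sum to 1")
  expect_error(synthetic_config(thresholds = c(2, 1)), "ascending")
  expect_error(synthetic_config(stage_rate = -1), "stage_rate")
  es <- build_event_set(paste0("r", 1:2), 1)
  expect_error(synthetic_config(roi_names = paste0("r", 1:2), thresholds = 1,
                                subtype_fractions = 1,
                                truth_sequences = list(c(1L, 1L))),
               "permutation")
})

test_that("truth generation is deterministic and follows the configured design", {
  cfg <- synthetic_config(seed = 5)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  base <- t1[t1$group == "patient" & t1$visit_index == 1, ]
  expect_equal(nrow(base), 270)
  expect_equal(sum(t1$group == "control"), 121)
  # follow-up schedule: 137 of 270 subjects have a second visit
  fu_subjects <- unique(t1$subject_id[t1$visit_index > 1])
  expect_equal(length(fu_subjects), 137)
  # stages never regress within subject
  for (id in sample(fu_subjects, 20)) {
    rows <- t1[t1$subject_id == id, ]
    expect_false(is.unsorted(rows$true_stage))
  }
})

test_that("degenerate fractions put all subjects in one subtype", {
  cfg <- synthetic_config(n_patients = 50, subtype_fractions = c(1, 0, 0, 0),
                          seed = 2)
  tr <- generate_truth(cfg)
  expect_true(all(tr$true_subtype[tr$group == "patient"] == 1))
})

test_that("empirical subtype proportions obey the multinomial law", {
  fr <- c(82, 71, 59, 52) / 264
  cfg <- synthetic_config(n_patients = 10000, n_controls = 10, seed = 33)
  tr <- generate_truth(cfg)
  base <- tr[tr$group == "patient" & tr$visit_index == 1, ]
  phat <- as.numeric(table(factor(base$true_subtype, levels = 1:4))) / 10000
  se <- sqrt(fr * (1 - fr) / 10000)
  expect_true(all(abs(phat - fr) <= 3 * se))
})

test_that("noise-free volumes invert exactly through the planted covariate model", {
  # stage 0: every biomarker at w = 0
  cfg0 <- synthetic_config(
    n_patients = 5, n_controls = 10, roi_names = paste0("r", 1:3),
    thresholds = c(1, 2, 3), subtype_fractions = 1,
    truth_sequences = list(1:9), noise_sd = 0,
    stage_distribution = c(1, rep(0, 9)), seed = 3)
  sim0 <- simulate_cohort(cfg0)
  W0 <- planted_wscores(sim0)
  expect_equal(max(abs(W0$scores)), 0, tolerance = 1e-9)

  # single-biomarker model at the stage crossing threshold 2: w exactly 2
  cfg2 <- synthetic_config(
    n_patients = 4, n_controls = 10, roi_names = "b",
    thresholds = c(1, 2, 3), subtype_fractions = 1,
    truth_sequences = list(1:3), noise_sd = 0,
    stage_distribution = c(0, 0, 1, 0), seed = 4)
  sim2 <- simulate_cohort(cfg2)
  W2 <- planted_wscores(sim2)
  expect_equal(unname(W2$scores[, "b"]), rep(2, 4), tolerance = 1e-9)
})

test_that("control rows have expected w-score zero under the fitted model", {
  cfg <- synthetic_config(n_patients = 20, seed = 21)
  sim <- simulate_cohort(cfg)
  ctl <- sim$table[sim$table$group == "control", ]
  w <- compute_wscores(ctl, fit_control_model(ctl))$scores
  expect_lt(max(abs(colMeans(w))), 1e-8) # exact by OLS
})

test_that("follow-up stage advance follows round(rate x interval) with a cap", {
  cfg <- synthetic_config(n_patients = 60, stage_rate = 0, seed = 11)
  tr <- generate_truth(cfg)
  pat <- tr[tr$group == "patient", ]
  for (id in unique(pat$subject_id[pat$visit_index > 1])) {
    rows <- pat[pat$subject_id == id, ]
    expect_true(all(rows$true_stage == rows$true_stage[1]))
  }
  # huge rate: every follow-up saturates at N_events
  cfg2 <- synthetic_config(n_patients = 60, stage_rate = 1000, seed = 12)
  tr2 <- generate_truth(cfg2)
  fu <- tr2[tr2$group == "patient" & tr2$visit_index > 1, ]
  expect_true(all(fu$true_stage == cfg2$event_set$n_events))
})

test_that("a serialized configuration regenerates the identical cohort", {
  cfg <- synthetic_config(n_patients = 12, n_controls = 6,
                          roi_names = paste0("r", 1:3), thresholds = c(1, 2),
                          subtype_fractions = c(0.6, 0.4),
                          truth_sequences = list(
                            c(1L, 2L, 3L, 4L, 5L, 6L),
                            c(3L, 4L, 5L, 6L, 1L, 2L)),
                          seed = 27)
  f <- tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, f)
  cfg2 <- read_synthetic_config(f)
  expect_equal(cfg2$truth_sequences, cfg$truth_sequences)
  expect_identical(simulate_cohort(cfg2)$table, simulate_cohort(cfg)$table)
  unlink(f)
})

test_that("serialized tables round-trip byte-for-byte for a fixed seed", {
  cfg <- synthetic_config(n_patients = 15, n_controls = 8,
                          roi_names = paste0("r", 1:3), thresholds = 1,
                          subtype_fractions = 1, truth_sequences = list(1:3),
                          seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  sim <- simulate_cohort(cfg)
  write_volume_table(sim$table, f1)
  write_volume_table(simulate_cohort(cfg)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_volume_table(f1)
  expect_equal(dim(back), dim(sim$table))
  expect_equal(back$r1, sim$table$r1, tolerance = 1e-9)
  unlink(c(f1, f2))
})
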