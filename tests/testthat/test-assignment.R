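two_subtype_model <- function() {
  es <- build_event_set(paste0("r", 1:4), c(1, 2))
  s1 <- sustainr:::canonicalize_sequence(es, 1:8)
  s2 <- sustainr:::canonicalize_sequence(es, c(5:8, 1:4))
  sustainr:::new_sustain_model(es, list(s1, s2), c(0.5, 0.5))
}

test_that("the joint stage-subtype posterior is a proper distribution", {
  model <- two_subtype_model()
  set.seed(2)
  for (r in 1:5) {
    p <- posterior_stage_subtype(rnorm(4, 1), model)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
    expect_equal(dim(p), c(2, 9))
  }
})

test_that("all-zero w-scores put the posterior mode at stage zero and block subtyping", {
  model <- two_subtype_model()
  p <- posterior_stage_subtype(rep(0, 4), model)
  stage_marg <- colSums(p)
  expect_true(all(stage_marg[1] > stage_marg[-1]))
  asg <- assign_visits(matrix(0, 3, 4), model)
  expect_equal(asg$stage, rep(0L, 3))
  expect_false(any(asg$subtypable))
  expect_true(all(is.na(asg$subtype)))
  # subtypable = false <=> stage = 0 <=> subtype = none
  expect_equal(asg$subtypable, asg$stage > 0)
})

test_that("noise-free profiles are assigned their generating subtype and stage", {
  model <- two_subtype_model()
  E2 <- sustainr:::stage_expectations(model$event_set, model$sequences[[2]])
  p <- posterior_stage_subtype(E2[7, ], model) # subtype 2, stage 6
  idx <- which(p == max(p), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(2, 7))
  asg <- assign_visits(matrix(E2[7, ], 1), model)
  expect_equal(asg$subtype, 2L)
  expect_equal(asg$stage, 6L)
  expect_gte(asg$assignment_probability, 0.75)
  # posterior columns sum to 1 with the stage posterior attribute
  expect_equal(asg$prob_S1 + asg$prob_S2, 1, tolerance = 1e-10)
  expect_equal(sum(attr(asg, "stage_posterior")[1, ]), 1, tolerance = 1e-10)
})

test_that("assigned stage never decreases along a subtype's own trajectory", {
  model <- two_subtype_model()
  E1 <- sustainr:::stage_expectations(model$event_set, model$sequences[[1]])
  stages <- assign_visits(E1[c(2, 4, 6, 8), ], model)$stage
  expect_true(all(diff(stages) >= 0))
})

test_that("assignment is equivariant under subtype relabeling", {
  model <- two_subtype_model()
  swapped <- sustainr:::new_sustain_model(
    model$event_set, model$sequences[c(2, 1)], model$fractions[c(2, 1)])
  set.seed(4)
  X <- matrix(rnorm(20 * 4, 1.5), 20, 4)
  a1 <- assign_visits(X, model)
  a2 <- assign_visits(X, swapped)
  expect_equal(a1$stage, a2$stage)
  relabel <- c(2L, 1L)[a2$subtype]
  expect_equal(a1$subtype, relabel)
  expect_equal(a1$prob_S1, a2$prob_S2, tolerance = 1e-10)
})

test_that("joint-argmax mode agrees with the joint posterior cell", {
  model <- two_subtype_model()
  set.seed(5)
  x <- rnorm(4, 1)
  p <- posterior_stage_subtype(x, model)
  cell <- which(p == max(p), arr.ind = TRUE)
  asg <- assign_visits(matrix(x, 1), model, mode = "joint")
  expect_equal(asg$subtype, unname(cell[1, 1]))
  expect_equal(asg$stage, unname(cell[1, 2]) - 1L)
})

test_that("external cohorts are scored on their own controls, assignments unchanged", {
  cfg <- synthetic_config(n_patients = 60, n_controls = 45,
                          roi_names = paste0("r", 1:4), thresholds = c(1, 2),
                          subtype_fractions = c(0.5, 0.5),
                          truth_sequences = list(
                            sustainr:::canonicalize_sequence(
                              build_event_set(paste0("r", 1:4), c(1, 2)), 1:8),
                            sustainr:::canonicalize_sequence(
                              build_event_set(paste0("r", 1:4), c(1, 2)),
                              c(5:8, 1:4))),
                          seed = 77)
  sim <- simulate_cohort(cfg)
  model <- sustainr:::true_subtype_model(cfg)
  tab <- sim$table[sim$table$visit_index == 1, ]
  internal <- assign_visits(
    compute_wscores(tab[tab$group == "patient", ],
                    fit_control_model(tab[tab$group == "control", ])), model)
  # identical cohort as "external" with its own controls: idempotent
  external <- assign_external(tab, tab[tab$group == "control", ], model)
  expect_equal(external$subtype, internal$subtype)
  expect_equal(external$stage, internal$stage)

  # a global scanner offset applied to the external copy is absorbed by its
  # own control fit: subtype recovery stays within 5 points
  tab2 <- tab
  rois <- paste0("r", 1:4)
  tab2[, rois] <- tab2[, rois] + 80 * (tab2$scanner == "scanB")
  ext2 <- assign_external(tab2, tab2[tab2$group == "control", ], model)
  tr <- baseline_truth(sim)
  acc <- function(a) {
    sel <- a$subtypable & tr$true_stage >= 2
    mean(a$subtype[sel] == tr$true_subtype[sel])
  }
  expect_lte(abs(acc(ext2) - acc(internal)), 0.05)

  # volumes at the control prediction map to stage zero
  ctl <- tab[tab$group == "control", ]
  cm <- fit_control_model(ctl)
  flat <- tab[tab$group == "patient", ][1:3, ]
  flat[, rois] <- sustainr:::predict_volumes(cm, flat)
  expect_equal(assign_external(flat, ctl, model)$stage, rep(0L, 3))

  # mismatched ROI panels are rejected
  expect_error(assign_external(tab[, setdiff(names(tab), "r4")],
                               tab[tab$group == "control", ], model),
               "ROI")
})
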