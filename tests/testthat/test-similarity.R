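test_that("Hellinger distance has the analytic endpoints and closed form", {
  expect_equal(hellinger(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
  expect_equal(hellinger(c(0.5, 0.5), c(1, 0)), sqrt(1 - sqrt(0.5)))
  # the two printed forms coincide
  set.seed(1)
  p <- prop.table(runif(6)); q <- prop.table(runif(6))
  expect_equal(hellinger(p, q), sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2)))
  expect_error(hellinger(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(hellinger(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
  expect_error(hellinger(c(0.2, 0.2), c(0.5, 0.5)), "sum")
})

test_that("Hellinger is a bounded metric on random probability vectors", {
  set.seed(42)
  for (r in 1:30) {
    p <- prop.table(runif(8)); q <- prop.table(runif(8))
    s <- prop.table(runif(8))
    expect_equal(hellinger(p, q), hellinger(q, p))
    expect_gte(hellinger(p, q), 0)
    expect_lte(hellinger(p, q), 1)
    expect_lte(hellinger(p, q), hellinger(p, s) + hellinger(s, q) + 1e-12)
  }
})

test_that("positional variance counts event positions across samples", {
  # one sample: delta rows
  P1 <- positional_variance(matrix(c(2L, 1L, 3L), 1))
  expect_equal(unname(P1[2, 1]), 1)
  expect_equal(unname(P1[1, 2]), 1)
  expect_equal(unname(P1[3, 3]), 1)
  # two samples swapping adjacent events: affected rows split 0.5/0.5
  P2 <- positional_variance(rbind(c(1L, 2L, 3L), c(2L, 1L, 3L)))
  expect_equal(P2[1, 1:2], c("1" = 0.5, "2" = 0.5))
  expect_equal(P2[2, 1:2], c("1" = 0.5, "2" = 0.5))
  expect_equal(unname(P2[3, 3]), 1)
  expect_error(positional_variance(list(1:3, 1:4)), "inconsistent")
})

test_that("model distance averages per-event Hellinger distances", {
  A <- positional_variance(matrix(1:4, 1))
  expect_equal(model_distance(A, A), 0)
  B <- positional_variance(matrix(c(2L, 1L, 4L, 3L), 1)) # no shared position
  expect_equal(model_distance(A, B), 1)
  C <- positional_variance(matrix(c(1L, 2L, 4L, 3L), 1)) # half shared
  expect_equal(model_distance(A, C), 0.5)
  expect_equal(model_distance(A, C, aggregate = "max"), 1)
  expect_error(model_distance(A, positional_variance(matrix(1:3, 1))),
               "mismatch")
})

test_that("the delta-permutation reference converges to 1 - 1/N", {
  es <- build_event_set(paste0("r", 1:4), c(1, 2)) # N = 8
  ref <- randomized_reference(es, "delta-permutation", n_pairs = 4000,
                              seed = 3)
  expect_lt(abs(ref$h0_mean - (1 - 1 / 8)),
            3 * ref$h0_sd / sqrt(ref$n_pairs))
  expect_true(all(ref$distances >= 0 & ref$distances <= 1))
  expect_true(ref$ci[1] >= 0 && ref$ci[2] <= 1)
  # a model paired with itself is at distance zero
  P <- positional_variance(matrix(1:8, 1))
  expect_equal(model_distance(P, P), 0)
})

test_that("the permuted-data reference separates refits from unrelated models", {
  cfg <- small_config(n = 50, seed = 29)
  sim <- simulate_cohort(cfg)
  W <- planted_wscores(sim)
  es <- cfg$event_set
  ref <- randomized_reference(es, "permuted-data", n_pairs = 2, seed = 5,
                              W = W, mcmc_iter = 100, n_restarts = 1)
  expect_true(all(ref$distances >= 0 & ref$distances <= 1))
  expect_equal(ref$scheme, "permuted-data")
  expect_error(randomized_reference(es, "permuted-data", n_pairs = 2),
               "requires W")
})

test_that("independent MCMC runs on the same data are far below the randomized reference", {
  cfg <- small_config(n = 80, seed = 37, roi_names = paste0("r", 1:4),
                      thresholds = c(1, 2))
  sim <- simulate_cohort(cfg)
  W <- planted_wscores(sim)
  es <- cfg$event_set
  fit <- fit_sustain(W, es, C = 1, n_restarts = 3, seed = 1)
  P1 <- positional_variance(sustain_mcmc(fit, W, 2000, seed = 11)$mcmc$samples[[1]])
  P2 <- positional_variance(sustain_mcmc(fit, W, 2000, seed = 22)$mcmc$samples[[1]])
  same <- model_distance(P1, P2)
  ref <- randomized_reference(es, "delta-permutation", n_pairs = 1000,
                              seed = 6)
  expect_lt(same, ref$h0_mean - 3 * ref$h0_sd)
})
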