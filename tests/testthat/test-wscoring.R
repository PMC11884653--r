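make_controls <- function(n = 40, seed = 1, sd = 3, slope_age = 0) {
  set.seed(seed)
  age <- seq(50, 80, length.out = n)
  data.frame(
    subject_id = paste0("C", seq_len(n)), visit_index = 1L,
    group = "control", diagnosis = "control",
    age = age, sex = rep(c("F", "M"), length.out = n),
    tiv = rnorm(n, 1.4e6, 1e5),
    scanner = rep(c("A", "A", "B"), length.out = n),
    roi1 = 300 + slope_age * age + rnorm(n, 0, sd),
    roi2 = 200 + rnorm(n, 0, sd)
  )
}

test_that("a constant-volume control cohort yields intercept-only fits", {
  ctl <- make_controls(seed = 2, sd = 0)
  ctl$roi2 <- 200
  m <- fit_control_model(ctl, covariates = c("sex", "age", "tiv", "scanner"))
  expect_equal(unname(m$coefficients["(Intercept)", "roi1"]), 300,
               tolerance = 1e-6)
  slopes <- m$coefficients[setdiff(rownames(m$coefficients), "(Intercept)"),
                           "roi1"]
  expect_true(all(abs(slopes) < 1e-8))
  expect_equal(unname(m$residual_sd["roi1"]), m$min_residual_sd)
  # with noise, the residual SD estimates the noise SD
  ctln <- make_controls(n = 200, seed = 2, sd = 3)
  mn <- fit_control_model(ctln)
  expect_equal(unname(mn$residual_sd["roi2"]), 3, tolerance = 0.7)
})

test_that("exact linear dependence is recovered with a guarded residual SD", {
  ctl <- data.frame(subject_id = paste0("C", 1:5), group = "control",
                    age = c(50, 55, 60, 65, 70), sex = "F",
                    tiv = 1.4e6, scanner = "A",
                    roi1 = 2 * c(50, 55, 60, 65, 70))
  m <- fit_control_model(ctl, covariates = "age")
  expect_equal(unname(m$coefficients["age", "roi1"]), 2, tolerance = 1e-10)
  expect_equal(unname(m$residual_sd["roi1"]), 1e-8) # floored at epsilon
})

test_that("w-scores follow (observed - predicted) / residual SD with sign flip", {
  # intercept-only: prediction 100, residual SD exactly 3
  ctl <- data.frame(subject_id = paste0("C", 1:3), group = "control",
                    age = 60, sex = "F", tiv = 1.4e6, scanner = "A",
                    roi1 = c(97, 100, 103))
  # age is constant so only the intercept is identifiable; drop it
  m <- fit_control_model(ctl, covariates = character(0))
  pat <- data.frame(subject_id = "P1", group = "patient", age = 60,
                    sex = "F", tiv = 1.4e6, scanner = "A", roi1 = 94)
  expect_equal(unname(compute_wscores(pat, m)$scores[1, "roi1"]), 2)
  expect_equal(unname(compute_wscores(pat, m, sign_flip = FALSE)$scores[1, "roi1"]),
               -2)
  same <- pat; same$roi1 <- 100
  expect_equal(unname(compute_wscores(same, m)$scores[1, "roi1"]), 0)
})

test_that("in-sample control w-scores are centred with unit spread", {
  ctl <- make_controls(n = 60, seed = 3, slope_age = -1.5)
  m <- fit_control_model(ctl)
  w <- compute_wscores(ctl, m)$scores
  expect_lt(max(abs(colMeans(w))), 1e-8)
  expect_true(all(abs(apply(w, 2, sd) - 1) < 1e-8))
})

test_that("w-scores are invariant to global volume scale and scanner offsets", {
  ctl <- make_controls(n = 50, seed = 4)
  pat <- make_controls(n = 10, seed = 5)
  pat$group <- "patient"
  pat$subject_id <- paste0("P", 1:10)
  w0 <- compute_wscores(pat, fit_control_model(ctl))$scores

  # multiply all volumes and TIV by a positive constant
  sc <- function(d, f) {
    d$tiv <- d$tiv * f; d$roi1 <- d$roi1 * f; d$roi2 <- d$roi2 * f; d
  }
  w1 <- compute_wscores(sc(pat, 3.7), fit_control_model(sc(ctl, 3.7)))$scores
  expect_equal(w1, w0, tolerance = 1e-6)

  # add a constant to one scanner group in controls and patients alike
  off <- function(d) {
    d$roi1 <- d$roi1 + 50 * (d$scanner == "B"); d
  }
  w2 <- compute_wscores(off(pat), fit_control_model(off(ctl)))$scores
  expect_equal(w2, w0, tolerance = 1e-6)
})

test_that("unseen scanner categories are rejected explicitly", {
  ctl <- make_controls()
  m <- fit_control_model(ctl)
  pat <- make_controls(n = 3, seed = 6)
  pat$scanner <- "Z"
  expect_error(compute_wscores(pat, m), "unseen scanner.*Z")
})

test_that("planted covariate coefficients are recovered within 3 SE", {
  cfg <- synthetic_config(seed = 9)
  sim <- simulate_cohort(cfg)
  ctl <- sim$table[sim$table$group == "control", ]
  m <- fit_control_model(ctl)
  # standard errors from a reference lm fit on one ROI
  roi <- cfg$roi_names[1]
  lf <- lm(ctl[[roi]] ~ sex + age + tiv + scanner, data = ctl)
  se <- summary(lf)$coefficients[, "Std. Error"]
  eff <- cfg$covariate_effects
  truth <- c(eff$sexM, eff$age, eff$tiv)
  est <- coef(lf)[c("sexM", "age", "tiv")]
  expect_true(all(abs(est - truth) <= 3 * se[c("sexM", "age", "tiv")]))
  # the packaged fit agrees with lm
  expect_equal(unname(m$coefficients[c("sexM", "age", "tiv"), roi]),
               unname(est), tolerance = 1e-8)
})

test_that("duplicate control rows and missing covariates are rejected", {
  ctl <- make_controls()
  expect_error(fit_control_model(rbind(ctl, ctl[1, ])), "one")
  ctl$age[3] <- NA
  expect_error(fit_control_model(ctl), "missing")
})
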