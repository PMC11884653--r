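# Synthetic cohort generator: patient/control regional volume tables with
# planted subtype, stage, covariate and longitudinal structure.

#' Default ROI panel for the synthetic cohort
#'
#' Nineteen largely cortical, left-lateralised regions implicated in primary
#' progressive aphasia (temporal, insular, temporoparietal and frontal
#' territories plus mesial temporal structures).
#'
#' @return character vector of 19 region names.
#' @export
ppa_roi_names <- function() {
  c("left_temporal_pole", "left_inferior_temporal", "left_middle_temporal",
    "left_superior_temporal", "right_temporal_pole", "left_hippocampus",
    "left_amygdala", "right_amygdala", "left_parahippocampal",
    "left_insula", "right_insula", "left_anterior_cingulate",
    "left_inferior_frontal", "left_orbitofrontal", "left_superior_frontal",
    "left_precentral", "left_temporoparietal", "left_inferior_parietal",
    "left_precuneus")
}

# Four qualitative ROI priority orderings: temporal-first, insula-first,
# temporoparietal-first, frontal-first. Each is a permutation of the ROI
# indices; remaining regions follow in panel order.
default_subtype_orderings <- function(roi_names) {
  pick <- function(first) {
    idx <- match(first, roi_names)
    if (anyNA(idx)) stop_config("unknown ROI in subtype ordering")
    c(idx, setdiff(seq_along(roi_names), idx))
  }
  list(
    temporal = pick(c("left_temporal_pole", "left_inferior_temporal",
                      "left_middle_temporal", "left_superior_temporal",
                      "left_hippocampus", "left_amygdala",
                      "left_parahippocampal", "right_temporal_pole",
                      "right_amygdala", "left_insula")),
    insula = pick(c("left_insula", "right_insula", "left_hippocampus",
                    "left_parahippocampal", "left_amygdala", "right_amygdala",
                    "left_inferior_frontal", "left_anterior_cingulate")),
    temporoparietal = pick(c("left_temporoparietal", "left_inferior_parietal",
                             "left_precuneus", "left_middle_temporal",
                             "left_superior_temporal",
                             "left_inferior_temporal")),
    frontal = pick(c("left_precentral", "left_inferior_frontal",
                     "left_orbitofrontal", "left_superior_frontal",
                     "left_anterior_cingulate", "left_insula"))
  )
}

# Turn an ROI priority ordering into a valid event sequence: events are
# ranked by roi_rank + (threshold_rank - 1) * lag, so early regions cross
# successive thresholds while later regions begin to decline.
make_truth_sequence <- function(event_set, roi_order, lag = 6) {
  ev <- event_set$events
  rank_of_roi <- match(ev$bio, roi_order)
  level <- match(ev$z, sort(unique(ev$z)))
  key <- rank_of_roi + (level - 1L) * lag
  seq_ids <- order(key, rank_of_roi, ev$z)
  canonicalize_sequence(event_set, seq_ids)
}

default_truth_sequences <- function(event_set, n_subtypes = 4L, lag = 6) {
  ords <- default_subtype_orderings(event_set$roi_names)
  if (n_subtypes > length(ords))
    stop_config("no default orderings for %d subtypes", n_subtypes)
  lapply(ords[seq_len(n_subtypes)], make_truth_sequence,
         event_set = event_set, lag = lag)
}

# Diagnosis-given-subtype probabilities mirroring the discovery cohort's
# subtype demographics (rows: subtypes, cols: diagnosis labels).
default_diagnosis_probs <- function(n_subtypes) {
  labels <- c("svPPA", "nfvPPA", "lvPPA", "PPA-nos")
  m <- rbind(c(71, 3, 1, 7), c(15, 34, 18, 4),
             c(4, 21, 31, 3), c(4, 45, 1, 2))
  m <- m / rowSums(m)
  colnames(m) <- labels
  if (n_subtypes == 4L) return(m)
  matrix(1 / 4, n_subtypes, 4L, dimnames = list(NULL, labels))
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the planted study design: cohort sizes, ROI panel, severity
#' thresholds, subtype mixture fractions and truth sequences, stage
#' distribution, noise, covariate effect sizes and longitudinal follow-up
#' parameters. Defaults emulate a primary progressive aphasia discovery
#' cohort: 270 patients (four subtypes with fractions 82/71/59/52 out of
#' 264), 121 controls, 19 ROIs with thresholds (1, 2, 3), follow-up scans
#' for 137/270 of subjects at 1.1 +/- 0.6-year intervals.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param roi_names ROI panel (default [ppa_roi_names()]).
#' @param thresholds ascending positive w-score severity levels.
#' @param subtype_fractions mixture fractions, summing to 1.
#' @param truth_sequences list of planted event sequences (one per subtype);
#'   default: four orderings with temporal-, insula-, temporoparietal- and
#'   frontal-first progression.
#' @param stage_distribution probabilities over baseline stages 0..N_events
#'   (default uniform).
#' @param noise_sd Gaussian noise on patient abnormality, w-score units.
#' @param baseline_volume per-ROI intercept volume in mm^3 (default a spread
#'   from 3000 to 12000).
#' @param residual_frac control residual SD as a fraction of
#'   `baseline_volume` (default 0.05).
#' @param covariate_effects list with `age` (mm^3/year), `sexM` (mm^3),
#'   `tiv` (mm^3/mm^3) and named `scanner` offsets (mm^3).
#' @param age_mean_sd_patient,age_mean_sd_control,tiv_mean_sd sampling
#'   parameters for covariates.
#' @param p_male probability of male sex.
#' @param scanner_probs sampling probabilities of the scanner levels.
#' @param followup_fraction fraction of patients with at least one follow-up.
#' @param followup_interval mean and SD (years) of the inter-scan interval,
#'   truncated at > 0.
#' @param followup_visits_probs distribution of the number of extra visits
#'   (1, 2, 3, ...) among followed-up subjects.
#' @param stage_rate true disease progression in stages/year; follow-up
#'   stage advances by `round(stage_rate * interval)`, capped at N_events.
#' @param scanner_change_prob probability a follow-up scan uses a different
#'   scanner.
#' @param diagnosis_probs matrix of diagnosis-given-subtype probabilities.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 270L, n_controls = 121L,
                             roi_names = ppa_roi_names(),
                             thresholds = c(1, 2, 3),
                             subtype_fractions = c(82, 71, 59, 52) / 264,
                             truth_sequences = NULL,
                             stage_distribution = NULL,
                             noise_sd = 1,
                             baseline_volume = NULL,
                             residual_frac = 0.05,
                             covariate_effects = list(
                               age = -25, sexM = 300, tiv = 0.004,
                               scanner = c(scanA = 0, scanB = 150,
                                           scanC = -150)),
                             age_mean_sd_patient = c(66.1, 7.9),
                             age_mean_sd_control = c(61.7, 11.1),
                             tiv_mean_sd = c(1450000, 130000),
                             p_male = 0.5,
                             scanner_probs = c(0.4, 0.35, 0.25),
                             followup_fraction = 137 / 270,
                             followup_interval = c(mean = 1.1, sd = 0.6),
                             followup_visits_probs = c(71, 43, 23) / 137,
                             stage_rate = 4,
                             scanner_change_prob = 0.2,
                             diagnosis_probs = NULL,
                             seed = 1L) {
  if (abs(sum(subtype_fractions) - 1) > 1e-12)
    stop_config("subtype_fractions must sum to 1")
  if (any(subtype_fractions < 0) || any(subtype_fractions > 1))
    stop_config("subtype_fractions must lie in [0, 1]")
  if (stage_rate < 0) stop_config("stage_rate must be non-negative")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  event_set <- build_event_set(roi_names, thresholds)
  C <- length(subtype_fractions)
  if (is.null(truth_sequences))
    truth_sequences <- default_truth_sequences(event_set, C)
  if (length(truth_sequences) != C)
    stop_config("need one truth sequence per subtype")
  for (s in truth_sequences) validate_sequence(event_set, s)
  N <- event_set$n_events
  if (is.null(stage_distribution))
    stage_distribution <- rep(1 / (N + 1), N + 1)
  if (length(stage_distribution) != N + 1 ||
      abs(sum(stage_distribution) - 1) > 1e-8)
    stop_config("stage_distribution must have %d probabilities summing to 1",
                N + 1)
  B <- length(roi_names)
  if (is.null(baseline_volume)) baseline_volume <- seq(3000, 12000,
                                                       length.out = B)
  baseline_volume <- stats::setNames(rep_len(baseline_volume, B), roi_names)
  if (is.null(diagnosis_probs)) diagnosis_probs <- default_diagnosis_probs(C)
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         roi_names = roi_names, thresholds = thresholds,
         event_set = event_set,
         subtype_fractions = subtype_fractions,
         truth_sequences = truth_sequences,
         stage_distribution = stage_distribution,
         noise_sd = noise_sd, baseline_volume = baseline_volume,
         residual_frac = residual_frac,
         covariate_effects = covariate_effects,
         age_mean_sd_patient = age_mean_sd_patient,
         age_mean_sd_control = age_mean_sd_control,
         tiv_mean_sd = tiv_mean_sd, p_male = p_male,
         scanner_probs = scanner_probs,
         followup_fraction = followup_fraction,
         followup_interval = followup_interval,
         followup_visits_probs = followup_visits_probs,
         stage_rate = stage_rate,
         scanner_change_prob = scanner_change_prob,
         diagnosis_probs = diagnosis_probs,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

sample_covariates <- function(n, config, group) {
  ams <- if (group == "patient") config$age_mean_sd_patient else
    config$age_mean_sd_control
  scanners <- names(config$covariate_effects$scanner)
  data.frame(
    age = rnorm_trunc(n, ams[1], ams[2], 40, 95),
    sex = ifelse(stats::rbinom(n, 1, config$p_male) == 1, "M", "F"),
    tiv = rnorm_trunc(n, config$tiv_mean_sd[1], config$tiv_mean_sd[2],
                      1e6, 2e6),
    scanner = sample(scanners, n, replace = TRUE,
                     prob = config$scanner_probs),
    stringsAsFactors = FALSE
  )
}

#' Draw the per-visit ground truth of a synthetic cohort
#'
#' Samples each patient's subtype (multinomial with the configured
#' fractions), baseline stage, covariates, diagnosis label, and the
#' follow-up schedule: a configured fraction of patients receive 1-3 extra
#' visits at truncated-normal intervals, with the true stage advancing by
#' `round(stage_rate * interval)` (capped at N_events) and the scanner
#' switching with the configured probability. Controls contribute one
#' baseline visit at stage 0. Deterministic for a fixed `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A data frame of class `sustain_truth`, one row per visit, with
#'   subject_id, visit_index, group, diagnosis, true_subtype, true_stage,
#'   covariates and interval_years.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  C <- length(config$subtype_fractions)
  N <- config$event_set$n_events
  subtype <- sample.int(C, n, replace = TRUE,
                        prob = config$subtype_fractions)
  stage0 <- sample(0:N, n, replace = TRUE, prob = config$stage_distribution)
  cov <- sample_covariates(n, config, "patient")
  dlabels <- colnames(config$diagnosis_probs)
  diagnosis <- vapply(subtype, function(c)
    sample(dlabels, 1L, prob = config$diagnosis_probs[c, ]), character(1))
  ids <- sprintf("P%03d", seq_len(n))

  base <- data.frame(
    subject_id = ids, visit_index = 1L, group = "patient",
    diagnosis = diagnosis, true_subtype = subtype, true_stage = stage0,
    age = cov$age, sex = cov$sex, tiv = cov$tiv, scanner = cov$scanner,
    interval_years = 0, stringsAsFactors = FALSE
  )

  n_fu <- round(config$followup_fraction * n)
  fu_ids <- sort(sample.int(n, n_fu))
  scanners <- names(config$covariate_effects$scanner)
  fu_rows <- list()
  for (i in fu_ids) {
    n_extra <- sample(seq_along(config$followup_visits_probs), 1L,
                      prob = config$followup_visits_probs)
    stage <- stage0[i]
    age <- cov$age[i]
    scanner <- cov$scanner[i]
    for (v in seq_len(n_extra)) {
      interval <- rnorm_trunc(1L, config$followup_interval[["mean"]],
                              config$followup_interval[["sd"]], lower = 0)
      stage <- min(N, stage + round(config$stage_rate * interval))
      age <- age + interval
      if (length(scanners) > 1L &&
          stats::runif(1) < config$scanner_change_prob)
        scanner <- sample(setdiff(scanners, scanner), 1L)
      fu_rows[[length(fu_rows) + 1L]] <- data.frame(
        subject_id = ids[i], visit_index = v + 1L, group = "patient",
        diagnosis = diagnosis[i], true_subtype = subtype[i],
        true_stage = stage, age = age, sex = cov$sex[i], tiv = cov$tiv[i],
        scanner = scanner, interval_years = interval,
        stringsAsFactors = FALSE
      )
    }
  }

  ccov <- sample_covariates(config$n_controls, config, "control")
  ctrl <- data.frame(
    subject_id = sprintf("C%03d", seq_len(config$n_controls)),
    visit_index = 1L, group = "control", diagnosis = "control",
    true_subtype = NA_integer_, true_stage = 0L,
    age = ccov$age, sex = ccov$sex, tiv = ccov$tiv, scanner = ccov$scanner,
    interval_years = 0, stringsAsFactors = FALSE
  )

  truth <- rbind(base, do.call(rbind, c(fu_rows, list(ctrl[0, ]))), ctrl)
  rownames(truth) <- NULL
  truth <- truth[order(truth$group, truth$subject_id, truth$visit_index), ]
  rownames(truth) <- NULL
  class(truth) <- c("sustain_truth", "data.frame")
  attr(truth, "config") <- config
  truth
}

# Volumes for a set of truth rows: linear covariate predictor minus
# sigma_ROI * abnormality. Patient abnormality = planted trajectory value +
# Gaussian noise; control abnormality is pure unit-variance noise so the
# control residual SD equals sigma_ROI.
volumes_for_rows <- function(rows, config) {
  B <- length(config$roi_names)
  eff <- config$covariate_effects
  sigma_roi <- config$residual_frac * config$baseline_volume
  pred <- outer(rep(1, nrow(rows)), config$baseline_volume) +
    eff$age * rows$age +
    eff$sexM * (rows$sex == "M") +
    eff$tiv * rows$tiv +
    eff$scanner[rows$scanner]
  Es <- lapply(config$truth_sequences, stage_expectations,
               event_set = config$event_set)
  ab <- matrix(0, nrow(rows), B)
  pat <- rows$group == "patient"
  if (any(pat)) {
    idx <- cbind(rows$true_stage[pat] + 1L, rep(1L, sum(pat)))
    for (c in seq_along(Es)) {
      sel <- which(pat & rows$true_subtype == c)
      if (length(sel))
        ab[sel, ] <- Es[[c]][rows$true_stage[sel] + 1L, , drop = FALSE]
    }
    ab[pat, ] <- ab[pat, , drop = FALSE] +
      matrix(stats::rnorm(sum(pat) * B, 0, config$noise_sd), ncol = B)
  }
  ctl <- !pat
  if (any(ctl))
    ab[ctl, ] <- matrix(stats::rnorm(sum(ctl) * B), ncol = B)
  vol <- pred - sweep(ab, 2L, sigma_roi, `*`)
  colnames(vol) <- config$roi_names
  vol
}

truth_to_table <- function(rows, config) {
  vol <- volumes_for_rows(rows, config)
  out <- cbind(
    rows[, c("subject_id", "visit_index", "group", "diagnosis",
             "age", "sex", "tiv", "scanner")],
    as.data.frame(vol)
  )
  rownames(out) <- NULL
  out
}

#' Generate baseline regional volumes from a synthetic truth
#'
#' Inverts the w-score model: volume = covariate predictor - sigma_ROI *
#' abnormality, where patient abnormality is the planted piecewise-linear
#' trajectory value at the true stage plus Gaussian noise of SD `noise_sd`,
#' and control abnormality is unit-variance noise (so the fitted control
#' residual SD recovers sigma_ROI). Deterministic given `config$seed`.
#'
#' @param truth a [generate_truth()] table.
#' @param config the matching [synthetic_config()].
#' @return Regional volume table (baseline visits of patients and controls).
#' @export
generate_cohort <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  for (v in c("age", "sex", "tiv", "scanner"))
    if (any(is.na(truth[[v]]))) stop_config("missing covariate '%s'", v)
  set.seed(config$seed + 1L)
  truth_to_table(truth[truth$visit_index == 1L, , drop = FALSE], config)
}

#' Generate follow-up regional volumes from a synthetic truth
#'
#' Emits the follow-up visit rows (visit_index > 1) of the truth schedule
#' with the same forward volume model as [generate_cohort()].
#'
#' @inheritParams generate_cohort
#' @return Regional volume table of follow-up visits.
#' @export
generate_followups <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  truth_to_table(truth[truth$visit_index > 1L, , drop = FALSE], config)
}

#' Planted covariate model of a synthetic configuration
#'
#' The exact generating covariate model as a `covariate_model` object:
#' scoring synthetic volumes with it inverts the forward model exactly, so
#' noise-free cohorts recover their planted abnormality scores to machine
#' precision.
#'
#' @param config a [synthetic_config()].
#' @return A `covariate_model` with the planted coefficients and
#'   `residual_sd = residual_frac * baseline_volume`.
#' @export
true_covariate_model <- function(config) {
  eff <- config$covariate_effects
  scanners <- names(eff$scanner)
  rois <- config$roi_names
  p <- c("(Intercept)", "sexM", "age", "tiv",
         paste0("scanner", scanners[-1L]))
  coef <- matrix(0, length(p), length(rois),
                 dimnames = list(p, rois))
  coef["(Intercept)", ] <- config$baseline_volume + eff$scanner[[1L]]
  coef["sexM", ] <- eff$sexM
  coef["age", ] <- eff$age
  coef["tiv", ] <- eff$tiv
  for (s in scanners[-1L])
    coef[paste0("scanner", s), ] <- eff$scanner[[s]] - eff$scanner[[1L]]
  structure(
    list(coefficients = coef,
         residual_sd = config$residual_frac * config$baseline_volume,
         covariates = c("sex", "age", "tiv", "scanner"),
         levels = list(sex = c("F", "M"), scanner = scanners),
         rois = rois, control_n = NA_integer_,
         min_residual_sd = 1e-8, source = "synthetic-truth"),
    class = "covariate_model"
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: draws the truth, baseline and follow-up volumes, and
#' returns them with the planted covariate model and event set.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `sustain_simulation` with `table` (all visits),
#'   `truth`, `true_model`, `event_set` and `config`.
#' @export
simulate_cohort <- function(config) {
  truth <- generate_truth(config)
  baseline <- generate_cohort(truth, config)
  followups <- generate_followups(truth, config)
  table <- rbind(baseline, followups)
  table <- table[order(table$group, table$subject_id, table$visit_index), ]
  rownames(table) <- NULL
  structure(list(table = table, truth = truth,
                 true_model = true_covariate_model(config),
                 event_set = config$event_set, config = config),
            class = "sustain_simulation")
}

# Subtype model carrying the planted sequences/fractions; used to evaluate
# the assignment machinery under known ground truth.
true_subtype_model <- function(config, noise_sd = 1) {
  new_sustain_model(config$event_set, config$truth_sequences,
                    config$subtype_fractions, noise_sd,
                    fit_info = list(source = "synthetic-truth"))
}
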