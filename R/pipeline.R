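# End-to-end analysis pipeline: simulate/ingest -> w-score -> (select C) ->
# fit -> MCMC -> assign -> similarity -> longitudinal -> reports.

#' Configure an end-to-end analysis run
#'
#' @param synthetic generate the cohort with [simulate_cohort()] (default);
#'   otherwise `input` and `controls` paths must point to volume tables.
#' @param synthetic_config a [synthetic_config()] for synthetic mode.
#' @param input,controls paths to patient / control volume tables when
#'   `synthetic = FALSE`.
#' @param thresholds severity thresholds of the event set.
#' @param n_subtypes fixed number of subtypes, or `NULL` to select by
#'   cross-validation over `candidate_C`.
#' @param candidate_C candidates for CVIC selection.
#' @param cv_folds folds for CVIC.
#' @param mcmc_iter MCMC iterations for the final model.
#' @param n_restarts,n_split,em_tol fitting controls, see [fit_sustain()].
#' @param reference_pairs pairs for the delta-permutation randomized
#'   reference.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synthetic_config = NULL,
                            input = NULL, controls = NULL,
                            thresholds = c(1, 2, 3),
                            n_subtypes = 4L, candidate_C = 1:5,
                            cv_folds = 10L, mcmc_iter = 10000L,
                            n_restarts = 10L, n_split = 5L, em_tol = 1e-6,
                            reference_pairs = 2000L, seed = 1L) {
  if (synthetic && is.null(synthetic_config))
    synthetic_config <- default_synthetic_config(thresholds, seed)
  if (!synthetic && (is.null(input) || is.null(controls)))
    stop_config("non-synthetic mode needs 'input' and 'controls' paths")
  structure(list(synthetic = synthetic, synthetic_config = synthetic_config,
                 input = input, controls = controls,
                 thresholds = thresholds, n_subtypes = n_subtypes,
                 candidate_C = candidate_C, cv_folds = cv_folds,
                 mcmc_iter = mcmc_iter, n_restarts = n_restarts,
                 n_split = n_split, em_tol = em_tol,
                 reference_pairs = reference_pairs, seed = as.integer(seed)),
            class = "pipeline_config")
}

default_synthetic_config <- function(thresholds, seed) {
  synthetic_config(thresholds = thresholds, seed = seed)
}

#' Filter the rows of a table with a predicate expression
#'
#' Evaluates a predicate (character expression over column names, e.g.
#' `"scan_year >= 2011"`) within the table and keeps the rows where it is
#' TRUE. Referencing an unknown column is an error; row counts are logged.
#'
#' @param table a data frame.
#' @param predicate character predicate expression.
#' @return the filtered data frame.
#' @export
filter_rows <- function(table, predicate) {
  expr <- parse(text = predicate)[[1L]]
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(table))
  if (length(unknown))
    stop_config("predicate references unknown column(s): %s",
                paste(unknown, collapse = ", "))
  keep <- eval(expr, table, baseenv())
  keep <- rep_len(!is.na(keep) & keep, nrow(table))
  message(sprintf("filter '%s': kept %d of %d rows", predicate, sum(keep),
                  nrow(table)))
  table[keep, , drop = FALSE]
}

stage_log <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full subtype-and-stage analysis pipeline
#'
#' Executes the stages in order (simulate or ingest, w-scoring, optional
#' CVIC subtype-count selection, model fit, MCMC, per-visit assignment,
#' positional variance and similarity with a randomized reference,
#' longitudinal stability, subtype-diagnosis contingency) and writes every
#' artifact plus a run manifest to `out_dir`. Re-running with the same
#' configuration reproduces byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory artifacts (w-scores, model,
#'   assignments, reports, manifest).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  if (config$synthetic) {
    sim <- stage_log("simulate", simulate_cohort(config$synthetic_config))
    table <- sim$table
    write_volume_table(table, p("volumes.tsv"))
    write_volume_table(sim$truth, p("truth.tsv"))
    write_synthetic_config(config$synthetic_config, p("synthetic_config.yaml"))
  } else {
    table <- stage_log("ingest", read_volume_table(config$input))
  }
  controls <- if (config$synthetic) table[table$group == "control", ]
              else read_volume_table(config$controls)
  patients <- table[table$group != "control", ]

  rois <- roi_columns(patients)
  event_set <- build_event_set(rois, config$thresholds)

  cm <- stage_log("wscore", fit_control_model(controls))
  W <- compute_wscores(patients, cm)
  write_wscores(W, p("wscores.tsv"))
  Wb <- subset_wscores(W, W$meta$visit_index == 1L)

  cv <- NULL
  C <- config$n_subtypes
  if (is.null(C)) {
    cv <- stage_log("select", cross_validate_sustain(
      Wb, event_set, candidate_C = config$candidate_C,
      n_folds = config$cv_folds, seed = seed + 11L))
    C <- cv$selected
    utils::write.table(
      data.frame(C = cv$candidate_C, cvic = cv$cvic,
                 selected = cv$candidate_C == cv$selected),
      p("cvic.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  model <- stage_log("fit", fit_sustain(
    Wb, event_set, C = C, n_restarts = config$n_restarts,
    n_split = config$n_split, em_tol = config$em_tol, seed = seed + 21L))
  model <- stage_log("mcmc", sustain_mcmc(model, Wb,
                                          n_iter = config$mcmc_iter,
                                          seed = seed + 31L))
  write_sustain_model(model, p("model.yaml"))

  pvds <- lapply(model$mcmc$samples, positional_variance,
                 labels = event_set$events$label)
  for (c in seq_along(pvds))
    utils::write.table(round(pvds[[c]], 6), p(sprintf("pvd_S%d.tsv", c)),
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA)
  ref <- stage_log("similarity", randomized_reference(
    event_set, "delta-permutation", n_pairs = config$reference_pairs,
    seed = seed + 41L))
  sim_tab <- subtype_similarity_table(pvds, ref)
  utils::write.table(sim_tab, p("similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assignments <- stage_log("assign", assign_visits(W, model))
  utils::write.table(as.data.frame(assignments), p("assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  stability <- NULL
  if (any(assignments$visit_index > 1L)) {
    stability <- stage_log("longitudinal", stability_metrics(assignments))
    yaml::write_yaml(list(
      n_longitudinal = stability$n_longitudinal,
      overall_stability = stability$overall_stability,
      per_subtype_stability = as.list(stability$per_subtype_stability),
      stage_outcomes = as.list(stability$stage_outcomes),
      staging_consistency = stability$staging_consistency,
      multi_visit = as.list(stability$multi_visit)),
      p("stability.yaml"))
    utils::write.table(stability$transition, p("transitions.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  contingency <- NULL
  if (C > 1L && length(unique(stats::na.omit(assignments$diagnosis))) > 1L) {
    contingency <- stage_log("report", contingency_report(assignments))
    utils::write.table(as.data.frame.matrix(contingency$table),
                       p("contingency.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sustainr")),
    seed = seed,
    synthetic = config$synthetic,
    n_patients = length(unique(patients$subject_id)),
    n_controls = length(unique(controls$subject_id)),
    n_rois = length(rois),
    thresholds = as.list(config$thresholds),
    n_events = event_set$n_events,
    n_subtypes = model$C,
    selected_by_cv = is.null(config$n_subtypes),
    mcmc_iter = config$mcmc_iter,
    loglik = model$loglik,
    fractions = as.list(model$fractions),
    stage_seeds = list(cv = seed + 11L, fit = seed + 21L,
                       mcmc = seed + 31L, reference = seed + 41L)
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(wscores = W, model = model, cv = cv,
                 assignments = assignments, pvds = pvds, reference = ref,
                 stability = stability, contingency = contingency,
                 manifest = manifest))
}

subtype_similarity_table <- function(pvds, ref) {
  C <- length(pvds)
  rows <- list()
  if (C > 1L)
    for (i in seq_len(C - 1L))
      for (j in seq((i + 1L), C))
        rows[[length(rows) + 1L]] <- data.frame(
          a = paste0("S", i), b = paste0("S", j),
          hellinger = model_distance(pvds[[i]], pvds[[j]]))
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), hellinger = numeric())
  d$reference_mean <- ref$h0_mean
  d$reference_sd <- ref$h0_sd
  d
}
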