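# Plain-text serialization of tables and model artifacts. All tables are
# tab-delimited with a header row; missing values use the explicit sentinel
# "NA".

#' Write / read a regional volume (or any) table as delimited text
#'
#' @param table a data frame.
#' @param path file path.
#' @return `read_volume_table` returns the data frame.
#' @export
write_volume_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_volume_table
#' @export
read_volume_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a fitted subtype model to structured text
#'
#' The model (event set, per-subtype sequences as ordered event labels,
#' fractions, noise SD, log-likelihood, fit metadata) is written as YAML;
#' MCMC sequence samples, if present, go to a companion tab-delimited table
#' `<path>.samples.tsv` (one row per iteration and subtype).
#'
#' @param model a `sustain_model`.
#' @param path output path for the YAML artifact.
#' @return invisibly, the path.
#' @export
write_sustain_model <- function(model, path) {
  es <- model$event_set
  doc <- list(
    class = "sustain_model",
    roi_names = as.list(es$roi_names),
    thresholds = as.list(es$thresholds),
    z_max = as.list(es$z_max),
    n_subtypes = model$C,
    sequences = lapply(model$sequences, function(s)
      as.list(es$events$label[s])),
    fractions = as.list(model$fractions),
    noise_sd = as.list(rep_len(model$noise_sd, length(es$roi_names))),
    loglik = model$loglik,
    fit_info = model$fit_info[setdiff(names(model$fit_info),
                                      "loglik_trace")],
    has_mcmc = !is.null(model$mcmc)
  )
  yaml::write_yaml(doc, path, precision = 15L)
  if (!is.null(model$mcmc)) {
    samp <- do.call(rbind, lapply(seq_len(model$C), function(c) {
      m <- model$mcmc$samples[[c]]
      data.frame(subtype = c, iteration = seq_len(nrow(m)), m)
    }))
    names(samp) <- c("subtype", "iteration", paste0("pos", seq_len(es$n_events)))
    utils::write.table(samp, paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a serialized subtype model
#'
#' @param path path written by [write_sustain_model()].
#' @return a `sustain_model`.
#' @export
read_sustain_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$class, "sustain_model"))
    stop_config("%s is not a serialized sustain_model", path)
  es <- build_event_set(unlist(doc$roi_names), unlist(doc$thresholds),
                        unlist(doc$z_max))
  sequences <- lapply(doc$sequences, function(lab)
    match(unlist(lab), es$events$label))
  model <- new_sustain_model(es, sequences, unlist(doc$fractions),
                             noise_sd = unlist(doc$noise_sd),
                             loglik = doc$loglik %||% NA_real_,
                             fit_info = doc$fit_info %||% list())
  sfile <- paste0(path, ".samples.tsv")
  if (isTRUE(doc$has_mcmc) && file.exists(sfile)) {
    samp <- utils::read.table(sfile, sep = "\t", header = TRUE)
    samples <- lapply(seq_len(model$C), function(c) {
      m <- as.matrix(samp[samp$subtype == c, -(1:2), drop = FALSE])
      dimnames(m) <- NULL
      storage.mode(m) <- "integer"
      m
    })
    model$mcmc <- list(samples = samples, n_iter = nrow(samples[[1L]]),
                       loglik = NULL, acceptance_rate = NA_real_,
                       seed = NA_integer_)
  }
  model
}

#' Serialize / restore a synthetic cohort configuration
#'
#' The full generator configuration (cohort sizes, ROI panel, thresholds,
#' fractions, truth sequences, covariate effects, longitudinal design and
#' seed) round-trips through a YAML text file, so a simulated study is fully
#' reproducible from its config artifact.
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `read_synthetic_config` returns the reconstructed
#'   `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  doc <- list(
    class = "synthetic_config",
    n_patients = config$n_patients, n_controls = config$n_controls,
    roi_names = as.list(config$roi_names),
    thresholds = as.list(config$thresholds),
    subtype_fractions = as.list(config$subtype_fractions),
    truth_sequences = lapply(config$truth_sequences, as.list),
    stage_distribution = as.list(config$stage_distribution),
    noise_sd = config$noise_sd,
    baseline_volume = as.list(unname(config$baseline_volume)),
    residual_frac = config$residual_frac,
    covariate_effects = list(
      age = config$covariate_effects$age,
      sexM = config$covariate_effects$sexM,
      tiv = config$covariate_effects$tiv,
      scanner = as.list(config$covariate_effects$scanner)),
    age_mean_sd_patient = as.list(config$age_mean_sd_patient),
    age_mean_sd_control = as.list(config$age_mean_sd_control),
    tiv_mean_sd = as.list(config$tiv_mean_sd),
    p_male = config$p_male,
    scanner_probs = as.list(config$scanner_probs),
    followup_fraction = config$followup_fraction,
    followup_interval = as.list(config$followup_interval),
    followup_visits_probs = as.list(config$followup_visits_probs),
    stage_rate = config$stage_rate,
    scanner_change_prob = config$scanner_change_prob,
    diagnosis_probs = apply(config$diagnosis_probs, 1, as.list,
                            simplify = FALSE),
    diagnosis_labels = as.list(colnames(config$diagnosis_probs)),
    seed = config$seed
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  d <- yaml::read_yaml(path)
  if (!identical(d$class, "synthetic_config"))
    stop_config("%s is not a serialized synthetic_config", path)
  dp <- do.call(rbind, lapply(d$diagnosis_probs, unlist))
  colnames(dp) <- unlist(d$diagnosis_labels)
  renorm <- function(p) p / sum(p) # YAML prints finite precision
  synthetic_config(
    n_patients = d$n_patients, n_controls = d$n_controls,
    roi_names = unlist(d$roi_names), thresholds = unlist(d$thresholds),
    subtype_fractions = renorm(unlist(d$subtype_fractions)),
    truth_sequences = lapply(d$truth_sequences, function(s)
      as.integer(unlist(s))),
    stage_distribution = renorm(unlist(d$stage_distribution)),
    noise_sd = d$noise_sd,
    baseline_volume = unlist(d$baseline_volume),
    residual_frac = d$residual_frac,
    covariate_effects = list(
      age = d$covariate_effects$age, sexM = d$covariate_effects$sexM,
      tiv = d$covariate_effects$tiv,
      scanner = unlist(d$covariate_effects$scanner)),
    age_mean_sd_patient = unlist(d$age_mean_sd_patient),
    age_mean_sd_control = unlist(d$age_mean_sd_control),
    tiv_mean_sd = unlist(d$tiv_mean_sd),
    p_male = d$p_male, scanner_probs = unlist(d$scanner_probs),
    followup_fraction = d$followup_fraction,
    followup_interval = unlist(d$followup_interval),
    followup_visits_probs = unlist(d$followup_visits_probs),
    stage_rate = d$stage_rate,
    scanner_change_prob = d$scanner_change_prob,
    diagnosis_probs = dp, seed = d$seed
  )
}

#' Write a w-score matrix with its metadata
#'
#' @param W a `wscore_matrix`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_wscores <- function(W, path) {
  stopifnot(inherits(W, "wscore_matrix"))
  out <- cbind(W$meta, as.data.frame(W$scores))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a w-score matrix written by [write_wscores()]
#'
#' @param path file path.
#' @return a `wscore_matrix`.
#' @export
read_wscores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta_cols <- c("subject_id", "visit_index", "group", "diagnosis")
  scores <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  meta <- df[, meta_cols]
  rownames(scores) <- paste(meta$subject_id, meta$visit_index, sep = ".")
  structure(list(scores = scores, meta = meta, model_ref = "deserialized"),
            class = "wscore_matrix")
}
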