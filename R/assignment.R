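# Probabilistic per-visit subtype and stage assignment.

#' Joint stage-subtype posterior for one subject-visit
#'
#' P(c, k | x) proportional to f_c * p(x | S_c, k) under a uniform stage
#' prior, normalised over all subtype-stage cells (computed in log space).
#'
#' @param w_row numeric w-score vector (one per biomarker).
#' @param model a fitted `sustain_model`.
#' @return A `C x (N_events + 1)` matrix of posterior probabilities summing
#'   to 1; rows subtypes, columns stages 0..N_events.
#' @export
posterior_stage_subtype <- function(w_row, model) {
  X <- matrix(as.numeric(w_row), nrow = 1L)
  lj <- joint_log_posterior(X, model)[1L, , ]
  lj <- matrix(lj, nrow = model$C)
  p <- exp(lj - logsumexp(lj))
  rownames(p) <- paste0("S", seq_len(model$C))
  colnames(p) <- 0:model$event_set$n_events
  p / sum(p)
}

# n x C x (N+1) array of unnormalised joint log posteriors.
joint_log_posterior <- function(X, model) {
  es <- model$event_set
  K <- es$n_events + 1L
  out <- array(NA_real_, c(nrow(X), model$C, K))
  for (c in seq_len(model$C)) {
    ll <- stage_loglik_matrix(X, es, model$sequences[[c]], model$noise_sd)
    out[, c, ] <- ll - log(K) + log(model$fractions[c])
  }
  out
}

#' Assign stages and subtypes to subject-visits
#'
#' Each visit receives the stage maximising its stage posterior (marginal
#' over subtypes, `mode = "marginal"`, the default) and, if that stage is
#' above zero, the subtype maximising its subtype posterior (marginal over
#' stages). Visits at stage zero are deemed not subtypable (their volumes
#' are compatible with controls) and carry no subtype. `mode = "joint"`
#' instead takes the argmax of the joint stage-subtype posterior. Ties break
#' to the smallest index.
#'
#' @param W a `wscore_matrix` (or numeric matrix) of visits to assign.
#' @param model a fitted `sustain_model`.
#' @param mode `"marginal"` (two-step, default) or `"joint"`.
#' @return A data frame of class `sustain_assignments`: subject_id,
#'   visit_index, group, diagnosis, stage, subtype (NA when not subtypable),
#'   subtypable, assignment_probability and per-subtype posterior columns
#'   `prob_S1..`; the full stage posterior is in
#'   `attr(x, "stage_posterior")`.
#' @export
assign_visits <- function(W, model, mode = c("marginal", "joint")) {
  mode <- match.arg(mode)
  X <- wscores(W)
  meta <- wscore_meta(W)
  lj <- joint_log_posterior(X, model)
  n <- nrow(X)
  K <- model$event_set$n_events + 1L
  C <- model$C
  flat <- matrix(lj, nrow = n) # n x (C*K), cell (c,k) at (k-1)*C + c
  norm <- row_logsumexp(flat)
  post <- exp(flat - norm)
  stage_post <- sapply(seq_len(K), function(k)
    rowSums(post[, (k - 1L) * C + seq_len(C), drop = FALSE]))
  stage_post <- matrix(stage_post, nrow = n)
  subtype_post <- sapply(seq_len(C), function(c)
    rowSums(post[, (seq_len(K) - 1L) * C + c, drop = FALSE]))
  subtype_post <- matrix(subtype_post, nrow = n)

  if (mode == "marginal") {
    stage <- max.col(stage_post, ties.method = "first") - 1L
    subtype <- max.col(subtype_post, ties.method = "first")
  } else {
    cell <- max.col(flat, ties.method = "first")
    stage <- (cell - 1L) %/% C
    subtype <- (cell - 1L) %% C + 1L
  }
  subtypable <- stage > 0L
  subtype[!subtypable] <- NA_integer_
  assignment_probability <- ifelse(
    subtypable, subtype_post[cbind(seq_len(n), ifelse(subtypable, subtype, 1L))],
    NA_real_)

  out <- data.frame(meta, stage = stage, subtype = subtype,
                    subtypable = subtypable,
                    assignment_probability = assignment_probability,
                    stringsAsFactors = FALSE)
  colnames(subtype_post) <- paste0("prob_S", seq_len(C))
  out <- cbind(out, as.data.frame(subtype_post))
  colnames(stage_post) <- paste0("stage", 0:(K - 1L))
  attr(out, "stage_posterior") <- stage_post
  class(out) <- c("sustain_assignments", "data.frame")
  out
}

#' Assign an external cohort with a trained model
#'
#' The external cohort is w-scored against its own control set (a fresh
#' covariate model is fitted on `own_controls`), then staged and subtyped
#' with the already-trained subtype model; no model refitting occurs.
#'
#' @param table external regional volume table (patient rows are scored; a
#'   `group` column, if present, selects `group != "control"`).
#' @param own_controls control rows from the same external study.
#' @param model a trained `sustain_model`.
#' @param covariates covariate list for the external w-scoring.
#' @param mode assignment mode, see [assign_visits()].
#' @return A `sustain_assignments` data frame.
#' @export
assign_external <- function(table, own_controls, model,
                            covariates = c("sex", "age", "tiv", "scanner"),
                            mode = "marginal") {
  rois <- model$event_set$roi_names
  missing_rois <- setdiff(rois, names(table))
  if (length(missing_rois))
    stop_config("external cohort lacks model ROIs: %s",
                paste(missing_rois, collapse = ", "))
  cm <- fit_control_model(own_controls, covariates, rois = rois)
  if ("group" %in% names(table))
    table <- table[table$group != "control", , drop = FALSE]
  W <- compute_wscores(table, cm)
  assign_visits(W, model, mode = mode)
}
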