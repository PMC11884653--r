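# Likelihood of w-score data under a threshold-event sequence model.

# Coerce a wscore_matrix or plain matrix to the numeric score matrix.
wscores <- function(W) {
  if (inherits(W, "wscore_matrix")) return(W$scores)
  if (is.data.frame(W)) return(as.matrix(W))
  if (!is.matrix(W)) stop_config("expected a wscore_matrix or numeric matrix")
  W
}

wscore_meta <- function(W) {
  if (inherits(W, "wscore_matrix")) return(W$meta)
  X <- wscores(W)
  data.frame(subject_id = rownames(X) %||% paste0("row", seq_len(nrow(X))),
             visit_index = 1L,
             group = "patient", diagnosis = NA_character_,
             stringsAsFactors = FALSE)
}

check_W_dims <- function(X, event_set) {
  B <- length(event_set$roi_names)
  if (ncol(X) != B)
    stop_config("w-score matrix has %d columns but the event set has %d biomarkers",
                ncol(X), B)
  if (!all(is.finite(X))) stop_config("w-score matrix contains non-finite values")
  invisible(TRUE)
}

seq_args <- function(event_set, sequence) {
  ev <- event_set$events
  list(bio = as.integer(ev$bio[sequence]),
       z = as.numeric(ev$z[sequence]),
       zmax = as.numeric(event_set$z_max))
}

# n x (N+1) matrix of log p(x_i | sequence, stage k), Gaussian noise sd
# noise_sd per biomarker around the expected trajectory.
stage_loglik_matrix <- function(W, event_set, sequence, noise_sd = 1) {
  X <- wscores(W)
  check_W_dims(X, event_set)
  validate_sequence(event_set, sequence)
  a <- seq_args(event_set, sequence)
  sig <- rep_len(noise_sd, ncol(X))
  cpp_stage_loglik(X, a$bio, a$z, a$zmax, sig)
}

# Per-subject marginal log-likelihood under a uniform stage prior 0..N.
marginal_loglik <- function(W, event_set, sequence, noise_sd = 1) {
  X <- wscores(W)
  check_W_dims(X, event_set)
  a <- seq_args(event_set, sequence)
  sig <- rep_len(noise_sd, ncol(X))
  cpp_marginal_loglik(X, a$bio, a$z, a$zmax, sig)
}

#' Likelihood of one subject-visit at a given stage
#'
#' Product over biomarkers of a Gaussian density centred on the expected
#' trajectory value at that stage, with standard deviation `noise_sd`.
#'
#' @param w_row numeric vector of w-scores (one per biomarker).
#' @param event_set an [build_event_set()] object.
#' @param sequence event permutation in stage order.
#' @param stage integer stage in 0..N_events.
#' @param noise_sd Gaussian noise standard deviation (w-score units), scalar
#'   or per-biomarker.
#' @return the probability density (not log).
#' @export
stage_likelihood <- function(w_row, event_set, sequence, stage, noise_sd = 1) {
  N <- event_set$n_events
  if (length(stage) != 1L || stage < 0 || stage > N)
    stop_config("stage out of range 0..%d", N)
  X <- matrix(as.numeric(w_row), nrow = 1L)
  ll <- stage_loglik_matrix(X, event_set, sequence, noise_sd)
  exp(ll[1L, stage + 1L])
}

#' Mixture log-likelihood of a w-score matrix under a subtype model
#'
#' Sums over subjects the log of the subtype mixture
#' \eqn{\sum_c f_c (N+1)^{-1} \sum_k p(x | S_c, k)} with a uniform stage
#' prior over stages 0..N_events.
#'
#' @param W a `wscore_matrix` or numeric matrix (subjects x biomarkers).
#' @param model a fitted [fit_sustain()] model.
#' @return total log-likelihood (scalar).
#' @export
data_log_likelihood <- function(W, model) {
  X <- wscores(W)
  if (nrow(X) == 0L) stop_config("empty w-score matrix")
  ls <- subtype_marginals(X, model)
  sum(row_logsumexp(sweep(ls, 2L, log(model$fractions), `+`)))
}

# n x C matrix of per-subtype marginal log-likelihoods.
subtype_marginals <- function(X, model) {
  m <- vapply(seq_len(model$C), function(c)
    marginal_loglik(X, model$event_set, model$sequences[[c]], model$noise_sd),
    numeric(nrow(X)))
  matrix(m, nrow = nrow(X), ncol = model$C)
}
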