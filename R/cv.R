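# Cross-validated selection of the number of subtypes.

#' Cross-validation information criterion over candidate subtype counts
#'
#' Random (unstratified) fold assignment under a fixed seed; for each fold
#' and candidate C the model hierarchy is fitted on the training folds and
#' the held-out subjects' mixture log-likelihood is evaluated with the
#' point-estimate sequences. CVIC(C) is the sum over folds of -2 x held-out
#' log-likelihood; the selected C minimises CVIC (smallest C wins ties).
#'
#' @param W `wscore_matrix` or numeric matrix.
#' @param event_set an [build_event_set()] object.
#' @param candidate_C candidate numbers of subtypes (default 1:5).
#' @param n_folds number of folds (default 10).
#' @param noise_sd trajectory noise SD.
#' @param seed integer seed controlling folds and fits.
#' @param n_restarts,n_split,em_tol,em_max_iter fitting controls passed to
#'   [fit_sustain()]; lighter defaults than a final fit, since each fold
#'   refits the full hierarchy.
#' @return An object of class `cvic_result` with per-fold held-out
#'   log-likelihoods, `cvic` per candidate and `selected`.
#' @export
cross_validate_sustain <- function(W, event_set, candidate_C = 1:5,
                                   n_folds = 10L, noise_sd = 1, seed = 1L,
                                   n_restarts = 3L, n_split = 1L,
                                   em_tol = 1e-2, em_max_iter = 8L,
                                   split_parents = "largest",
                                   n_em_starts = 1L) {
  X <- wscores(W)
  check_W_dims(X, event_set)
  if (n_folds < 2L) stop_config("n_folds must be >= 2")
  if (!length(candidate_C)) stop_config("no candidate subtype counts")
  candidate_C <- sort(unique(as.integer(candidate_C)))
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  if (min(tabulate(fold, n_folds)) == 0L)
    stop_config("a fold has zero test subjects")

  heldout <- matrix(NA_real_, n_folds, length(candidate_C),
                    dimnames = list(NULL, paste0("C", candidate_C)))
  for (f in seq_len(n_folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    fit <- fit_sustain(X[train, , drop = FALSE], event_set,
                       C = max(candidate_C), noise_sd = noise_sd,
                       n_restarts = n_restarts, n_split = n_split,
                       em_tol = em_tol, em_max_iter = em_max_iter,
                       seed = seed + 1000L * f, keep_path = TRUE,
                       split_parents = split_parents,
                       n_em_starts = n_em_starts)
    path <- attr(fit, "path")
    for (j in seq_along(candidate_C))
      heldout[f, j] <- data_log_likelihood(X[test, , drop = FALSE],
                                           path[[candidate_C[j]]])
  }
  cvic <- -2 * colSums(heldout)
  selected <- candidate_C[which.min(cvic)]
  structure(list(candidate_C = candidate_C, heldout_loglik = heldout,
                 cvic = cvic, selected = selected, n_folds = n_folds,
                 seed = seed),
            class = "cvic_result")
}

#' @export
print.cvic_result <- function(x, ...) {
  cat(sprintf("CVIC over %d folds:\n", x$n_folds))
  for (j in seq_along(x$candidate_C))
    cat(sprintf("  C=%d  CVIC %.2f%s\n", x$candidate_C[j], x$cvic[j],
                if (x$candidate_C[j] == x$selected) "  <- selected" else ""))
  invisible(x)
}
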