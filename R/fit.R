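# Fitting the subtype-and-stage mixture model: greedy sequence ascent for a
# single subtype, cluster-splitting EM initialisation and EM refinement for
# multiple subtypes.

new_sustain_model <- function(event_set, sequences, fractions, noise_sd = 1,
                              loglik = NA_real_, responsibilities = NULL,
                              fit_info = list(), mcmc = NULL) {
  fractions <- as.numeric(fractions)
  if (abs(sum(fractions) - 1) > 1e-12)
    stop_config("subtype fractions must sum to 1")
  for (s in sequences) validate_sequence(event_set, s)
  structure(
    list(event_set = event_set, C = length(sequences),
         sequences = unname(sequences), fractions = fractions,
         noise_sd = noise_sd, loglik = loglik,
         responsibilities = responsibilities, fit_info = fit_info,
         mcmc = mcmc),
    class = "sustain_model"
  )
}

#' @export
print.sustain_model <- function(x, ...) {
  cat(sprintf("Subtype-and-stage model: %d subtype(s), %d events, log-lik %.2f\n",
              x$C, x$event_set$n_events, x$loglik))
  cat(sprintf("  fractions: %s\n",
              paste(sprintf("%.3f", x$fractions), collapse = " ")))
  if (!is.null(x$mcmc))
    cat(sprintf("  MCMC: %d samples, acceptance %.2f\n",
                x$mcmc$n_iter, x$mcmc$acceptance_rate))
  invisible(x)
}

# Weighted greedy event-relocation ascent from a start sequence. Weights
# default to 1 per subject. Returns list(sequence, objective).
optimize_sequence <- function(X, event_set, start, weights = NULL,
                              noise_sd = 1, max_passes = 20L, tol = 1e-9) {
  if (is.null(weights)) weights <- rep(1, nrow(X))
  a <- seq_args(event_set, start)
  sig <- rep_len(noise_sd, ncol(X))
  res <- cpp_greedy_opt(X, a$bio, a$z, a$zmax, sig, as.numeric(weights),
                        as.integer(max_passes), tol)
  list(sequence = sequence_from_bio_z(event_set, res$bio, res$z),
       objective = res$objective, passes = res$passes)
}

# Map (bio, z) stage arrays back to event indices.
sequence_from_bio_z <- function(event_set, bio, z) {
  ev <- event_set$events
  key_all <- paste(ev$bio, ev$z)
  idx <- match(paste(bio, z), key_all)
  if (anyNA(idx)) stop_config("internal: unknown (biomarker, threshold) pair")
  idx
}

# Data-driven start: order events by decreasing weighted exceedance
# frequency, so commonly-abnormal (region, threshold) pairs come early.
init_sequence_datadriven <- function(X, event_set, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(X))
  ev <- event_set$events
  score <- vapply(seq_len(nrow(ev)), function(e)
    sum(weights * (X[, ev$bio[e]] >= ev$z[e])), numeric(1))
  canonicalize_sequence(event_set, order(-score, ev$bio, ev$z))
}

# Single-subtype maximum-likelihood sequence over restarts: one data-driven
# start plus (n_restarts - 1) random starts.
fit_single <- function(X, event_set, weights = NULL, noise_sd = 1,
                       n_restarts = 10L, max_passes = 20L) {
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    start <- if (r == 1L) init_sequence_datadriven(X, event_set, weights)
             else random_sequence(event_set)
    cand <- optimize_sequence(X, event_set, start, weights, noise_sd,
                              max_passes)
    if (is.null(best) || cand$objective > best$objective) best <- cand
  }
  best
}

mixture_loglik <- function(ls, fractions) {
  sum(row_logsumexp(sweep(ls, 2L, log(fractions), `+`)))
}

responsibilities_from <- function(ls, fractions) {
  lw <- sweep(ls, 2L, log(fractions), `+`)
  r <- exp(lw - row_logsumexp(lw))
  r / rowSums(r)
}

#' Fit the subtype-and-stage progression model
#'
#' For `C = 1`, the maximum-likelihood event sequence is found by greedy
#' event-relocation ascent on the marginal log-likelihood over random and
#' data-driven restarts. For `C > 1` the model is built hierarchically: one
#' subtype of the fitted (C-1)-subtype model is split (random bipartitions
#' of its hard-assigned subjects, each half refitted; the best of `n_split`
#' attempts per parent subtype is kept), then refined by
#' expectation-maximization alternating subject responsibilities, fraction
#' updates and responsibility-weighted sequence re-optimisation until the
#' log-likelihood improves by less than `em_tol`.
#'
#' @param W `wscore_matrix` or numeric matrix (subjects x biomarkers).
#' @param event_set an [build_event_set()] object.
#' @param C number of subtypes.
#' @param noise_sd trajectory noise SD in w-score units (default 1; the data
#'   are standardized by w-scoring).
#' @param n_restarts greedy restarts for single-subtype fits.
#' @param n_split bipartition attempts per parent subtype when splitting.
#' @param em_tol EM log-likelihood convergence tolerance.
#' @param em_max_iter maximum EM iterations.
#' @param seed integer seed for restarts and bipartitions.
#' @param keep_path keep the fitted 1..C models as `attr(model, "path")`.
#' @param split_parents `"all"` (default) tries splitting every subtype of
#'   the (C-1)-model; `"largest"` splits only the subtype with most
#'   hard-assigned subjects (cheaper, used inside cross-validation).
#' @param n_em_starts number of top-ranked split initialisations refined by
#'   EM at each level (the initialisation likelihood ranking is an
#'   imperfect predictor of the post-EM optimum; refining the top few and
#'   keeping the best escapes poor hierarchy branches).
#' @param verbose print per-stage log-likelihoods.
#' @return An object of class `sustain_model`.
#' @export
fit_sustain <- function(W, event_set, C = 1L, noise_sd = 1,
                        n_restarts = 10L, n_split = 5L, em_tol = 1e-6,
                        em_max_iter = 100L, seed = NULL, keep_path = FALSE,
                        split_parents = c("all", "largest"),
                        n_em_starts = 2L, verbose = FALSE) {
  split_parents <- match.arg(split_parents)
  X <- wscores(W)
  check_W_dims(X, event_set)
  if (C < 1L) stop_config("C must be >= 1")
  if (C > nrow(X)) stop_config("more subtypes (%d) than subjects (%d)", C,
                               nrow(X))
  if (!is.null(seed)) set.seed(seed)

  path <- vector("list", C)
  fit1 <- fit_single(X, event_set, NULL, noise_sd, n_restarts)
  ls1 <- matrix(marginal_loglik(X, event_set, fit1$sequence, noise_sd),
                ncol = 1L)
  path[[1L]] <- new_sustain_model(
    event_set, list(fit1$sequence), 1, noise_sd, loglik = fit1$objective,
    responsibilities = matrix(1, nrow(X), 1L),
    fit_info = list(n_restarts = n_restarts, em_tol = em_tol, seed = seed,
                    loglik_trace = fit1$objective)
  )
  if (verbose) message(sprintf("C=1 log-lik %.3f", fit1$objective))

  for (cc in seq_len(C)[-1L]) {
    prev <- path[[cc - 1L]]
    inits <- split_inits(X, event_set, prev, noise_sd, n_split,
                         n_restarts, split_parents, n_em_starts)
    em <- NULL
    parent <- NA_integer_
    for (init in inits) {
      cand <- em_refine(X, event_set, init$sequences, init$fractions,
                        noise_sd, em_tol, em_max_iter)
      if (is.null(em) || cand$loglik > em$loglik) {
        em <- cand
        parent <- init$parent
      }
    }
    path[[cc]] <- new_sustain_model(
      event_set, em$sequences, em$fractions, noise_sd, loglik = em$loglik,
      responsibilities = em$responsibilities,
      fit_info = list(n_restarts = n_restarts, n_split = n_split,
                      em_tol = em_tol, em_iter = em$n_iter, seed = seed,
                      loglik_trace = em$trace, split_parent = parent)
    )
    if (verbose) message(sprintf("C=%d log-lik %.3f (%d EM iterations)",
                                 cc, em$loglik, em$n_iter))
  }
  out <- path[[C]]
  if (keep_path) attr(out, "path") <- path
  out
}

# C-subtype initialisations by splitting parent subtypes of the (C-1)-model
# with n_split random bipartitions each; returns the top_k initialisations
# ranked by the mixture likelihood of the un-refined split.
split_inits <- function(X, event_set, prev, noise_sd, n_split,
                        n_restarts, split_parents = "all", top_k = 1L) {
  r <- prev$responsibilities
  hard <- max.col(r, ties.method = "first")
  half_restarts <- max(1L, ceiling(n_restarts / 5L))
  parents <- if (split_parents == "largest")
    which.max(tabulate(hard, prev$C)) else seq_len(prev$C)
  cands <- list()
  for (parent in parents) {
    members <- which(hard == parent)
    if (length(members) < 4L) next
    for (att in seq_len(n_split)) {
      flip <- stats::rbinom(length(members), 1L, 0.5)
      if (sum(flip) < 2L || sum(1 - flip) < 2L) next
      g1 <- members[flip == 1L]
      g2 <- members[flip == 0L]
      s1 <- fit_single(X[g1, , drop = FALSE], event_set, NULL, noise_sd,
                       half_restarts)$sequence
      s2 <- fit_single(X[g2, , drop = FALSE], event_set, NULL, noise_sd,
                       half_restarts)$sequence
      seqs <- c(prev$sequences[-parent], list(s1, s2))
      fr <- c(prev$fractions[-parent],
              prev$fractions[parent] * length(g1) / length(members),
              prev$fractions[parent] * length(g2) / length(members))
      fr <- fr / sum(fr)
      ls <- vapply(seqs, function(s)
        marginal_loglik(X, event_set, s, noise_sd), numeric(nrow(X)))
      ll <- mixture_loglik(matrix(ls, nrow = nrow(X)), fr)
      cands[[length(cands) + 1L]] <- list(sequences = seqs, fractions = fr,
                                          loglik = ll, parent = parent)
    }
  }
  if (!length(cands))
    stop_config("could not split any subtype: clusters too small")
  ord <- order(vapply(cands, `[[`, numeric(1), "loglik"),
               decreasing = TRUE)
  cands[ord[seq_len(min(top_k, length(cands)))]]
}

# EM refinement of a C-subtype model. The sequence M-step runs the weighted
# greedy ascent over the subjects carrying non-negligible responsibility for
# the subtype (weight_floor) and the re-optimised sequence is only accepted
# if it improves the full-data mixture log-likelihood, so the observed
# log-likelihood is non-decreasing by construction (and checked).
em_refine <- function(X, event_set, sequences, fractions, noise_sd,
                      em_tol, em_max_iter, weight_floor = 1e-3) {
  C <- length(sequences)
  ls <- vapply(sequences, function(s)
    marginal_loglik(X, event_set, s, noise_sd), numeric(nrow(X)))
  ls <- matrix(ls, nrow = nrow(X))
  ll <- mixture_loglik(ls, fractions)
  trace <- ll
  # A subtype whose sequence came back unchanged is skipped on subsequent
  # iterations (its responsibilities move little between iterations) until
  # convergence is near, at which point a full sweep over every subtype is
  # forced before convergence may be declared.
  active <- rep(TRUE, C)
  for (it in seq_len(em_max_iter)) {
    r <- responsibilities_from(ls, fractions)
    fractions <- pmax(colMeans(r), 1e-12)
    fractions <- fractions / sum(fractions)
    swept_all <- all(active)
    for (c in seq_len(C)) {
      if (!active[c]) next
      keep <- which(r[, c] > weight_floor)
      if (length(keep) < 2L) next
      # relocations must improve the weighted objective by a meaningful
      # margin (tied to em_tol), otherwise sequences churn on 1e-9 gains
      # and no subtype ever stabilises
      opt <- optimize_sequence(X[keep, , drop = FALSE], event_set,
                               sequences[[c]], r[keep, c], noise_sd,
                               tol = max(em_tol / 10, 1e-9))
      if (identical(opt$sequence, sequences[[c]])) {
        active[c] <- FALSE
        next
      }
      ls_try <- ls
      ls_try[, c] <- marginal_loglik(X, event_set, opt$sequence, noise_sd)
      if (mixture_loglik(ls_try, fractions) >= mixture_loglik(ls, fractions)) {
        sequences[[c]] <- opt$sequence
        ls <- ls_try
      } else {
        active[c] <- FALSE
      }
    }
    new_ll <- mixture_loglik(ls, fractions)
    if (new_ll < ll - 1e-6)
      warning(sprintf("EM log-likelihood decreased by %.2e", ll - new_ll))
    trace <- c(trace, new_ll)
    if (new_ll - ll < em_tol) {
      ll <- new_ll
      if (swept_all) break
      active <- rep(TRUE, C) # confirm convergence with a full sweep
    } else {
      ll <- new_ll
    }
  }
  list(sequences = sequences, fractions = fractions, loglik = ll,
       responsibilities = responsibilities_from(ls, fractions),
       n_iter = length(trace) - 1L, trace = trace)
}
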