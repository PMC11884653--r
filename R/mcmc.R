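# Metropolis MCMC over event sequences for model uncertainty.

#' MCMC uncertainty estimation for a fitted subtype model
#'
#' Metropolis sampling over the per-subtype event sequences: each iteration
#' picks one subtype uniformly, moves one randomly chosen event to a
#' uniformly random position (restoring ascending threshold order within
#' that event's biomarker), and accepts with probability min(1, likelihood
#' ratio) of the full mixture data likelihood (fractions held at their
#' fitted values). The sampler starts from the fitted (EM-initialised)
#' model, so no burn-in is discarded: all `n_iter` samples are retained.
#'
#' @param model a fitted [fit_sustain()] model (used as the start point).
#' @param W the w-score data the model was fitted to.
#' @param n_iter number of MCMC iterations (default 10000).
#' @param seed integer seed.
#' @return The model with a `mcmc` component: `samples` (one
#'   `n_iter x N_events` matrix of event indices per subtype), `loglik`
#'   trace, `acceptance_rate`, `n_iter` and `seed`.
#' @export
sustain_mcmc <- function(model, W, n_iter = 10000L, seed = NULL) {
  if (n_iter < 1L) stop_config("n_iter must be >= 1")
  X <- wscores(W)
  es <- model$event_set
  check_W_dims(X, es)
  if (!is.null(seed)) set.seed(seed)
  N <- es$n_events
  C <- model$C
  seqs <- model$sequences
  ls <- subtype_marginals(X, model)
  logf <- log(model$fractions)
  ll <- sum(row_logsumexp(sweep(ls, 2L, logf, `+`)))

  samples <- lapply(seq_len(C), function(c)
    matrix(NA_integer_, n_iter, N))
  ll_trace <- numeric(n_iter)
  accepted <- 0L

  for (it in seq_len(n_iter)) {
    c <- if (C > 1L) sample.int(C, 1L) else 1L
    from <- sample.int(N, 1L)
    to <- sample.int(N, 1L)
    prop <- propose_move(es, seqs[[c]], from, to)
    if (identical(prop, seqs[[c]])) {
      accepted <- accepted + 1L # identical proposal: ratio 1
    } else {
      ls_c <- marginal_loglik(X, es, prop, model$noise_sd)
      ls2 <- ls
      ls2[, c] <- ls_c
      new_ll <- sum(row_logsumexp(sweep(ls2, 2L, logf, `+`)))
      if (log(stats::runif(1)) < new_ll - ll) {
        seqs[[c]] <- prop
        ls <- ls2
        ll <- new_ll
        accepted <- accepted + 1L
      }
    }
    for (cc in seq_len(C)) samples[[cc]][it, ] <- seqs[[cc]]
    ll_trace[it] <- ll
  }

  model$mcmc <- list(samples = samples, loglik = ll_trace,
                     acceptance_rate = accepted / n_iter,
                     n_iter = n_iter, seed = seed)
  model
}

# Move the event at stage `from` to stage `to`, then restore ascending
# threshold order within the moved event's biomarker.
propose_move <- function(event_set, sequence, from, to) {
  s <- sequence[-from]
  s <- append(s, sequence[from], after = to - 1L)
  canonicalize_bio(event_set, s, event_set$events$bio[sequence[from]])
}

# Canonicalize a single biomarker's threshold order (cheaper than the full
# canonicalization when only one biomarker may be out of order).
canonicalize_bio <- function(event_set, sequence, b) {
  bio <- event_set$events$bio[sequence]
  pos <- which(bio == b)
  sequence[pos] <- sort(sequence[pos])
  sequence
}
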