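# Positional-variance distributions, Hellinger distance and randomized
# reference values for subtype similarity.

#' Positional variance distribution of MCMC sequence samples
#'
#' The matrix behind a positional variance diagram: entry (e, s) is the
#' posterior probability that event e occupies stage position s, estimated
#' as its empirical frequency across MCMC samples. Because every sample is a
#' permutation, rows and columns each sum to 1.
#'
#' @param samples integer matrix (samples x N_events) of sequences, e.g.
#'   `model$mcmc$samples[[c]]`, or a list of equal-length sequences.
#' @param labels optional event labels for the rows.
#' @return An `N_events x N_events` matrix of class `positional_variance`;
#'   rows events, columns stage positions.
#' @export
positional_variance <- function(samples, labels = NULL) {
  if (is.list(samples)) {
    if (length(unique(lengths(samples))) != 1L)
      stop_config("samples have inconsistent lengths")
    samples <- do.call(rbind, samples)
  }
  if (!is.matrix(samples) || nrow(samples) < 1L)
    stop_config("need at least one sample")
  N <- ncol(samples)
  P <- matrix(0, N, N)
  for (s in seq_len(N)) {
    tab <- tabulate(samples[, s], nbins = N)
    P[, s] <- tab / nrow(samples)
  }
  if (!is.null(labels)) rownames(P) <- labels
  colnames(P) <- seq_len(N)
  class(P) <- c("positional_variance", class(P))
  P
}

#' Hellinger distance between two discrete distributions
#'
#' \eqn{H(P,Q) = \sqrt{1 - \sum_i \sqrt{p_i q_i}}}, equivalently
#' \eqn{\sqrt{\frac12 \sum_i (\sqrt{p_i} - \sqrt{q_i})^2}}: 0 for identical
#' distributions, 1 when the supports are disjoint.
#'
#' @param p,q non-negative probability vectors of equal length, each
#'   summing to 1 (tolerance 1e-8).
#' @return distance in \[0, 1\].
#' @export
hellinger <- function(p, q) {
  if (length(p) != length(q)) stop_config("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop_config("negative probabilities")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop_config("p and q must each sum to 1")
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

#' Distance between two positional variance distributions
#'
#' Aggregates the Hellinger distance between corresponding per-event
#' position distributions (matrix rows) over all events.
#'
#' @param A,B `positional_variance` matrices over the same event set.
#' @param aggregate `"mean"` (default) or `"max"` over events.
#' @return distance in \[0, 1\].
#' @export
model_distance <- function(A, B, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!all(dim(A) == dim(B)))
    stop_config("positional variance matrices have mismatched event sets")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop_config("positional variance matrices have mismatched event labels")
  d <- vapply(seq_len(nrow(A)), function(e) hellinger(A[e, ], B[e, ]),
              numeric(1))
  if (aggregate == "mean") mean(d) else max(d)
}

#' Randomized-model reference distance
#'
#' The expected distance between unrelated models, against which observed
#' subtype similarities are judged. Scheme `"delta-permutation"` draws pairs
#' of independent uniformly random event permutations (delta positional
#' distributions); by symmetry each event occupies the same position with
#' probability 1/N, so the mean distance converges to 1 - 1/N. Scheme
#' `"permuted-data"` destroys the cross-biomarker correlation of a w-score
#' matrix by permuting each biomarker's rows independently, fits a
#' single-subtype model with a short MCMC to each of two independently
#' permuted copies, and measures the distance between their positional
#' variance distributions.
#'
#' @param event_set an [build_event_set()] object.
#' @param scheme `"delta-permutation"` or `"permuted-data"`.
#' @param n_pairs number of random pairs (>= 2).
#' @param seed integer seed.
#' @param W w-score data (required for `"permuted-data"`).
#' @param mcmc_iter MCMC iterations per refit (`"permuted-data"` only).
#' @param n_restarts greedy restarts per refit (`"permuted-data"` only).
#' @return A list of class `randomized_reference` with `h0_mean`, `h0_sd`,
#'   95% `ci` of the mean, `n_pairs`, `scheme` and `seed`.
#' @export
randomized_reference <- function(event_set,
                                 scheme = c("delta-permutation",
                                            "permuted-data"),
                                 n_pairs = 2000L, seed = 1L, W = NULL,
                                 mcmc_iter = 200L, n_restarts = 2L) {
  scheme <- match.arg(scheme)
  if (n_pairs < 2L) stop_config("n_pairs must be >= 2")
  set.seed(seed)
  N <- event_set$n_events
  d <- numeric(n_pairs)
  if (scheme == "delta-permutation") {
    for (p in seq_len(n_pairs)) {
      a <- sample.int(N)
      b <- sample.int(N)
      # delta rows: Hellinger is 0 where positions agree, 1 otherwise
      d[p] <- mean(order(a) != order(b))
    }
  } else {
    if (is.null(W)) stop_config("scheme 'permuted-data' requires W")
    X <- wscores(W)
    check_W_dims(X, event_set)
    one_pvd <- function() {
      Xp <- apply(X, 2L, sample)
      fit <- fit_sustain(Xp, event_set, C = 1L, n_restarts = n_restarts,
                         seed = sample.int(2^30, 1L))
      fit <- sustain_mcmc(fit, Xp, n_iter = mcmc_iter,
                          seed = sample.int(2^30, 1L))
      positional_variance(fit$mcmc$samples[[1L]])
    }
    for (p in seq_len(n_pairs)) d[p] <- model_distance(one_pvd(), one_pvd())
  }
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(h0_mean = m, h0_sd = s,
                 ci = m + c(-1, 1) * stats::qnorm(0.975) * s / sqrt(n_pairs),
                 n_pairs = n_pairs, scheme = scheme, seed = seed,
                 distances = d),
            class = "randomized_reference")
}

#' @export
print.randomized_reference <- function(x, ...) {
  cat(sprintf("Randomized reference (%s): H0 = %.3f +/- %.3f (95%% CI %.3f, %.3f; %d pairs)\n",
              x$scheme, x$h0_mean, x$h0_sd, x$ci[1], x$ci[2], x$n_pairs))
  invisible(x)
}
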