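# Small shared helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# argmax with deterministic smallest-index tie-break
which_max1 <- function(x) which.max(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Kendall rank correlation between two event sequences
#'
#' Compares two orderings of the same event set by the Kendall tau of the
#' stage positions they assign to each event. A value of 1 means identical
#' orderings, -1 a fully reversed ordering.
#'
#' @param seq_a,seq_b integer vectors, each a permutation of the same event
#'   indices in stage order.
#' @return Kendall's tau in \[-1, 1\].
#' @export
sequence_kendall <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b) || !setequal(seq_a, seq_b))
    stop_config("sequences must be permutations of the same event set")
  pos_a <- order(seq_a)
  pos_b <- order(seq_b)
  stats::cor(pos_a, pos_b, method = "kendall")
}

# Best assignment of fitted subtypes to planted subtypes, maximizing the mean
# Kendall tau over all subtype permutations (C <= 6).
match_subtypes <- function(fitted_sequences, truth_sequences) {
  C <- length(fitted_sequences)
  stopifnot(length(truth_sequences) == C)
  tau <- matrix(NA_real_, C, C)
  for (i in seq_len(C))
    for (j in seq_len(C))
      tau[i, j] <- sequence_kendall(fitted_sequences[[i]], truth_sequences[[j]])
  perms <- permutations_of(seq_len(C))
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    v <- mean(tau[cbind(seq_len(C), p)])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  list(map = best, mean_tau = best_val,
       tau = tau[cbind(seq_len(C), best)])
}

# All permutations of a vector (small n only).
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}
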