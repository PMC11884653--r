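# Shared fixtures: all data is generated in code at test time.

# A tiny 3-biomarker, single-threshold design (3 events, 6 valid sequences).
tiny_event_set <- function() build_event_set(paste0("r", 1:3), 1)

# A small single-subtype synthetic configuration.
small_config <- function(n = 60, noise_sd = 1, seed = 11,
                         roi_names = paste0("r", 1:3), thresholds = 1,
                         truth_sequences = NULL, ...) {
  es <- build_event_set(roi_names, thresholds)
  if (is.null(truth_sequences))
    truth_sequences <- list(seq_len(es$n_events))
  synthetic_config(
    n_patients = n, n_controls = 40, roi_names = roi_names,
    thresholds = thresholds, subtype_fractions = 1,
    truth_sequences = truth_sequences, noise_sd = noise_sd, seed = seed, ...)
}

# Planted w-scores of baseline patients, scored with the exact generating
# covariate model (so noise-free cohorts invert exactly).
planted_wscores <- function(sim) {
  tab <- sim$table
  compute_wscores(tab[tab$group == "patient" & tab$visit_index == 1L, ],
                  sim$true_model)
}

baseline_truth <- function(sim) {
  tr <- sim$truth
  tr[tr$group == "patient" & tr$visit_index == 1L, ]
}

# Exact sequence posterior on a small event set by full enumeration.
enumerated_posterior <- function(X, event_set, noise_sd = 1) {
  seqs <- sustainr:::enumerate_sequences(event_set)
  ll <- vapply(seqs, function(s)
    sum(sustainr:::marginal_loglik(X, event_set, s, noise_sd)), numeric(1))
  p <- exp(ll - max(ll))
  list(sequences = seqs, posterior = p / sum(p), loglik = ll)
}

seq_key <- function(s) paste(s, collapse = "-")
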