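#' Build the threshold-event set for a progression model
#'
#' Each biomarker (region of interest) contributes one event per severity
#' threshold: event (b, z) "occurs" when biomarker b's abnormality w-score
#' reaches z. With shared thresholds the number of model events is
#' `length(roi_names) * length(thresholds)`; e.g. 19 regions with thresholds
#' (1, 2, 3) give 57 events. Beyond its top threshold a biomarker's expected
#' trajectory rises towards `z_max` (default: top threshold + 2) at the final
#' stage.
#'
#' @param roi_names character vector of biomarker (region) names.
#' @param thresholds strictly ascending positive w-score severity levels
#'   shared by all biomarkers.
#' @param z_max trajectory ceiling per biomarker; scalar or vector of
#'   `length(roi_names)`. Must exceed the top threshold.
#' @return An object of class `event_set`: a list with `events` (data frame
#'   with columns `bio`, `z`, `label`), `roi_names`, `thresholds`, `z_max`
#'   and `n_events`.
#' @examples
#' es <- build_event_set(paste0("roi", 1:3), thresholds = c(1, 3))
#' es$n_events # 6
#' @export
build_event_set <- function(roi_names, thresholds = c(1, 2, 3),
                            z_max = NULL) {
  if (length(roi_names) < 1L) stop_config("need at least one ROI")
  if (length(thresholds) < 1L || any(thresholds <= 0) ||
      any(diff(thresholds) <= 0))
    stop_config("thresholds must be strictly ascending and positive")
  if (anyDuplicated(roi_names)) stop_config("duplicated ROI names")
  B <- length(roi_names)
  if (is.null(z_max)) z_max <- max(thresholds) + 2
  z_max <- rep_len(z_max, B)
  if (any(z_max <= max(thresholds)))
    stop_config("z_max must exceed the top threshold for every biomarker")
  events <- data.frame(
    bio = rep(seq_len(B), each = length(thresholds)),
    z = rep(thresholds, times = B)
  )
  events$label <- paste0(roi_names[events$bio], "|z", events$z)
  structure(
    list(events = events, roi_names = roi_names, thresholds = thresholds,
         z_max = z_max, n_events = nrow(events)),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("Threshold event set: %d biomarkers x %d thresholds = %d events\n",
              length(x$roi_names), length(x$thresholds), x$n_events))
  invisible(x)
}

# A sequence is an integer vector of event indices in stage order
# (sequence[k] = event occurring at stage k). Valid sequences keep each
# biomarker's threshold events in ascending z order.
validate_sequence <- function(event_set, sequence) {
  N <- event_set$n_events
  if (length(sequence) != N || !setequal(sequence, seq_len(N)))
    stop_config("sequence must be a permutation of the %d event indices", N)
  ev <- event_set$events[sequence, ]
  for (b in unique(ev$bio)) {
    zb <- ev$z[ev$bio == b]
    if (is.unsorted(zb, strictly = TRUE))
      stop_config("thresholds of biomarker %d out of ascending order", b)
  }
  invisible(TRUE)
}

# Reassign each biomarker's thresholds in ascending order along its current
# positions, turning an arbitrary permutation into a valid sequence.
canonicalize_sequence <- function(event_set, sequence) {
  ev <- event_set$events
  bio <- ev$bio[sequence]
  out <- sequence
  for (b in unique(bio)) {
    pos <- which(bio == b)
    ids <- sort(sequence[pos]) # event indices ascend with z within biomarker
    out[pos] <- ids
  }
  out
}

# Uniformly random *valid* sequence (random permutation, then canonicalized).
random_sequence <- function(event_set) {
  canonicalize_sequence(event_set, sample.int(event_set$n_events))
}

# Enumerate all valid sequences of a (small) event set. Used as a brute-force
# oracle for greedy/MCMC checks; guard against combinatorial blow-up.
enumerate_sequences <- function(event_set, max_n = 100000L) {
  N <- event_set$n_events
  perms <- permutations_of(seq_len(N))
  keep <- list()
  for (p in perms) {
    ok <- tryCatch({
      validate_sequence(event_set, p)
      TRUE
    }, error = function(e) FALSE)
    if (ok) keep[[length(keep) + 1L]] <- p
    if (length(keep) > max_n) stop_config("too many sequences to enumerate")
  }
  keep
}

#' Expected abnormality trajectory value
#'
#' The expected w-score of a biomarker at a model stage under a given event
#' sequence: 0 at stage 0, exactly the threshold z at the stage where the
#' (biomarker, z) event sits, linear in between, and rising linearly from the
#' last threshold to the biomarker's `z_max` at the final stage.
#'
#' @param event_set an [build_event_set()] object.
#' @param sequence integer event permutation in stage order.
#' @param biomarker biomarker index (1-based) or ROI name.
#' @param stage integer stage(s) in 0..N_events.
#' @return numeric vector of expected w-scores, one per stage.
#' @export
expected_value <- function(event_set, sequence, biomarker, stage) {
  validate_sequence(event_set, sequence)
  if (is.character(biomarker))
    biomarker <- match(biomarker, event_set$roi_names)
  if (is.na(biomarker) || biomarker < 1 ||
      biomarker > length(event_set$roi_names))
    stop_config("unknown biomarker")
  N <- event_set$n_events
  if (any(stage < 0 | stage > N)) stop_config("stage out of range 0..%d", N)
  E <- stage_expectations(event_set, sequence)
  unname(E[stage + 1L, biomarker])
}

# Full (N+1) x B expected-value matrix for a sequence.
stage_expectations <- function(event_set, sequence) {
  ev <- event_set$events
  E <- cpp_expected_matrix(as.integer(ev$bio[sequence]),
                           as.numeric(ev$z[sequence]),
                           as.numeric(event_set$z_max),
                           length(event_set$roi_names))
  colnames(E) <- event_set$roi_names
  rownames(E) <- 0:event_set$n_events
  E
}
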