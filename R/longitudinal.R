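# Longitudinal stability of subtype and stage assignments.

#' Longitudinal stability of subtype and stage assignments
#'
#' Summarises assignment consistency across visits. Subjects unsubtypable at
#' baseline (stage zero) are excluded from all denominators. Subtype
#' stability compares baseline with the first follow-up visit; staging
#' outcomes (advanced / same / regressed) and the same-or-advanced staging
#' consistency are computed among subjects whose subtype was stable.
#' Multi-visit counts (always same subtype; monotonically non-decreasing
#' stage) cover subjects with three or more visits.
#'
#' @param assignments a [assign_visits()] data frame containing at least one
#'   subject with two or more visits.
#' @return A list of class `stability_report`: `n_longitudinal`,
#'   `per_subtype_stability`, `overall_stability`, `stage_outcomes`
#'   (advanced/same/regressed counts), `staging_consistency`,
#'   `multi_visit` counts and the [transition_counts()] matrix.
#' @export
stability_metrics <- function(assignments) {
  a <- assignments[order(assignments$subject_id, assignments$visit_index), ]
  base <- a[a$visit_index == 1L, ]
  fu <- a[a$visit_index > 1L, ]
  has_fu <- intersect(base$subject_id, fu$subject_id)
  if (!length(has_fu))
    stop_config("no longitudinal subjects: every subject has a single visit")
  base <- base[base$subject_id %in% has_fu & base$subtypable, ]
  n_long <- nrow(base)
  if (!n_long)
    stop_config("no subtypable baseline among longitudinal subjects")

  first_fu <- fu[!duplicated(fu$subject_id), ] # earliest follow-up per subject
  m <- match(base$subject_id, first_fu$subject_id)
  f1 <- first_fu[m, ]
  stable <- !is.na(f1$subtype) & f1$subtype == base$subtype

  C <- length(grep("^prob_S", names(assignments)))
  per_subtype <- vapply(seq_len(C), function(c) {
    idx <- base$subtype == c
    if (!any(idx)) return(NA_real_)
    mean(stable[idx])
  }, numeric(1))
  names(per_subtype) <- paste0("S", seq_len(C))

  ds <- f1$stage[stable] - base$stage[stable]
  outcomes <- c(advanced = sum(ds > 0), same = sum(ds == 0),
                regressed = sum(ds < 0))

  multi_ids <- names(which(table(a$subject_id[a$subject_id %in%
                                                base$subject_id]) >= 3L))
  always_same <- 0L
  monotone <- 0L
  for (id in multi_ids) {
    rows <- a[a$subject_id == id, ]
    if (length(unique(rows$subtype)) == 1L && !anyNA(rows$subtype))
      always_same <- always_same + 1L
    if (!is.unsorted(rows$stage)) monotone <- monotone + 1L
  }

  structure(list(
    n_longitudinal = n_long,
    per_subtype_stability = per_subtype,
    overall_stability = mean(stable),
    stage_outcomes = outcomes,
    staging_consistency = if (sum(outcomes) > 0)
      unname((outcomes["advanced"] + outcomes["same"]) / sum(outcomes))
      else NA_real_,
    multi_visit = c(n = length(multi_ids), always_same_subtype = always_same,
                    monotone_stage = monotone),
    transition = transition_counts(assignments)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Longitudinal stability over %d subjects:\n", x$n_longitudinal))
  cat(sprintf("  subtype stability %.1f%% (per subtype: %s)\n",
              100 * x$overall_stability,
              paste(sprintf("%s %.0f%%", names(x$per_subtype_stability),
                            100 * x$per_subtype_stability),
                    collapse = ", ")))
  o <- x$stage_outcomes
  cat(sprintf("  staging: %d advanced / %d same / %d regressed (consistency %.1f%%)\n",
              o["advanced"], o["same"], o["regressed"],
              100 * x$staging_consistency))
  invisible(x)
}

#' Baseline-to-follow-up subtype transition counts
#'
#' Counts of baseline subtype versus first-follow-up subtype among subjects
#' subtypable at baseline, with a final "stage-zero" sink column for
#' follow-ups assigned stage zero.
#'
#' @param assignments a [assign_visits()] data frame.
#' @return An integer matrix, rows baseline subtypes, columns follow-up
#'   subtypes plus `stage0`.
#' @export
transition_counts <- function(assignments) {
  a <- assignments[order(assignments$subject_id, assignments$visit_index), ]
  base <- a[a$visit_index == 1L & a$subtypable, ]
  fu <- a[a$visit_index > 1L, ]
  first_fu <- fu[!duplicated(fu$subject_id), ]
  m <- match(base$subject_id, first_fu$subject_id)
  keep <- !is.na(m)
  base <- base[keep, ]
  f1 <- first_fu[m[keep], ]
  C <- length(grep("^prob_S", names(assignments)))
  tm <- matrix(0L, C, C + 1L,
               dimnames = list(paste0("S", seq_len(C)),
                               c(paste0("S", seq_len(C)), "stage0")))
  for (i in seq_len(nrow(base))) {
    to <- if (is.na(f1$subtype[i])) C + 1L else f1$subtype[i]
    tm[base$subtype[i], to] <- tm[base$subtype[i], to] + 1L
  }
  tm
}
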