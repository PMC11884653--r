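# Subtype-phenotype cross-tabulation and single-phenotype staging models.

#' Subtype-by-diagnosis contingency report
#'
#' Cross-tabulates data-driven subtype assignments against clinical
#' diagnosis labels among subtypable visits and runs a Pearson chi-square
#' test of independence (no continuity correction). Rows or columns with a
#' zero margin are dropped with a warning.
#'
#' @param assignments a [assign_visits()] data frame (baseline rows with
#'   `visit_index == 1` are used).
#' @param diagnosis optional vector overriding the `diagnosis` column.
#' @return A list of class `contingency_report`: `table`, `statistic`, `df`,
#'   `n`, `p_value`.
#' @export
contingency_report <- function(assignments, diagnosis = NULL) {
  base <- assignments[assignments$visit_index == 1L, ]
  if (is.null(diagnosis)) diagnosis <- base$diagnosis
  keep <- base$subtypable & !is.na(diagnosis)
  tab <- table(subtype = paste0("S", base$subtype[keep]),
               diagnosis = diagnosis[keep])
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d zero-margin row(s) and %d column(s)",
                    sum(zr), sum(zc)))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_config("contingency table needs >= 2 rows and columns")
  # small expected counts only affect the asymptotic p-value approximation;
  # the statistic itself is exact, so the caveat is not re-raised per call
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), n = sum(tab),
                 p_value = unname(ct$p.value)),
            class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square(%d, n = %d) = %.1f, P = %.3g\n",
              x$df, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' Single-phenotype staging model
#'
#' Fits a one-subtype progression model (with MCMC uncertainty) to the
#' subset of visits carrying one clinical diagnosis, for Hellinger
#' comparison of its positional variance distribution with the data-driven
#' subtypes. All model parameters other than the subtype count match
#' [fit_sustain()].
#'
#' @param W a `wscore_matrix` whose metadata carries diagnosis labels.
#' @param diagnosis the diagnosis label to keep.
#' @param event_set an [build_event_set()] object.
#' @param min_n minimum subset size (default 20).
#' @param mcmc_iter MCMC iterations (default 10000).
#' @param seed integer seed.
#' @param ... further arguments to [fit_sustain()].
#' @return A `sustain_model` with `C = 1` and MCMC samples.
#' @export
single_phenotype_fit <- function(W, diagnosis, event_set, min_n = 20L,
                                 mcmc_iter = 10000L, seed = NULL, ...) {
  if (!inherits(W, "wscore_matrix"))
    stop_config("W must be a wscore_matrix with diagnosis metadata")
  idx <- which(W$meta$diagnosis == diagnosis & W$meta$visit_index == 1L)
  if (length(idx) < min_n)
    stop_config("only %d visits with diagnosis '%s' (need >= %d)",
                length(idx), diagnosis, min_n)
  Wd <- subset_wscores(W, idx)
  fit <- fit_sustain(Wd, event_set, C = 1L, seed = seed, ...)
  sustain_mcmc(fit, Wd, n_iter = mcmc_iter, seed = seed)
}
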